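#' Comparative delta-delta-Ct quantification
#'
#' For each target gene and sample: `dCt = Ct_gene - mean(Ct_refs)` with
#' the reference aggregated as the arithmetic mean of the reference-gene
#' Ct values (the geometric mean of their linear quantities);
#' `ddCt = dCt - mean dCt of the calibrator group`; relative expression
#' `FC = 2^(-ddCt)`. The calibrator group's mean ddCt is zero by
#' construction, so its geometric-mean fold change is 1.
#'
#' @param ct Long-format data.frame with columns `gene`, `sample`, `ct`
#'   (raw Ct in cycles), containing the reference genes for every sample.
#' @param groups Named character vector or data.frame (`sample`, `group`)
#'   mapping samples to groups.
#' @param reference_genes Reference mRNAs averaged per sample.
#' @param calibrator Group whose mean dCt anchors ddCt (reported fold
#'   changes are relative to it).
#' @return A `ddct_table` data.frame with per-(gene, sample) columns
#'   `ref_mean_ct`, `delta_ct`, `ddct`, `fold_change`, plus `group`.
#' @export
delta_delta_ct <- function(ct, groups, reference_genes = c("ACTB", "GUSB"),
                           calibrator) {
  stopifnot(all(c("gene", "sample", "ct") %in% colnames(ct)))
  if (is.data.frame(groups)) {
    groups <- stats::setNames(groups$group, groups$sample)
  }
  samples <- unique(ct$sample)
  unmapped <- setdiff(samples, names(groups))
  if (length(unmapped)) {
    stop("sample(s) without group assignment: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  if (!calibrator %in% groups) {
    stop("calibrator group ", calibrator, " has no samples", call. = FALSE)
  }
  ref_mean <- vapply(samples, function(s) {
    r <- ct$ct[ct$sample == s & ct$gene %in% reference_genes]
    if (length(r) != length(reference_genes) || anyNA(r)) {
      stop("missing reference Ct for sample ", s, call. = FALSE)
    }
    mean(r)
  }, numeric(1))
  tgt <- ct[!ct$gene %in% reference_genes, , drop = FALSE]
  tgt$ref_mean_ct <- ref_mean[tgt$sample]
  tgt$delta_ct <- tgt$ct - tgt$ref_mean_ct
  tgt$group <- unname(groups[tgt$sample])
  cal_mean <- vapply(unique(tgt$gene), function(g) {
    mean(tgt$delta_ct[tgt$gene == g & tgt$group == calibrator])
  }, numeric(1))
  tgt$ddct <- tgt$delta_ct - cal_mean[tgt$gene]
  tgt$fold_change <- 2^(-tgt$ddct)
  rownames(tgt) <- NULL
  class(tgt) <- c("ddct_table", "data.frame")
  attr(tgt, "reference_genes") <- reference_genes
  attr(tgt, "calibrator") <- calibrator
  tgt
}

#' @export
print.ddct_table <- function(x, ...) {
  cat(sprintf("ddct_table: %d genes x %d samples (references: %s; calibrator: %s)\n",
              length(unique(x$gene)), length(unique(x$sample)),
              paste(attr(x, "reference_genes"), collapse = "/"),
              attr(x, "calibrator")))
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Per-gene two-group comparison of relative expression
#'
#' Welch two-sided t-test on the log2 fold changes (equivalently on
#' `-ddCt`), each gene analyzed individually without assuming a common
#' standard deviation. Degenerate input with zero variance in both groups
#' and equal means yields p = 1.
#'
#' @param ddct A `ddct_table`.
#' @param group_a,group_b Group labels to compare.
#' @return data.frame per gene: group mean fold changes with SEM (of the
#'   per-sample fold changes), mean log2 FC difference, raw `p`.
#' @export
compare_groups <- function(ddct, group_a, group_b) {
  stopifnot(inherits(ddct, "ddct_table"))
  genes <- unique(ddct$gene)
  rows <- lapply(genes, function(g) {
    xa <- -ddct$ddct[ddct$gene == g & ddct$group == group_a]
    xb <- -ddct$ddct[ddct$gene == g & ddct$group == group_b]
    if (length(xa) < 2L || length(xb) < 2L) {
      stop("gene ", g, ": each group needs >= 2 samples", call. = FALSE)
    }
    p <- if (stats::sd(xa) == 0 && stats::sd(xb) == 0) {
      if (isTRUE(all.equal(mean(xa), mean(xb)))) 1 else 0
    } else {
      stats::t.test(xa, xb, var.equal = FALSE)$p.value
    }
    fa <- 2^xa; fb <- 2^xb
    data.frame(gene = g,
               mean_fc_a = mean(fa), sem_fc_a = stats::sd(fa) / sqrt(length(fa)),
               mean_fc_b = mean(fb), sem_fc_b = stats::sd(fb) / sqrt(length(fb)),
               log2fc_diff = mean(xa) - mean(xb), p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "comparison") <- c(group_a, group_b)
  out
}

#' Holm-Sidak step-down multiple-comparison adjustment
#'
#' Sorts p ascending and sets
#' `adj_(i) = max_{j <= i} [1 - (1 - p_(j))^(m - j + 1)]`, clipped at 1,
#' then restores input order. The running maximum enforces monotone
#' step-down rejection; `reject` flags `adj <= alpha`.
#'
#' @param p Raw p-values in \[0, 1\].
#' @param alpha Familywise significance level.
#' @return data.frame with columns `p`, `adj_p`, `reject` in input order.
#' @export
holm_sidak_adjust <- function(p, alpha = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj_sorted <- pmin(1, cummax(1 - (1 - ps)^(m - seq_len(m) + 1)))
  adj <- numeric(m)
  adj[ord] <- adj_sorted
  data.frame(p = p, adj_p = adj, reject = adj <= alpha)
}
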