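#' Union of predicted target genes of a miRNA set
#'
#' Looks each query miRNA up in a miRNA-to-gene mapping table (columns
#' `mirna_id`, `gene_id`) after name canonicalization and returns the
#' union of their targets. Query miRNAs absent from the table are reported
#' with a warning, not an error (prediction databases are never complete).
#'
#' @param mirnas Character vector of miRNA names.
#' @param targets Mapping data.frame (see [read_mapping_table()]).
#' @param min_score Optional lower bound applied to a numeric `score`
#'   column when present (interaction-confidence filtering).
#' @return Character vector of unique target gene ids.
#' @export
mirna_target_union <- function(mirnas, targets, min_score = NULL) {
  stopifnot(all(c("mirna_id", "gene_id") %in% colnames(targets)))
  if (!nrow(targets)) stop("empty mapping table", call. = FALSE)
  if (!is.null(min_score)) {
    if (!"score" %in% colnames(targets)) {
      stop("min_score given but mapping table has no 'score' column",
           call. = FALSE)
    }
    targets <- targets[as.numeric(targets$score) >= min_score, , drop = FALSE]
  }
  key <- canonicalize_mirna(targets$mirna_id)
  q <- canonicalize_mirna(mirnas)
  missing <- mirnas[!q %in% key]
  if (length(missing)) {
    warning("miRNA(s) absent from target table: ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  unique(targets$gene_id[key %in% q])
}

#' Hypergeometric over-representation analysis
#'
#' For each pathway, tests whether the query gene set overlaps the pathway
#' more than expected by chance when drawing `n` genes from a universe of
#' `N`: the one-sided upper tail
#' `p = sum_{i >= k} C(K,i) C(N-K, n-i) / C(N, n)`, with BH adjustment
#' across pathways. Query genes outside the universe are dropped with a
#' warning. Only over-representation is tested.
#'
#' @param query Character vector of gene ids.
#' @param pathways Mapping data.frame with columns `gene_id`, `pathway_id`
#'   and optionally `pathway_name`.
#' @param universe Gene universe; defaults to all genes in `pathways`.
#' @return An `ora_result` data.frame sorted by adjusted p: pathway id and
#'   name, `N`, `K`, `n`, `k`, `p`, `adj_p`, and the overlapping gene ids
#'   (comma-separated).
#' @export
hypergeometric_ora <- function(query, pathways, universe = NULL) {
  stopifnot(all(c("gene_id", "pathway_id") %in% colnames(pathways)))
  if (is.null(universe)) universe <- unique(pathways$gene_id)
  universe <- unique(universe)
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped",
            call. = FALSE)
    query <- intersect(query, universe)
  }
  if (!length(query)) stop("empty query after universe filtering", call. = FALSE)
  N <- length(universe)
  n <- length(query)
  ids <- unique(pathways$pathway_id)
  rows <- lapply(ids, function(pid) {
    genes <- intersect(unique(pathways$gene_id[pathways$pathway_id == pid]),
                       universe)
    K <- length(genes)
    if (K > N) stop("pathway ", pid, " larger than the universe", call. = FALSE)
    if (K < 1L) return(NULL)
    ov <- intersect(query, genes)
    k <- length(ov)
    # P(X >= k) for X ~ Hypergeom(N, K, n); k = 0 gives p = 1
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    nm <- if ("pathway_name" %in% colnames(pathways)) {
      pathways$pathway_name[match(pid, pathways$pathway_id)]
    } else pid
    data.frame(pathway_id = pid, pathway_name = nm, N = N, K = K, n = n,
               k = k, p = p, genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- bh_adjust(out$p)
  out <- out[order(out$adj_p, out$p), c("pathway_id", "pathway_name", "N",
                                        "K", "n", "k", "p", "adj_p", "genes")]
  rownames(out) <- NULL
  class(out) <- c("ora_result", "data.frame")
  out
}

#' @export
print.ora_result <- function(x, ...) {
  cat(sprintf("ora_result: %d pathways, universe %d genes, query %d genes\n",
              nrow(x), x$N[1L], x$n[1L]))
  print(as.data.frame(x[, setdiff(colnames(x), "genes")]), row.names = FALSE)
  invisible(x)
}
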