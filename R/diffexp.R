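#' Per-assay two-group summary statistics
#'
#' Retains only assays complete (all replicates detected) in both groups;
#' incomplete assays are routed to the exclusivity logic or reported
#' `not_evaluable` by [call_de()]. Variances are pooled over the two groups
#' with `d_g = n_A + n_B - 2` residual degrees of freedom.
#'
#' @param norm A `normalized_cq` matrix.
#' @param det A `detection_table` with group fields.
#' @param group_a,group_b Group labels; each group needs >= 2 samples.
#' @return data.frame (class `group_stats`) with per-assay n, means,
#'   variances, `log2fc` (A minus B), pooled `s2` and `df`.
#' @export
fit_group_stats <- function(norm, det, group_a, group_b) {
  stopifnot(inherits(norm, "normalized_cq"))
  if (is.null(det$complete)) stop("run group_complete() first", call. = FALSE)
  a_cols <- .group_samples(det$annot, group_a)
  b_cols <- .group_samples(det$annot, group_b)
  if (length(a_cols) < 2L || length(b_cols) < 2L) {
    stop("each group needs at least two samples for the statistical test",
         call. = FALSE)
  }
  keep <- det$complete[, group_a] & det$complete[, group_b]
  assays <- rownames(norm)[keep]
  a <- unclass(norm)[keep, a_cols, drop = FALSE]
  b <- unclass(norm)[keep, b_cols, drop = FALSE]
  n_a <- length(a_cols); n_b <- length(b_cols)
  mean_a <- rowMeans(a); mean_b <- rowMeans(b)
  var_a <- apply(a, 1L, stats::var)
  var_b <- apply(b, 1L, stats::var)
  df <- n_a + n_b - 2L
  s2 <- ((n_a - 1) * var_a + (n_b - 1) * var_b) / df
  out <- data.frame(
    assay = assays, n_a = n_a, n_b = n_b,
    mean_a = mean_a, mean_b = mean_b,
    var_a = var_a, var_b = var_b,
    log2fc = mean_a - mean_b, s2 = s2, df = df,
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(out) <- c("group_stats", "data.frame")
  attr(out, "comparison") <- c(group_a, group_b)
  out
}

# Newton inversion of the trigamma function (decreasing, convex on y > 0),
# iterated on 1/psi'(y) which is nearly linear in y.
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi)) return(if (xi > 0) 1e-8 else Inf)
    if (xi <= 0) return(Inf)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (i in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2L)
      y <- y + dif
      if (-dif / y < 1e-10) break
    }
    y
  }, numeric(1))
}

#' Estimate empirical-Bayes variance moderation parameters
#'
#' Models per-assay sample variances as s^2 ~ s0^2 * F(d_g, d0) and
#' recovers the prior degrees of freedom `d0` and prior variance `s0^2` by
#' moment matching on the log scale: E\[log s^2\] and Var\[log s^2\] have
#' closed forms in digamma/trigamma, and the trigamma equation is solved
#' with a Newton inverse. When the empirical spread of log s^2 does not
#' exceed what sampling alone predicts (`Var <= trigamma(d_g/2)`), the
#' prior is effectively infinitely informative: `d0 = Inf` and every
#' moderated variance equals `s0^2`.
#'
#' @param s2 Numeric vector of per-assay pooled variances (>= 10 positive
#'   values required).
#' @param df Residual degrees of freedom `d_g` shared by the variances.
#' @return A `moderation_params` list with elements `d0` and `s0_sq`.
#' @export
estimate_moderation <- function(s2, df) {
  s2 <- s2[is.finite(s2)]
  if (all(s2 == 0)) stop("all variances are zero; cannot moderate", call. = FALSE)
  s2 <- s2[s2 > 0]
  if (length(s2) < 10L) {
    stop("need at least 10 assays with positive variance", call. = FALSE)
  }
  z <- log(s2)
  # z = log s0^2 + log F; E[log F] and Var[log F] from log-chi^2 moments
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1L) - trigamma(df / 2)
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  structure(list(d0 = d0, s0_sq = s0_sq), class = "moderation_params")
}

#' @export
print.moderation_params <- function(x, ...) {
  cat(sprintf("moderation_params: d0 = %s, s0^2 = %.4g\n",
              format(x$d0, digits = 4), x$s0_sq))
  invisible(x)
}

#' Moderated t-statistics for one two-group contrast
#'
#' Shrinks each assay's pooled variance toward the prior,
#' `s~^2 = (d0 s0^2 + d_g s^2) / (d0 + d_g)`, and tests
#' `t = log2FC / sqrt(s~^2 (1/n_A + 1/n_B))` against a Student t
#' distribution with `d0 + d_g` degrees of freedom (two-sided). Setting
#' `d0 = 0` (e.g. `moderation_params_manual(0, 1)`) recovers the classical
#' pooled-variance two-sample t-test exactly.
#'
#' @param stats A `group_stats` data.frame from [fit_group_stats()].
#' @param mod A `moderation_params` object.
#' @return The input data.frame with `s2_post`, `t`, `df_total` and `p`
#'   columns added; assays with zero moderated variance get `NA` t/p and
#'   are flagged `not_evaluable` downstream.
#' @export
moderated_t_contrast <- function(stats, mod) {
  stopifnot(inherits(stats, "group_stats"), inherits(mod, "moderation_params"))
  d0 <- mod$d0; s0 <- mod$s0_sq
  dg <- stats$df
  s2_post <- if (is.infinite(d0)) rep(s0, nrow(stats)) else {
    (d0 * s0 + dg * stats$s2) / (d0 + dg)
  }
  se <- sqrt(s2_post * (1 / stats$n_a + 1 / stats$n_b))
  t <- stats$log2fc / se
  df_total <- d0 + dg
  p <- 2 * stats::pt(-abs(t), df = df_total)
  p[stats$log2fc == 0] <- 1
  bad <- !is.finite(se) | se == 0
  t[bad] <- NA_real_; p[bad] <- NA_real_
  stats$s2_post <- s2_post
  stats$t <- t
  stats$df_total <- df_total
  stats$p <- p
  attr(stats, "moderation") <- mod
  stats
}

#' Manually specified moderation parameters
#'
#' Useful for the `d0 = 0` (classical t) and `d0 = Inf` (fully pooled
#' variance) limit cases.
#'
#' @param d0 Prior degrees of freedom (0, finite, or `Inf`).
#' @param s0_sq Prior variance.
#' @return A `moderation_params` object.
#' @export
moderation_params_manual <- function(d0, s0_sq) {
  stopifnot(d0 >= 0, s0_sq >= 0)
  structure(list(d0 = d0, s0_sq = s0_sq), class = "moderation_params")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment `adj_(i) = min_{j >= i} (m/j) p_(j)` clipped at 1,
#' restoring input order.
#'
#' @param p Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  pp <- p[!is.na(p)]
  if (length(pp) && (any(pp < 0) || any(pp > 1))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Merge statistical and exclusivity calls into final DE status
#'
#' Status rules: `up_A` iff adjusted p <= `alpha` and
#' `log2FC >= log2(fc_threshold)` (the fold-change rule is applied on the
#' log2 scale where the test is run); `up_B` symmetric; exclusivity
#' overrides the statistical call (an exclusive assay is incomplete in one
#' group and never reaches the test); assays neither testable nor
#' exclusive are `not_evaluable`. Every assay of the comparison universe
#' gets exactly one status.
#'
#' @param res Output of [moderated_t_contrast()].
#' @param excl Output of [exclusivity_call()] for the same ordered pair.
#' @param fc_threshold Linear fold-change threshold (> 1).
#' @param alpha Adjusted-p significance level.
#' @return A `contrast_result` data.frame with columns assay, log2fc,
#'   fc_linear, t, df, p, adj_p, status.
#' @export
call_de <- function(res, excl, fc_threshold = 1.5, alpha = 0.05) {
  stopifnot(fc_threshold > 0, alpha > 0)
  adj <- bh_adjust(res$p)
  lfc_min <- log2(fc_threshold)
  assays <- excl$assay
  out <- data.frame(
    assay = assays,
    log2fc = NA_real_, fc_linear = NA_real_,
    t = NA_real_, df = NA_real_, p = NA_real_, adj_p = NA_real_,
    status = "not_evaluable",
    row.names = NULL, stringsAsFactors = FALSE
  )
  idx <- match(res$assay, assays)
  out$log2fc[idx] <- res$log2fc
  out$fc_linear[idx] <- sign(res$log2fc) * 2^abs(res$log2fc)
  out$t[idx] <- res$t
  out$df[idx] <- res$df_total
  out$p[idx] <- res$p
  out$adj_p[idx] <- adj
  tested <- !is.na(out$adj_p)
  out$status[tested] <- "ns"
  out$status[tested & out$adj_p <= alpha & out$log2fc >= lfc_min] <- "up_A"
  out$status[tested & out$adj_p <= alpha & out$log2fc <= -lfc_min] <- "up_B"
  out$status[excl$status == "exclusive_A"] <- "exclusive_A"
  out$status[excl$status == "exclusive_B"] <- "exclusive_B"
  excl_rows <- out$status %in% c("exclusive_A", "exclusive_B")
  out$t[excl_rows] <- NA_real_
  out$p[excl_rows] <- NA_real_
  out$adj_p[excl_rows] <- NA_real_
  class(out) <- c("contrast_result", "data.frame")
  attr(out, "comparison") <- attr(excl, "comparison")
  attr(out, "fc_threshold") <- fc_threshold
  attr(out, "alpha") <- alpha
  attr(out, "moderation") <- attr(res, "moderation")
  out
}

#' One-call two-group differential expression
#'
#' Convenience wrapper chaining [fit_group_stats()],
#' [estimate_moderation()], [moderated_t_contrast()],
#' [exclusivity_call()] and [call_de()] for one ordered comparison.
#'
#' @param norm A `normalized_cq` matrix.
#' @param det A `detection_table` with group fields.
#' @param group_a,group_b Group labels; log2FC is A minus B.
#' @param fc_threshold,alpha DE thresholds (see [call_de()]).
#' @param expressed_cq Exclusivity expression bound in cycles.
#' @param moderation Optional `moderation_params` override (`NULL` =
#'   estimate from the contrast's variances).
#' @param exclusivity_method Passed to [exclusivity_call()].
#' @return A `contrast_result` data.frame.
#' @export
cq_contrast <- function(norm, det, group_a, group_b, fc_threshold = 1.5,
                        alpha = 0.05, expressed_cq = 28, moderation = NULL,
                        exclusivity_method = "replicate") {
  stats <- fit_group_stats(norm, det, group_a, group_b)
  if (is.null(moderation)) {
    moderation <- estimate_moderation(stats$s2, stats$df[1L])
  }
  res <- moderated_t_contrast(stats, moderation)
  excl <- exclusivity_call(det, group_a, group_b, expressed_cq = expressed_cq,
                           method = exclusivity_method)
  call_de(res, excl, fc_threshold = fc_threshold, alpha = alpha)
}

#' @export
print.contrast_result <- function(x, ...) {
  cmp <- attr(x, "comparison")
  cat(sprintf("contrast_result: %s vs %s (%d assays)\n",
              cmp[1L], cmp[2L], nrow(x)))
  print(table(status = x$status))
  invisible(x)
}

#' @export
summary.contrast_result <- function(object, ...) {
  counts <- table(factor(object$status,
                         levels = c("up_A", "up_B", "exclusive_A",
                                    "exclusive_B", "ns", "not_evaluable")))
  structure(list(comparison = attr(object, "comparison"),
                 counts = counts,
                 n_tested = sum(!is.na(object$adj_p))),
            class = "summary.contrast_result")
}

#' @export
print.summary.contrast_result <- function(x, ...) {
  cat(sprintf("%s vs %s: %d tested\n", x$comparison[1L], x$comparison[2L],
              x$n_tested))
  print(x$counts)
  invisible(x)
}

#' Volcano plot of a contrast
#'
#' @param x A `contrast_result`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.contrast_result <- function(x, ...) {
  tested <- !is.na(x$adj_p)
  sig <- tested & x$status %in% c("up_A", "up_B")
  graphics::plot(x$log2fc[tested], -log10(x$p[tested]),
                 pch = 20, col = ifelse(sig[tested], "red3", "grey50"),
                 xlab = "log2 fold change", ylab = "-log10 p", ...)
  graphics::abline(v = c(-1, 1) * log2(attr(x, "fc_threshold")), lty = 2)
  invisible(x)
}
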