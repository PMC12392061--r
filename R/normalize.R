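#' Global-normalizer assay set
#'
#' The assays detected in every sample of the dataset. Computing the set
#' once on the full dataset (rather than per comparison) keeps all samples
#' on one common scale.
#'
#' @param det A `detection_table`.
#' @return Character vector of assay ids; errors if empty.
#' @export
normalizer_set <- function(det) {
  set <- detected_in_all(det)
  if (!length(set)) {
    stop("no consistently detected assays; cannot normalize", call. = FALSE)
  }
  message(sprintf("normalizer set: %d assays detected in all %d samples",
                  length(set), ncol(det$detected)))
  set
}

#' Global-mean normalization of Cq values
#'
#' For each sample j, the normalizer mean `m_j` is the arithmetic mean of
#' the Cq values of the normalizer assays in that sample (Cq is already a
#' log2-scale quantity, so the arithmetic mean of Cq is the geometric mean
#' of linear abundances). Relative expression is
#' `expr(g, j) = m_j - Cq(g, j)` for detected cells: one cycle equals one
#' log2 unit, and the sign convention makes larger expr mean higher
#' abundance, so a two-group log2 fold change is simply
#' `mean(expr_A) - mean(expr_B)`. Non-detected cells stay missing.
#'
#' @param cq A [cq_matrix].
#' @param det The matching `detection_table`.
#' @param norm_set Assay ids to normalize against; every one must be
#'   detected in every sample. Defaults to [normalizer_set()].
#' @return A `normalized_cq` matrix of log2 relative expression (`NA` where
#'   non-detected) with attributes `normalizer_set` and `normalizer_mean`.
#' @export
global_mean_normalize <- function(cq, det, norm_set = NULL) {
  stopifnot(inherits(cq, "cq_matrix"), inherits(det, "detection_table"))
  if (is.null(norm_set)) norm_set <- normalizer_set(det)
  if (!length(norm_set)) stop("empty normalizer set", call. = FALSE)
  missing_assay <- setdiff(norm_set, rownames(cq))
  if (length(missing_assay)) {
    stop("normalizer assay(s) absent from matrix: ",
         paste(missing_assay, collapse = ", "), call. = FALSE)
  }
  ok <- rowSums(det$detected[norm_set, , drop = FALSE]) == ncol(cq)
  if (!all(ok)) {
    stop("normalizer assay(s) not detected in every sample: ",
         paste(norm_set[!ok], collapse = ", "), call. = FALSE)
  }
  m <- colMeans(unclass(cq)[norm_set, , drop = FALSE])
  expr <- sweep(-unclass(cq), 2L, m, `+`)   # m_j - Cq
  expr[!det$detected] <- NA_real_
  structure(expr, normalizer_set = norm_set, normalizer_mean = m,
            class = c("normalized_cq", "matrix", "array"))
}

#' @export
print.normalized_cq <- function(x, ...) {
  cat(sprintf("normalized_cq: %d assays x %d samples, normalizer set of %d assays\n",
              nrow(x), ncol(x), length(attr(x, "normalizer_set"))))
  invisible(x)
}
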