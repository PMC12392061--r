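#' Detection calling on a Cq matrix
#'
#' A reaction is called detected iff its Cq is numeric and falls inside the
#' reliable amplification window `lower_cq <= Cq <= upper_cq` (defaults 15
#' and 30 cycles, both inclusive). Low-abundance reactions above the upper
#' bound are kept as numeric Cq in the matrix but flagged non-detected, as
#' are sentinel ("Undetermined") cells. Using the inclusive upper bound
#' makes "Cq = 30 is the detection cut-off" and "Cq > 30 is non-expressed"
#' consistent.
#'
#' @param cq A [cq_matrix].
#' @param lower_cq,upper_cq Detection window in cycles,
#'   `0 < lower_cq < upper_cq <= 40`.
#' @return A `detection_table`: list with the logical `detected` matrix, the
#'   source `cq` matrix and the window bounds. Group-level fields are added
#'   by [group_complete()].
#' @export
detection_call <- function(cq, lower_cq = 15, upper_cq = 30) {
  stopifnot(inherits(cq, "cq_matrix"))
  if (!(lower_cq > 0 && lower_cq < upper_cq && upper_cq <= 40)) {
    stop("detection window must satisfy 0 < lower_cq < upper_cq <= 40",
         call. = FALSE)
  }
  det <- !is.na(cq) & unclass(cq) >= lower_cq & unclass(cq) <= upper_cq
  dimnames(det) <- dimnames(cq)
  structure(
    list(detected = det, cq = cq, lower_cq = lower_cq, upper_cq = upper_cq),
    class = "detection_table"
  )
}

#' @export
print.detection_table <- function(x, ...) {
  cat(sprintf("detection_table: %d assays x %d samples, window [%g, %g] cycles\n",
              nrow(x$detected), ncol(x$detected), x$lower_cq, x$upper_cq))
  cat(sprintf("  detected cells: %d / %d (%.1f%%)\n", sum(x$detected),
              length(x$detected), 100 * mean(x$detected)))
  if (!is.null(x$groups)) {
    cat("  groups:", paste(x$groups$group, collapse = ", "), "\n")
  }
  invisible(x)
}

.group_samples <- function(annot, group) {
  s <- annot$sample_id[annot$group == group]
  if (!length(s)) stop("no samples in group ", group, call. = FALSE)
  s
}

#' Fill group-level completeness fields of a detection table
#'
#' Groups are the (cell_type, compartment) combinations of the annotation.
#' An assay is complete in a group iff every replicate is detected; assays
#' with one or more failed reads in a group carry no group mean there, so
#' downstream means always rest on the full set of biological replicates.
#'
#' @param det A `detection_table` from [detection_call()].
#' @param annot Sample annotation data.frame (see [read_sample_sheet()]).
#' @return The `detection_table` with `groups` (data.frame), `complete`
#'   (assays x groups logical), `n_detected` (integer) and `group_mean`
#'   (mean Cq, `NA` where incomplete) filled in.
#' @export
group_complete <- function(det, annot) {
  stopifnot(inherits(det, "detection_table"))
  annot <- annot[annot$sample_id %in% colnames(det$detected), , drop = FALSE]
  if (!nrow(annot)) stop("no annotated samples overlap the Cq matrix", call. = FALSE)
  groups <- unique(annot[, c("group", "cell_type", "compartment")])
  groups$n <- vapply(groups$group,
                     function(g) sum(annot$group == g), integer(1))
  if (any(groups$n < 1L)) stop("each group needs at least one sample", call. = FALSE)
  assays <- rownames(det$detected)
  complete <- matrix(FALSE, length(assays), nrow(groups),
                     dimnames = list(assays, groups$group))
  n_det <- matrix(0L, length(assays), nrow(groups),
                  dimnames = list(assays, groups$group))
  gmean <- matrix(NA_real_, length(assays), nrow(groups),
                  dimnames = list(assays, groups$group))
  for (g in groups$group) {
    cols <- .group_samples(annot, g)
    dsub <- det$detected[, cols, drop = FALSE]
    n_det[, g] <- rowSums(dsub)
    complete[, g] <- n_det[, g] == length(cols)
    csub <- unclass(det$cq)[, cols, drop = FALSE]
    m <- rowMeans(csub)
    gmean[complete[, g], g] <- m[complete[, g]]
  }
  det$groups <- groups
  det$annot <- annot
  det$complete <- complete
  det$n_detected <- n_det
  det$group_mean <- gmean
  det
}

#' Expressed/non-expressed exclusivity calls between two groups
#'
#' An assay is exclusive to group A when, in the comparison A vs B, it is
#' robustly expressed in A and absent from B: by the default per-replicate
#' rule every A replicate must be detected with `Cq < expressed_cq`
#' (default 28 cycles) and every B replicate must be non-detected with
#' `Cq > upper_cq` or a sentinel. `method = "group_mean"` instead applies
#' the same thresholds to the group mean Cq (A complete with mean < 28; B
#' with no detected replicate and mean, over numeric values, > upper bound
#' or all sentinel). Assays complete in both groups are `both_evaluable`
#' (they go to the statistical test); everything else is `neither`.
#'
#' @param det A `detection_table` with group fields ([group_complete()]).
#' @param group_a,group_b Group labels (e.g. `"PSC_EV"`, `"PSC_IN"`).
#' @param expressed_cq Expression bound in cycles, `< upper_cq`.
#' @param method `"replicate"` (default, stricter) or `"group_mean"`.
#' @return data.frame with columns `assay` and `status` in
#'   {exclusive_A, exclusive_B, both_evaluable, neither}; the evaluation
#'   `method` is recorded as an attribute.
#' @export
exclusivity_call <- function(det, group_a, group_b, expressed_cq = 28,
                             method = c("replicate", "group_mean")) {
  stopifnot(inherits(det, "detection_table"))
  if (is.null(det$complete)) stop("run group_complete() first", call. = FALSE)
  method <- match.arg(method)
  if (!(expressed_cq < det$upper_cq)) {
    stop("expressed_cq must be below the detection upper bound", call. = FALSE)
  }
  for (g in c(group_a, group_b)) {
    if (!g %in% det$groups$group) stop("unknown group: ", g, call. = FALSE)
  }
  cq <- unclass(det$cq)
  a_cols <- .group_samples(det$annot, group_a)
  b_cols <- .group_samples(det$annot, group_b)

  expressed_in <- function(cols) {
    sub <- cq[, cols, drop = FALSE]
    dsub <- det$detected[, cols, drop = FALSE]
    if (method == "replicate") {
      rowSums(dsub & !is.na(sub) & sub < expressed_cq) == length(cols)
    } else {
      m <- rowMeans(sub)
      rowSums(dsub) == length(cols) & !is.na(m) & m < expressed_cq
    }
  }
  absent_in <- function(cols) {
    sub <- cq[, cols, drop = FALSE]
    dsub <- det$detected[, cols, drop = FALSE]
    nondet <- is.na(sub) | sub > det$upper_cq
    if (method == "replicate") {
      rowSums(nondet) == length(cols)
    } else {
      none_det <- rowSums(dsub) == 0L
      m_num <- rowMeans(sub, na.rm = TRUE)   # NaN when all sentinel
      none_det & (is.nan(m_num) | m_num > det$upper_cq)
    }
  }

  excl_a <- expressed_in(a_cols) & absent_in(b_cols)
  excl_b <- expressed_in(b_cols) & absent_in(a_cols)
  both <- det$complete[, group_a] & det$complete[, group_b]
  status <- rep("neither", nrow(cq))
  status[both] <- "both_evaluable"
  status[excl_a] <- "exclusive_A"
  status[excl_b] <- "exclusive_B"
  out <- data.frame(assay = rownames(cq), status = status,
                    stringsAsFactors = FALSE)
  attr(out, "comparison") <- c(group_a, group_b)
  attr(out, "expressed_cq") <- expressed_cq
  attr(out, "method") <- method
  out
}

#' Assays detected in every sample
#'
#' @param det A `detection_table`.
#' @return Character vector of assay ids detected in all samples of the
#'   dataset (the candidate global-normalizer set).
#' @export
detected_in_all <- function(det) {
  stopifnot(inherits(det, "detection_table"))
  rownames(det$detected)[rowSums(det$detected) == ncol(det$detected)]
}
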