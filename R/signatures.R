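.CATALOG_COMPARISONS <- list(
  c("PSC_IN", "NSC_IN"), c("PSC_IN", "FPP_IN"), c("NSC_IN", "FPP_IN"),
  c("PSC_EV", "NSC_EV"), c("PSC_EV", "FPP_EV"), c("NSC_EV", "FPP_EV"),
  c("PSC_EV", "PSC_IN"), c("NSC_EV", "NSC_IN"), c("FPP_EV", "FPP_IN")
)

#' Run all nine pairwise comparisons of the three-population, two-compartment design
#'
#' Three intracellular cell-type pairs, three EV cell-type pairs, and the
#' three within-cell-type EV-vs-IN contrasts (EV listed first, so `up_A`
#' means EV-enriched). Each comparison runs the full
#' detection-exclusivity + moderated-t pipeline independently, mirroring
#' the per-comparison replicate-completeness rule.
#'
#' @param norm A `normalized_cq` matrix.
#' @param det A `detection_table` with group fields.
#' @param fc_threshold,alpha,expressed_cq,moderation,exclusivity_method
#'   Passed to [cq_contrast()].
#' @return A `comparison_catalog`: named list of `contrast_result` objects
#'   plus a `counts` data.frame of per-comparison status tallies.
#' @export
build_catalog <- function(norm, det, fc_threshold = 1.5, alpha = 0.05,
                          expressed_cq = 28, moderation = NULL,
                          exclusivity_method = "replicate") {
  present <- det$groups$group
  comps <- Filter(function(p) all(p %in% present), .CATALOG_COMPARISONS)
  if (!length(comps)) stop("no catalog comparison has both groups present", call. = FALSE)
  contrasts <- lapply(comps, function(p) {
    cq_contrast(norm, det, p[1L], p[2L], fc_threshold = fc_threshold,
                alpha = alpha, expressed_cq = expressed_cq,
                moderation = moderation,
                exclusivity_method = exclusivity_method)
  })
  names(contrasts) <- vapply(comps, function(p) paste(p, collapse = "_vs_"),
                             character(1))
  counts <- do.call(rbind, lapply(names(contrasts), function(nm) {
    s <- summary(contrasts[[nm]])$counts
    data.frame(comparison = nm, up_A = s[["up_A"]], up_B = s[["up_B"]],
               exclusive_A = s[["exclusive_A"]], exclusive_B = s[["exclusive_B"]],
               ns = s[["ns"]], not_evaluable = s[["not_evaluable"]],
               stringsAsFactors = FALSE)
  }))
  structure(list(contrasts = contrasts, counts = counts),
            class = "comparison_catalog")
}

#' @export
print.comparison_catalog <- function(x, ...) {
  cat(sprintf("comparison_catalog: %d comparisons\n", length(x$contrasts)))
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Two-set Venn partition
#'
#' @param set_a,set_b Character vectors.
#' @return Named integer vector `(a_only, b_only, both)`; the three parts
#'   are disjoint and sum to `|A union B|`.
#' @export
venn_partition <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  both <- intersect(a, b)
  c(a_only = length(setdiff(a, b)), b_only = length(setdiff(b, a)),
    both = length(both))
}

#' Intersect miRNA name lists after canonicalization
#'
#' Published miRNA lists mix spellings ("hsa-miR-137" vs "miR-137");
#' names are canonicalized with [canonicalize_mirna()] before the exact
#' set intersection. Returned members use the spelling of `list1`.
#'
#' @param list1,list2 Character vectors of miRNA names.
#' @return Common members (spelling of `list1`).
#' @export
intersect_named_sets <- function(list1, list2) {
  c1 <- canonicalize_mirna(list1)
  c2 <- canonicalize_mirna(list2)
  unique(list1[c1 %in% c2])
}

#' Classify EV-enrichment signatures across cell populations
#'
#' From the three within-cell-type EV-vs-IN contrasts: per type,
#' `EV_enriched` are the statistically EV-up assays and `EV_exclusive` the
#' categorically EV-only assays; an assay counts as EV-loaded in a type if
#' it is either. The universal EV signature is the assays EV-loaded in all
#' three types (both evidence kinds count, since a strongly loaded assay
#' can drop below detection intracellularly and become exclusive rather
#' than testable). Population-specific sets are assays EV-loaded in
#' exactly one type. The neural-shared set is, by default
#' (`neural_shared_def = "ev_vs_in"`), assays EV-loaded in both neural
#' types (NSC and FPP) but not in PSC; the alternative
#' `"vs_psc_ev"` definition instead takes assays up in both NSC-EV and
#' FPP-EV relative to PSC-EV (requires the EV cell-type contrasts).
#'
#' @param catalog A `comparison_catalog` containing the three EV-vs-IN
#'   comparisons (and, for `"vs_psc_ev"`, the PSC-EV contrasts).
#' @param neural_shared_def `"ev_vs_in"` (default) or `"vs_psc_ev"`.
#' @return A `signature_sets` list: `EV_enriched` and `EV_exclusive`
#'   (per-type lists), `specific` (per-type lists), `shared_neural_EV`,
#'   `universal_EV`; the definition used is recorded as an attribute.
#' @export
classify_ev_signatures <- function(catalog,
                                   neural_shared_def = c("ev_vs_in", "vs_psc_ev")) {
  stopifnot(inherits(catalog, "comparison_catalog"))
  neural_shared_def <- match.arg(neural_shared_def)
  types <- c("PSC", "NSC", "FPP")
  need <- paste0(types, "_EV_vs_", types, "_IN")
  miss <- setdiff(need, names(catalog$contrasts))
  if (length(miss)) {
    stop("catalog is missing EV-vs-IN comparison(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  enriched <- exclusive <- loaded <- list()
  for (i in seq_along(types)) {
    cr <- catalog$contrasts[[need[i]]]
    enriched[[types[i]]] <- cr$assay[cr$status == "up_A"]
    exclusive[[types[i]]] <- cr$assay[cr$status == "exclusive_A"]
    loaded[[types[i]]] <- union(enriched[[types[i]]], exclusive[[types[i]]])
  }
  universal <- Reduce(intersect, loaded)
  n_types <- table(unlist(loaded))
  specific <- lapply(types, function(ty) {
    s <- loaded[[ty]]
    s[n_types[s] == 1L]
  })
  names(specific) <- types
  shared_neural <- if (neural_shared_def == "ev_vs_in") {
    setdiff(intersect(loaded$NSC, loaded$FPP), loaded$PSC)
  } else {
    nsc <- catalog$contrasts[["PSC_EV_vs_NSC_EV"]]
    fpp <- catalog$contrasts[["PSC_EV_vs_FPP_EV"]]
    if (is.null(nsc) || is.null(fpp)) {
      stop("vs_psc_ev definition needs the PSC_EV cell-type contrasts",
           call. = FALSE)
    }
    up_in <- function(cr) cr$assay[cr$status %in% c("up_B", "exclusive_B")]
    intersect(up_in(nsc), up_in(fpp))
  }
  structure(list(EV_enriched = enriched, EV_exclusive = exclusive,
                 specific = specific, shared_neural_EV = shared_neural,
                 universal_EV = universal),
            neural_shared_def = neural_shared_def,
            class = "signature_sets")
}

#' @export
print.signature_sets <- function(x, ...) {
  cat("signature_sets (neural-shared definition:",
      attr(x, "neural_shared_def"), ")\n")
  for (ty in names(x$EV_enriched)) {
    cat(sprintf("  %s: %d EV-enriched, %d EV-exclusive, %d specific\n", ty,
                length(x$EV_enriched[[ty]]), length(x$EV_exclusive[[ty]]),
                length(x$specific[[ty]])))
  }
  cat(sprintf("  shared neural EV: %d\n", length(x$shared_neural_EV)))
  cat(sprintf("  universal EV: %d (%s)\n", length(x$universal_EV),
              paste(x$universal_EV, collapse = ", ")))
  invisible(x)
}
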