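# Shared fixtures and independent oracles for the test suite.

# Build a fully detected dataset (detection table + normalized matrix) from a
# log2 expression matrix: Cq = 26 - expr, so everything lies inside the
# detection window as long as |expr| < 10.
make_dataset <- function(expr, groups, donors = NULL) {
  stopifnot(is.matrix(expr))
  n_s <- ncol(expr)
  if (is.null(rownames(expr))) rownames(expr) <- sprintf("a%04d", seq_len(nrow(expr)))
  if (is.null(donors)) donors <- paste0("C", ave(seq_len(n_s), groups, FUN = seq_along))
  parts <- strsplit(groups, "_", fixed = TRUE)
  annot <- data.frame(
    sample_id = paste(groups, donors, sep = "_"),
    donor = donors,
    cell_type = vapply(parts, `[`, "", 1L),
    compartment = vapply(parts, `[`, "", 2L),
    stringsAsFactors = FALSE
  )
  annot <- validate_sample_sheet(annot)
  colnames(expr) <- annot$sample_id
  cq <- cq_matrix(26 - expr)
  det <- group_complete(detection_call(cq), annot)
  norm <- global_mean_normalize(cq, det, rownames(expr))
  list(cq = cq, annot = annot, det = det, norm = norm)
}

# Classical pooled-variance two-sample t-test, textbook formula.
pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  s2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(s2 * (1 / na + 1 / nb))
  list(t = t, df = na + nb - 2, p = 2 * pt(-abs(t), na + nb - 2))
}

# Welch t-test, textbook formula.
welch_t_oracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  2 * pt(-abs(t), df)
}

# Brute-force hypergeometric upper tail P(X >= k).
hyper_tail_oracle <- function(k, N, K, n) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Load the bundled worked-example fixtures.
load_de_sets <- function() {
  read_mirna_sets(system.file("extdata", "tlda_de_sets.tsv", package = "evmir"))
}

load_ev_candidate_run <- function() {
  cq <- read_cq_matrix(system.file("extdata", "ev_candidate_cq_synthetic.tsv",
                                   package = "evmir"))
  annot <- sample_sheet_from_ids(colnames(cq))
  det <- group_complete(detection_call(cq), annot)
  norm <- global_mean_normalize(cq, det, suppressMessages(normalizer_set(det)))
  catalog <- build_catalog(norm, det, moderation = moderation_params_manual(0, 1))
  list(cq = cq, annot = annot, det = det, norm = norm, catalog = catalog,
       signatures = classify_ev_signatures(catalog))
}
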