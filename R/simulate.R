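#' Simulation configuration for synthetic Cq array data
#'
#' Defaults emulate a 754-assay TLDA profiling run of three cell
#' populations (PSC, NSC, FPP) in two compartments (intracellular and EV)
#' with three donors as biological replicates. Noise is Gaussian on the
#' Cq scale (Cq is log2-linear in template abundance); non-detection is
#' abundance-dependent, rising logistically above the detection boundary,
#' which concentrates dropout near Cq 30 as observed on real cards. A
#' minority of assays is expressed at all (`p_expressed`), which yields
#' roughly a quarter of reactions detected per compartment and about a
#' tenth of assays detected in every sample.
#'
#' @param n_assays Number of assays on the card.
#' @param n_donors Biological replicates (one sample per donor per group).
#' @param seed Mandatory integer seed; identical config + seed is bitwise
#'   reproducible.
#' @param p_expressed Fraction of assays expressed intracellularly.
#' @param baseline_mean,baseline_sd Baseline Cq of expressed assays.
#' @param ev_baseline_offset Global Cq offset of the EV compartment
#'   (cycles; positive = less template recovered from vesicles, so EV
#'   detection runs slightly below intracellular detection).
#' @param unexpressed_mean,unexpressed_sd Latent Cq of unexpressed assays
#'   (mostly beyond the instrument's reliable range).
#' @param frac_de Fraction of expressed assays with a planted cell-type
#'   effect.
#' @param de_min,de_max Magnitude range of planted |log2FC| (cycles).
#' @param frac_ev_enriched Fraction of expressed assays with selective EV
#'   loading (lower Cq in EV).
#' @param ev_shift_min,ev_shift_max EV-loading shift range (cycles).
#' @param frac_ev_exclusive Fraction of all assays detectable only in EVs.
#' @param ev_exclusive_mean,ev_exclusive_sd EV Cq of EV-exclusive assays.
#' @param noise_sd Replicate technical/biological noise sd (cycles).
#' @param donor_sd Donor random-intercept sd per assay (cycles).
#' @param plate_sd Per-sample plate offset sd (cycles).
#' @param dropout_mid,dropout_scale Logistic dropout midpoint and scale:
#'   P(non-detection) = plogis((Cq - mid)/scale).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_assays = 754, n_donors = 3, seed,
                       p_expressed = 0.31,
                       baseline_mean = 26.5, baseline_sd = 3,
                       ev_baseline_offset = 0.6,
                       unexpressed_mean = 36, unexpressed_sd = 2,
                       frac_de = 0.25, de_min = 0.6, de_max = 2.5,
                       frac_ev_enriched = 0.10,
                       ev_shift_min = 1, ev_shift_max = 3,
                       frac_ev_exclusive = 0.02,
                       ev_exclusive_mean = 24.5, ev_exclusive_sd = 0.8,
                       noise_sd = 0.35, donor_sd = 0.2, plate_sd = 0.3,
                       dropout_mid = 29, dropout_scale = 0.8) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility", call. = FALSE)
  cfg <- list(n_assays = n_assays, n_donors = n_donors, seed = as.integer(seed),
              p_expressed = p_expressed, baseline_mean = baseline_mean,
              baseline_sd = baseline_sd, ev_baseline_offset = ev_baseline_offset,
              unexpressed_mean = unexpressed_mean,
              unexpressed_sd = unexpressed_sd, frac_de = frac_de,
              de_min = de_min, de_max = de_max,
              frac_ev_enriched = frac_ev_enriched,
              ev_shift_min = ev_shift_min, ev_shift_max = ev_shift_max,
              frac_ev_exclusive = frac_ev_exclusive,
              ev_exclusive_mean = ev_exclusive_mean,
              ev_exclusive_sd = ev_exclusive_sd,
              noise_sd = noise_sd, donor_sd = donor_sd, plate_sd = plate_sd,
              dropout_mid = dropout_mid, dropout_scale = dropout_scale)
  fracs <- c(cfg$p_expressed, cfg$frac_de, cfg$frac_ev_enriched,
             cfg$frac_ev_exclusive)
  if (any(fracs < 0 | fracs > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (n_assays < 1L || n_donors < 1L) {
    stop("n_assays and n_donors must be positive", call. = FALSE)
  }
  if (any(c(noise_sd, donor_sd, plate_sd, baseline_sd, dropout_scale) < 0)) {
    stop("standard deviations and scales must be non-negative", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic Cq dataset with ground truth
#'
#' Each assay gets a latent mean Cq per (cell type, compartment) group:
#' expressed assays start from a common baseline, a planted subset carries
#' a cell-type effect (applied in both compartments, mirroring the
#' observed correlation between cellular and EV miRNA levels), a subset is
#' selectively EV-loaded (EV Cq shifted down), and a small class is
#' EV-exclusive (intracellularly silent, well expressed in EVs).
#' Observed Cq adds a per-(assay, donor) random intercept, a per-sample
#' plate offset, and replicate noise; cells then drop out with logistic
#' probability in the observed Cq, and anything beyond the 40-cycle
#' ceiling is non-detected. Non-detected cells carry the sentinel.
#'
#' @param cfg A [sim_config].
#' @return A `cq_simulation` list: `cq` ([cq_matrix]), `annot` (sample
#'   sheet data.frame), `truth` (per-assay data.frame with expressed flag,
#'   EV class and shift, planted cell-type effect, plus the latent
#'   `mu` matrix of group mean Cq), and `cfg`.
#' @export
generate_cq_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_assays
  assays <- sprintf("sim-mir-%04d", seq_len(n))
  donors <- paste0("C", seq_len(cfg$n_donors))
  groups <- as.vector(outer(.CELL_TYPES, .COMPARTMENTS, paste, sep = "_"))

  ev_exclusive <- stats::runif(n) < cfg$frac_ev_exclusive
  expressed <- !ev_exclusive & stats::runif(n) < cfg$p_expressed
  baseline <- ifelse(expressed,
                     stats::rnorm(n, cfg$baseline_mean, cfg$baseline_sd),
                     stats::rnorm(n, cfg$unexpressed_mean, cfg$unexpressed_sd))

  de_assay <- expressed & stats::runif(n) < cfg$frac_de
  de_type <- ifelse(de_assay, sample(.CELL_TYPES, n, replace = TRUE), NA)
  de_shift <- ifelse(de_assay,
                     sample(c(-1, 1), n, replace = TRUE) *
                       stats::runif(n, cfg$de_min, cfg$de_max), 0)

  ev_enriched <- expressed & stats::runif(n) < cfg$frac_ev_enriched
  ev_shift <- ifelse(ev_enriched,
                     stats::runif(n, cfg$ev_shift_min, cfg$ev_shift_max), 0)
  ev_class <- ifelse(ev_exclusive, "exclusive",
                     ifelse(ev_enriched, "enriched", "none"))

  mu <- matrix(NA_real_, n, length(groups), dimnames = list(assays, groups))
  ev_excl_cq <- stats::rnorm(n, cfg$ev_exclusive_mean, cfg$ev_exclusive_sd)
  for (ct in .CELL_TYPES) {
    m_in <- baseline - ifelse(de_assay & de_type == ct, de_shift, 0)
    m_ev <- m_in + cfg$ev_baseline_offset - ev_shift
    m_ev[ev_exclusive] <- ev_excl_cq[ev_exclusive]
    mu[, paste0(ct, "_IN")] <- m_in
    mu[, paste0(ct, "_EV")] <- m_ev
  }

  annot <- expand.grid(donor = donors, cell_type = .CELL_TYPES,
                       compartment = .COMPARTMENTS,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  annot$group <- paste(annot$cell_type, annot$compartment, sep = "_")
  annot$sample_id <- paste(annot$group, annot$donor, sep = "_")
  annot <- annot[, c("sample_id", "donor", "cell_type", "compartment", "group")]

  donor_eff <- matrix(stats::rnorm(n * cfg$n_donors, 0, cfg$donor_sd),
                      n, cfg$n_donors, dimnames = list(assays, donors))
  plate <- stats::rnorm(nrow(annot), 0, cfg$plate_sd)

  vals <- matrix(NA_real_, n, nrow(annot),
                 dimnames = list(assays, annot$sample_id))
  for (j in seq_len(nrow(annot))) {
    cqj <- mu[, annot$group[j]] + donor_eff[, annot$donor[j]] + plate[j] +
      stats::rnorm(n, 0, cfg$noise_sd)
    drop <- stats::runif(n) < stats::plogis((cqj - cfg$dropout_mid) /
                                              cfg$dropout_scale)
    cqj[drop | cqj > 40 | cqj <= 0] <- NA_real_
    vals[, j] <- round(cqj, 3)
  }

  truth <- data.frame(assay = assays, expressed = expressed,
                      baseline_cq = baseline, ev_class = ev_class,
                      ev_shift = ev_shift,
                      de_cell_type = de_type, de_log2fc = de_shift,
                      stringsAsFactors = FALSE)
  structure(list(cq = cq_matrix(vals), annot = annot,
                 truth = list(assays = truth, mu = mu), cfg = cfg),
            class = "cq_simulation")
}

#' @export
print.cq_simulation <- function(x, ...) {
  cat(sprintf("cq_simulation: %d assays x %d samples (seed %d)\n",
              nrow(x$cq), ncol(x$cq), x$cfg$seed))
  cat(sprintf("  expressed: %d; EV-enriched: %d; EV-exclusive: %d; cell-type DE: %d\n",
              sum(x$truth$assays$expressed),
              sum(x$truth$assays$ev_class == "enriched"),
              sum(x$truth$assays$ev_class == "exclusive"),
              sum(x$truth$assays$de_log2fc != 0)))
  invisible(x)
}

#' True group log2 fold change of a simulated dataset
#'
#' Latent log2FC (A minus B, higher = more abundant) implied by the
#' simulator's group mean Cq values.
#'
#' @param sim A `cq_simulation`.
#' @param group_a,group_b Group labels.
#' @return Named numeric vector per assay: `mu_B - mu_A` in cycles.
#' @export
true_log2fc <- function(sim, group_a, group_b) {
  stopifnot(inherits(sim, "cq_simulation"))
  sim$truth$mu[, group_b] - sim$truth$mu[, group_a]
}

#' Generate a synthetic target-validation Ct table
#'
#' Emulates an mRNA validation experiment: reference genes ACTB and GUSB
#' with stable Ct across samples, target genes with a planted linear fold
#' change in the affected group (Ct shifted by `-log2(true_fc)` there,
#' since one cycle is one log2 unit).
#'
#' @param genes Character vector of target gene names.
#' @param true_fc Per-gene linear fold change (> 0) of `affected` relative
#'   to the other group; recycled to `length(genes)`.
#' @param groups Two group labels.
#' @param affected Group carrying the effect.
#' @param n_per_group Samples per group.
#' @param ct_noise_sd Target-gene Ct noise sd (cycles).
#' @param ref_noise_sd Reference-gene Ct noise sd (cycles).
#' @param target_baseline_ct Baseline target Ct.
#' @param seed Mandatory integer seed.
#' @return List with `ct` (long data.frame gene/sample/ct), `groups`
#'   (named vector sample -> group) and `true_fc` (named per gene).
#' @export
generate_validation_ct <- function(genes, true_fc, groups = c("FPP", "NSC"),
                                   affected = groups[1L], n_per_group = 3,
                                   ct_noise_sd = 0.2, ref_noise_sd = 0.15,
                                   target_baseline_ct = 25, seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility", call. = FALSE)
  if (any(true_fc <= 0)) stop("true_fc must be positive", call. = FALSE)
  stopifnot(length(groups) == 2L, affected %in% groups)
  true_fc <- rep_len(true_fc, length(genes))
  names(true_fc) <- genes
  set.seed(as.integer(seed))
  samples <- as.vector(vapply(groups, function(g) {
    paste0(g, "_", seq_len(n_per_group))
  }, character(n_per_group)))
  grp <- stats::setNames(rep(groups, each = n_per_group), samples)
  ref_base <- c(ACTB = 20, GUSB = 22)
  rows <- list()
  for (ref in names(ref_base)) {
    rows[[ref]] <- data.frame(
      gene = ref, sample = samples,
      ct = ref_base[[ref]] + stats::rnorm(length(samples), 0, ref_noise_sd),
      stringsAsFactors = FALSE)
  }
  for (g in genes) {
    shift <- ifelse(grp == affected, -log2(true_fc[[g]]), 0)
    rows[[g]] <- data.frame(
      gene = g, sample = samples,
      ct = target_baseline_ct + shift +
        stats::rnorm(length(samples), 0, ct_noise_sd),
      stringsAsFactors = FALSE)
  }
  ct <- do.call(rbind, rows)
  rownames(ct) <- NULL
  list(ct = ct, groups = grp, true_fc = true_fc)
}
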