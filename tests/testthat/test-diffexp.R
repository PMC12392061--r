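test_that("group stats reproduce hand arithmetic and routing rules", {
  expr <- rbind(
    hand = c(1, 2, 3, 0, 1, 2),
    same = c(2, 2, 2, 2, 2, 2),
    routed = c(1, 1, 1, 1, 1, 1)
  )
  ds <- make_dataset(expr, rep(c("NSC_IN", "FPP_IN"), each = 3))
  # knock one FPP replicate of "routed" out of detection
  vals <- unclass(ds$cq); vals["routed", 4] <- NA
  cq <- cq_matrix(vals)
  det <- group_complete(detection_call(cq), ds$annot)
  norm <- global_mean_normalize(cq, det, c("hand", "same"))
  st <- fit_group_stats(norm, det, "NSC_IN", "FPP_IN")
  expect_false("routed" %in% st$assay)
  # normalization shifts both groups by sample means; use an unnormalized view
  st_raw <- fit_group_stats(
    structure(expr, class = c("normalized_cq", "matrix", "array"),
              dimnames = list(rownames(expr), ds$annot$sample_id)),
    det, "NSC_IN", "FPP_IN")
  h <- st_raw[st_raw$assay == "hand", ]
  expect_equal(h$mean_a, 2); expect_equal(h$mean_b, 1)
  expect_equal(h$log2fc, 1); expect_equal(h$df, 4)
  expect_equal(h$s2, 1)   # pooled variance of {1,2,3} and {0,1,2}
  expect_equal(st_raw[st_raw$assay == "same", "log2fc"], 0)
})

test_that("moderation recovers simulated hyperparameters", {
  set.seed(42)
  d0 <- 4; s0 <- 0.05; dg <- 4
  s2 <- s0 * (rchisq(5000, dg) / dg) / (rchisq(5000, d0) / d0)
  mp <- estimate_moderation(s2, dg)
  expect_lt(abs(mp$d0 - d0) / d0, 0.25)
  expect_lt(abs(mp$s0_sq - s0) / s0, 0.10)
})

test_that("moderation matches the reference empirical-Bayes implementation", {
  skip_if_not_installed("limma")
  set.seed(43)
  s2 <- 0.1 * (rchisq(800, 4) / 4) / (rchisq(800, 6) / 6)
  mp <- estimate_moderation(s2, 4)
  fd <- limma::fitFDist(s2, df1 = 4)
  expect_equal(mp$d0, fd$df2, tolerance = 1e-8)
  expect_equal(mp$s0_sq, fd$scale, tolerance = 1e-8)
})

test_that("identical variances trigger the infinite-prior branch", {
  mp <- estimate_moderation(rep(0.2, 50), 4)
  expect_true(is.infinite(mp$d0))
  st <- data.frame(assay = paste0("m", 1:3), n_a = 3, n_b = 3,
                   mean_a = c(1, 2, 0), mean_b = 0,
                   var_a = 0.2, var_b = 0.2,
                   log2fc = c(1, 2, 0), s2 = c(0.1, 0.5, 0.2), df = 4)
  class(st) <- c("group_stats", "data.frame")
  res <- moderated_t_contrast(st, mp)
  expect_true(all(res$s2_post == mp$s0_sq))
  expect_error(estimate_moderation(rep(0, 20), 4), "zero")
  expect_error(estimate_moderation(rep(0.1, 5), 4), "at least 10")
})

test_that("d0 = 0 reduces the moderated t to the classical pooled t", {
  set.seed(44)
  for (rep in 1:10) {
    expr <- matrix(rnorm(20 * 6, sd = 0.5), 20, 6)
    expr[1:4, 1:3] <- expr[1:4, 1:3] + 2
    ds <- make_dataset(expr, rep(c("PSC_IN", "NSC_IN"), each = 3))
    st <- fit_group_stats(ds$norm, ds$det, "PSC_IN", "NSC_IN")
    res <- moderated_t_contrast(st, moderation_params_manual(0, 1))
    for (i in seq_len(nrow(res))) {
      a <- ds$norm[res$assay[i], 1:3]; b <- ds$norm[res$assay[i], 4:6]
      o <- pooled_t_oracle(a, b)
      expect_equal(res$t[i], o$t, tolerance = 1e-10)
      expect_equal(res$p[i], o$p, tolerance = 1e-10)
      expect_equal(res$df_total[i], o$df)
    }
  }
})

test_that("null effects give t = 0, p = 1; doubling deviations doubles t", {
  st <- data.frame(assay = c("null", "base"), n_a = 3, n_b = 3,
                   mean_a = c(1, 2), mean_b = c(1, 1),
                   var_a = 0.2, var_b = 0.2,
                   log2fc = c(0, 1), s2 = 0.2, df = 4)
  class(st) <- c("group_stats", "data.frame")
  mod <- moderation_params_manual(0, 1)
  res <- moderated_t_contrast(st, mod)
  expect_equal(res$t[1], 0); expect_equal(res$p[1], 1)
  st2 <- st; st2$log2fc <- st$log2fc * 2
  res2 <- moderated_t_contrast(st2, mod)
  expect_equal(res2$t, res$t * 2)
})

test_that("BH adjustment matches the hand-evaluated step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  p <- sort(runif(50))
  expect_true(all(bh_adjust(p) >= p))
})

test_that("DE status needs both thresholds; exclusivity overrides", {
  excl <- data.frame(assay = c("a", "b", "c"),
                     status = c("both_evaluable", "both_evaluable", "exclusive_A"),
                     stringsAsFactors = FALSE)
  attr(excl, "comparison") <- c("G1", "G2")
  res <- data.frame(assay = c("a", "b"),
                    log2fc = c(log2(1.6), log2(1.4)),
                    t = c(3, 3), df_total = 6, p = c(0.01, 0.01),
                    stringsAsFactors = FALSE)
  out <- call_de(res, excl, fc_threshold = 1.5, alpha = 0.05)
  expect_equal(out$status[out$assay == "a"], "up_A")
  expect_equal(out$status[out$assay == "b"], "ns")
  expect_equal(out$status[out$assay == "c"], "exclusive_A")
  expect_true(is.na(out$p[out$assay == "c"]))
  expect_true(all(out$adj_p >= out$p, na.rm = TRUE))
})

test_that("realized false discovery proportion is controlled on null data", {
  set.seed(45)
  n_assay <- 2000; reps <- 200
  fdp <- numeric(reps)
  groups <- rep(c("NSC_IN", "FPP_IN"), each = 3)
  for (r in seq_len(reps)) {
    expr <- matrix(rnorm(n_assay * 6, sd = 0.35), n_assay, 6)
    ds <- make_dataset(expr, groups)
    cr <- cq_contrast(ds$norm, ds$det, "NSC_IN", "FPP_IN")
    n_rej <- sum(cr$status %in% c("up_A", "up_B"))
    fdp[r] <- n_rej / max(n_rej, 1)   # all discoveries are false under the null
  }
  mc_se <- sd(fdp) / sqrt(reps)
  expect_lte(mean(fdp), 0.05 + 3 * mc_se)
})

test_that("planted 1.5 log2FC effects are recovered with >= 80% power", {
  set.seed(46)
  n_assay <- 2000; n_true <- 200
  expr <- matrix(rnorm(n_assay * 6, sd = 0.35), n_assay, 6)
  signs <- sample(c(-1, 1), n_true, replace = TRUE)
  expr[seq_len(n_true), 1:3] <- expr[seq_len(n_true), 1:3] + signs * 1.5
  ds <- make_dataset(expr, rep(c("NSC_IN", "FPP_IN"), each = 3))
  cr <- cq_contrast(ds$norm, ds$det, "NSC_IN", "FPP_IN")
  truth <- rownames(ds$norm)[seq_len(n_true)]
  hit <- cr$assay[cr$status %in% c("up_A", "up_B")]
  expect_gte(length(intersect(hit, truth)) / n_true, 0.80)
})

test_that("swapping group labels negates log2FC and swaps statuses", {
  set.seed(47)
  expr <- matrix(rnorm(60 * 6, sd = 0.4), 60, 6)
  expr[1:6, 1:3] <- expr[1:6, 1:3] + 2
  expr[7:12, 4:6] <- expr[7:12, 4:6] + 2
  ds <- make_dataset(expr, rep(c("NSC_IN", "FPP_IN"), each = 3))
  mod <- moderation_params_manual(2, 0.1)
  ab <- cq_contrast(ds$norm, ds$det, "NSC_IN", "FPP_IN", moderation = mod)
  ba <- cq_contrast(ds$norm, ds$det, "FPP_IN", "NSC_IN", moderation = mod)
  m <- match(ab$assay, ba$assay)
  expect_equal(ab$log2fc, -ba$log2fc[m])
  expect_equal(ab$p, ba$p[m])
  swap <- c(up_A = "up_B", up_B = "up_A", exclusive_A = "exclusive_B",
            exclusive_B = "exclusive_A", ns = "ns",
            not_evaluable = "not_evaluable")
  expect_equal(unname(swap[ab$status]), ba$status[m])
})
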