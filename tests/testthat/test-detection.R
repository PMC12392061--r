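make_cq <- function(vals, assays = NULL, samples = NULL) {
  m <- matrix(vals, nrow = if (is.null(assays)) 1L else length(assays),
              byrow = TRUE)
  rownames(m) <- if (is.null(assays)) "m1" else assays
  colnames(m) <- if (is.null(samples)) paste0("s", seq_len(ncol(m))) else samples
  cq_matrix(m)
}

test_that("detection window is inclusive at both bounds", {
  cq <- make_cq(c(24.3, 33.4, 30, 30.01, 15, 14.99, NA),
                samples = paste0("s", 1:7))
  det <- detection_call(cq)
  expect_equal(unname(det$detected[1, ]),
               c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE))
})

test_that("detection window bounds are validated", {
  cq <- make_cq(20)
  expect_error(detection_call(cq, lower_cq = 30, upper_cq = 15), "lower_cq")
  expect_error(detection_call(cq, upper_cq = 45), "upper_cq")
})

test_that("group completeness requires every replicate detected", {
  assays <- c("complete", "partial", "empty")
  vals <- rbind(c(24, 25, 26), c(24, 25, NA), c(NA, NA, NA))
  rownames(vals) <- assays
  colnames(vals) <- paste0("PSC_IN_C", 1:3)
  cq <- cq_matrix(vals)
  annot <- sample_sheet_from_ids(colnames(cq))
  det <- group_complete(detection_call(cq), annot)
  expect_true(det$complete["complete", "PSC_IN"])
  expect_equal(det$group_mean["complete", "PSC_IN"], 25)
  expect_false(det$complete["partial", "PSC_IN"])
  expect_true(is.na(det$group_mean["partial", "PSC_IN"]))
  expect_equal(unname(det$n_detected[, "PSC_IN"]), c(3L, 2L, 0L))
})

test_that("exclusivity follows the expressed/non-detected pattern", {
  samples <- c(paste0("PSC_EV_C", 1:3), paste0("PSC_IN_C", 1:3))
  vals <- rbind(
    mir622 = c(24.3, 24.3, 24.3, 33.4, 33.4, 33.4),  # expressed vs absent
    gap    = c(29.0, 29.0, 29.0, 33.0, 33.0, 33.0),  # detected but >= 28
    same   = c(20.0, 20.0, 20.0, 20.0, 20.0, 20.0)   # complete in both
  )
  colnames(vals) <- samples
  cq <- cq_matrix(vals)
  det <- group_complete(detection_call(cq), sample_sheet_from_ids(samples))
  ex <- exclusivity_call(det, "PSC_EV", "PSC_IN")
  expect_equal(ex$status[ex$assay == "mir622"], "exclusive_A")
  expect_equal(ex$status[ex$assay == "gap"], "neither")
  expect_equal(ex$status[ex$assay == "same"], "both_evaluable")
})

test_that("exclusivity is antisymmetric under group swap", {
  set.seed(11)
  for (rep in 1:5) {
    vals <- matrix(runif(60, 20, 38), 10, 6)
    vals[vals > 34] <- NA
    dimnames(vals) <- list(paste0("m", 1:10),
                           c(paste0("NSC_IN_C", 1:3), paste0("FPP_IN_C", 1:3)))
    det <- group_complete(detection_call(cq_matrix(vals)),
                          sample_sheet_from_ids(colnames(vals)))
    ab <- exclusivity_call(det, "NSC_IN", "FPP_IN")
    ba <- exclusivity_call(det, "FPP_IN", "NSC_IN")
    swap <- c(exclusive_A = "exclusive_B", exclusive_B = "exclusive_A",
              both_evaluable = "both_evaluable", neither = "neither")
    expect_equal(unname(swap[ab$status]), ba$status)
  }
})

test_that("raising the bounds never shrinks detected or exclusive sets", {
  set.seed(12)
  vals <- matrix(runif(120, 14, 40), 20, 6)
  vals[sample(120, 10)] <- NA
  dimnames(vals) <- list(paste0("m", 1:20),
                         c(paste0("PSC_EV_C", 1:3), paste0("PSC_IN_C", 1:3)))
  cq <- cq_matrix(vals)
  annot <- sample_sheet_from_ids(colnames(vals))
  det_sets <- lapply(c(28, 30, 32, 34), function(u) {
    which(detection_call(cq, upper_cq = u)$detected)
  })
  for (i in seq_len(length(det_sets) - 1L)) {
    expect_true(all(det_sets[[i]] %in% det_sets[[i + 1L]]))
  }
  base_det <- group_complete(detection_call(cq), annot)
  excl_sets <- lapply(c(24, 26, 28), function(e) {
    ex <- exclusivity_call(base_det, "PSC_EV", "PSC_IN", expressed_cq = e)
    ex$assay[ex$status %in% c("exclusive_A", "exclusive_B")]
  })
  for (i in seq_len(length(excl_sets) - 1L)) {
    expect_true(all(excl_sets[[i]] %in% excl_sets[[i + 1L]]))
  }
})

test_that("group-mean exclusivity variant is available and flagged", {
  samples <- c(paste0("PSC_EV_C", 1:3), paste0("PSC_IN_C", 1:3))
  # one A replicate at 28.5: per-replicate rule fails, mean (27.2) passes
  vals <- matrix(c(26, 27, 28.5, NA, NA, NA), 1,
                 dimnames = list("m1", samples))
  det <- group_complete(detection_call(cq_matrix(vals)),
                        sample_sheet_from_ids(samples))
  per_rep <- exclusivity_call(det, "PSC_EV", "PSC_IN")
  by_mean <- exclusivity_call(det, "PSC_EV", "PSC_IN", method = "group_mean")
  expect_equal(per_rep$status, "neither")
  expect_equal(by_mean$status, "exclusive_A")
  expect_equal(attr(by_mean, "method"), "group_mean")
})

test_that("detected_in_all equals the brute-force intersection over samples", {
  set.seed(13)
  for (rep in 1:5) {
    vals <- matrix(runif(80, 18, 36), 16, 5)
    vals[sample(80, 12)] <- NA
    dimnames(vals) <- list(paste0("m", 1:16), paste0("PSC_IN_C", 1:5))
    det <- detection_call(cq_matrix(vals))
    brute <- Reduce(intersect, lapply(seq_len(ncol(vals)), function(j) {
      rownames(vals)[det$detected[, j]]
    }))
    expect_setequal(detected_in_all(det), brute)
  }
  empty <- detection_call(cq_matrix(matrix(NA_real_, 2, 2,
                                           dimnames = list(c("a", "b"), c("s1", "s2")))))
  expect_length(detected_in_all(empty), 0L)
})
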