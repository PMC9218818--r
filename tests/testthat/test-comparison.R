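make_calls <- function(ids, phase, rhythmic = TRUE,
                       reason = ifelse(rhythmic, "none",
                                       "fails_correlation")) {
  calls <- data.frame(probe_id = ids, phase = phase, r = 0.9,
                      p_value = 0.001, predicted_fc = 2, abs_change = 10,
                      rhythmic = rhythmic, failure_reason = reason)
  class(calls) <- c("rhythm_calls", "data.frame")
  calls
}

test_that("circular phase shift uses the signed minimal difference", {
  expect_equal(circular_phase_shift(23, 1), 2)
  expect_equal(circular_phase_shift(8, 8), 0)
  expect_equal(circular_phase_shift(0, 12), 12)  # boundary -> +period/2
  expect_equal(circular_phase_shift(1, 23), -2)
  ## antisymmetric away from the boundary
  set.seed(2)
  a <- runif(100, 0, 24); b <- runif(100, 0, 24)
  s1 <- circular_phase_shift(a, b); s2 <- circular_phase_shift(b, a)
  off_boundary <- abs(abs(s1) - 12) > 1e-9
  expect_equal(s1[off_boundary], -s2[off_boundary])
})

test_that("compare_rhythm_sets partitions the rhythmic union", {
  ids <- sprintf("g%02d", 1:10)
  a <- make_calls(ids, phase = rep(4, 10),
                  rhythmic = c(rep(TRUE, 6), rep(FALSE, 4)))
  b <- make_calls(ids, phase = rep(7, 10),
                  rhythmic = c(rep(TRUE, 3), rep(FALSE, 5), TRUE, TRUE),
                  reason = c(rep("none", 3), rep("fails_amplitude", 5),
                             "none", "none"))
  cmp <- compare_rhythm_sets(a, b)
  expect_setequal(cmp$set_both, ids[1:3])
  expect_setequal(cmp$set_a_only, ids[4:6])
  expect_setequal(cmp$set_b_only, ids[9:10])
  ## the three sets partition rhythmic_A union rhythmic_B
  all_r <- union(ids[1:6], ids[c(1:3, 9, 10)])
  expect_setequal(c(cmp$set_both, cmp$set_a_only, cmp$set_b_only), all_r)
  expect_equal(sum(lengths(cmp[c("set_both", "set_a_only", "set_b_only")])),
               length(all_r))
  ## all lost genes failed amplitude in B
  expect_equal(cmp$failure_breakdown[["fails_amplitude"]], 1)
  expect_equal(sum(cmp$failure_breakdown), 1)
  ## crosstab sums to the shared set
  expect_equal(sum(cmp$phase_crosstab), 3)
  expect_equal(cmp$phase_crosstab["4", "7"], 3L)
  ## identical call sets: everything shared
  cmp2 <- compare_rhythm_sets(a, a)
  expect_setequal(cmp2$set_both, ids[1:6])
  expect_length(cmp2$set_a_only, 0)
  expect_equal(cmp2$phase_shift_median_h, 0)
  expect_error(compare_rhythm_sets(a, make_calls("zz", 1)), "no probes")
})

test_that("phase crosstab and histogram count what they should", {
  ids <- c("a", "b", "c")
  a <- make_calls(ids, phase = c(4, 4, 9))
  b <- make_calls(ids, phase = c(7, 7, 12))
  ct <- phase_crosstab(a, b, ids)
  expect_equal(dim(ct), c(24L, 24L))
  expect_equal(sum(ct), 3)
  expect_equal(ct["4", "7"], 2L)
  expect_equal(ct["9", "12"], 1L)
  ## identical phases give a diagonal
  ct2 <- phase_crosstab(a, a, ids)
  expect_equal(sum(diag(ct2)), 3)
  h <- phase_histogram(make_calls(rep("x", 10), phase = rep(8, 10)))
  expect_equal(unname(h["8"]), 10L)
  expect_equal(sum(h), 10)
  expect_equal(sum(phase_histogram(make_calls("y", 1, rhythmic = FALSE))), 0)
})

test_that("phase histogram of uniform simulator phases is near-uniform", {
  spec <- synthetic_dataset_spec(n_genes = 2400, fraction_rhythmic = 1,
                                 peak_trough_ratio = 3, noise_sd_frac = 0,
                                 seed = 31)
  sim <- simulate_expression(spec)
  calls <- classify_all(sim$dataset, "white", "WT",
                        rhythm_params(abs_change_multiplier = 0))
  h <- phase_histogram(calls)
  expect_equal(sum(h), 2400)
  ## binomial bound: 5 sd around 100 per bin
  sd_bin <- sqrt(2400 * (1 / 24) * (23 / 24))
  expect_true(all(abs(h - 100) <= 5 * sd_bin))
})

test_that("expression change profile bins log2 changes against phase", {
  times <- c(24, 32, 40, 48)
  sim <- simulate_paired(
    synthetic_dataset_spec(n_genes = 60, fraction_rhythmic = 1,
                           peak_trough_ratio = 3, noise_sd_frac = 0,
                           schedule = "red", seed = 41),
    effects = list())   # identity
  calls <- classify_all(sim$combined, "white", "WT",
                        rhythm_params(abs_change_multiplier = 0))
  prof <- expression_change_profile(
    sim$combined, c(condition = "white", genotype = "WT"),
    c(condition = "red", genotype = "WT"),
    genes = calls$probe_id[calls$rhythmic], phase_source = calls)
  ## identity effects: all log2 changes 0, central bin only, no up/down
  expect_true(all(abs(prof$log2_change) < 1e-9))
  expect_length(prof$up_set, 0)
  expect_length(prof$down_set, 0)
  expect_equal(sum(prof$histogram), length(prof$log2_change))
  expect_equal(sum(prof$histogram[, "(-0.25,0.25]"]),
               length(prof$log2_change))

  ## programmed 3x increase lands every gene in the up set
  sim3 <- simulate_paired(
    synthetic_dataset_spec(n_genes = 30, fraction_rhythmic = 1,
                           peak_trough_ratio = 3, noise_sd_frac = 0,
                           schedule = "red", seed = 43),
    effects = list(mean_scale = 3))
  calls3 <- classify_all(sim3$combined, "white", "WT",
                         rhythm_params(abs_change_multiplier = 0))
  prof3 <- expression_change_profile(
    sim3$combined, c(condition = "white", genotype = "WT"),
    c(condition = "red", genotype = "WT"),
    genes = calls3$probe_id[calls3$rhythmic], phase_source = calls3)
  expect_equal(unname(prof3$log2_change),
               rep(log2(3), length(prof3$log2_change)), tolerance = 1e-9)
  expect_setequal(prof3$up_set, names(prof3$log2_change))
  expect_length(prof3$down_set, 0)
})

test_that("night-phased programmed down-regulation is recovered by phase", {
  ## genes phased 0..23; those phased 14..21 drop 2-fold in condition B
  phases <- rep(0:23, each = 8)
  spec <- synthetic_dataset_spec(n_genes = length(phases),
                                 fraction_rhythmic = 1, phases = phases,
                                 peak_trough_ratio = 3,
                                 noise_sd_frac = 0.05, seed = 47)
  night <- phases >= 14 & phases <= 21
  sim <- simulate_paired(spec, effects = list(mean_scale = 0.5,
                                              affected = which(night)))
  calls <- classify_all(sim$combined, "white", "WT",
                        rhythm_params(abs_change_multiplier = 0))
  prof <- expression_change_profile(
    sim$combined, c(condition = "white", genotype = "WT"),
    c(condition = "red", genotype = "WT"),
    genes = calls$probe_id[calls$rhythmic], phase_source = calls)
  truth_down <- sim$truth$gene_id[night]
  hits <- intersect(prof$down_set, truth_down)
  ## essentially all programmed-down genes recovered, few spurious
  expect_gt(length(hits) / length(truth_down), 0.9)
  expect_lt(length(setdiff(prof$down_set, truth_down)) /
              length(prof$down_set), 0.1)
  expect_length(intersect(prof$up_set, prof$down_set), 0)
})
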