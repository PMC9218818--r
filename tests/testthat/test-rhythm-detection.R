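params0 <- rhythm_params(abs_change_multiplier = 0)

test_that("circadian_time wraps clock time onto the cycle", {
  expect_equal(circadian_time(c(24, 32, 68)), c(0, 8, 20))
  expect_error(circadian_time(-1), "t_h")
})

test_that("template bank has one peak-at-phase cosine per candidate phase", {
  bank <- build_template_bank(c(24, 32, 40, 48), params0)
  expect_equal(dim(bank$templates), c(4L, 24L))
  expect_equal(bank$phases, 0:23)
  ## phase-0 template peaks at CT0: mean + amplitude = 120
  expect_equal(unname(bank$templates[1, "0"]), 120)
  ## phase-12 template at CT0 sits at its trough: mean - amplitude = 0
  expect_equal(unname(bank$templates[1, "12"]), 0)
  expect_error(build_template_bank(c(24, 48, 72), params0), "distinct")
})

test_that("best phase is the argmax template, ties to the smallest label", {
  bank <- build_template_bank(c(0, 6, 12, 18), params0)
  series <- 100 + 20 * cos(2 * pi * (c(0, 6, 12, 18) - 8) / 24)
  expect_equal(round(series, 2), c(90, 117.32, 110, 82.68))
  bp <- best_phase_correlation(series, bank)
  expect_equal(bp$phase, 8)
  expect_equal(bp$r, 1, tolerance = 1e-12)
  ## constant series takes the degenerate path
  bp0 <- best_phase_correlation(rep(5, 4), bank)
  expect_true(bp0$degenerate)
  expect_equal(bp0$r, 0)
})

test_that("calls are invariant to template mean and amplitude", {
  tiny <- rhythm_params(template_mean = 0.001, template_amplitude = 0.001,
                        abs_change_multiplier = 0)
  times <- seq(24, 68, by = 4)
  set.seed(3)
  gm <- 100
  for (i in 1:20) {
    series <- 100 + 30 * cos(2 * pi * (times - sample(0:23, 1)) / 24) +
      rnorm(12, sd = 10)
    c1 <- classify_gene(series, times, gm, params0)
    c2 <- classify_gene(series, times, gm, tiny)
    expect_equal(c1, c2)
  }
})

test_that("best phase agrees with a dense brute-force oracle", {
  set.seed(11)
  for (times in list(seq(24, 68, by = 4), c(24, 32, 40, 48))) {
    n <- 60
    m <- matrix(100 + rnorm(n * length(times), sd = 20), length(times), n)
    bank <- build_template_bank(times, params0)
    got <- apply(m, 2, function(s) best_phase_correlation(s, bank)$phase)
    want <- dense_phase_oracle(m, times)
    d <- pmin(abs(got - want), 24 - abs(got - want))
    expect_true(all(d <= 1 + 1e-9))
  }
})

test_that("correlation p-value matches the t test and its critical values", {
  expect_equal(correlation_pvalue(0, 12), 1)
  expect_equal(correlation_pvalue(1, 4), 0)
  expect_equal(correlation_pvalue(-1, 4), 0)
  expect_error(correlation_pvalue(0.5, 2), "n >= 3")
  ## agree with cor.test on arbitrary data
  set.seed(5)
  x <- rnorm(12); y <- rnorm(12)
  expect_equal(correlation_pvalue(cor(x, y), 12),
               cor.test(x, y)$p.value)
  ## critical r inverted independently from the p-value function itself
  for (n in c(12L, 4L)) {
    r_crit <- uniroot(function(r) correlation_pvalue(r, n) - 0.01,
                      c(1e-6, 1 - 1e-9), tol = 1e-12)$root
    expect_equal(min_significant_r(n, 0.01), r_crit, tolerance = 1e-9)
  }
  expect_equal(min_significant_r(12, 0.01), 0.708, tolerance = 5e-4)
  expect_equal(min_significant_r(4, 0.01), 0.990, tolerance = 5e-4)
})

test_that("nearest extremum samples follow circular distance with earliest-time ties", {
  ## CT {0,8,16}, phase 0: trough target CT12 ties CT8/CT16 -> earliest
  ext <- nearest_extremum_samples(c(0, 8, 16), phase = 0)
  expect_equal(ext, list(peak = 1L, trough = 2L))
  ext <- nearest_extremum_samples(c(0, 6, 12, 18), phase = 8)
  expect_equal(ext, list(peak = 2L, trough = 4L))
  ## random times and phases agree with exhaustive search
  set.seed(7)
  for (i in 1:50) {
    times <- sort(runif(6, 0, 72))
    phase <- runif(1, 0, 24)
    ext <- nearest_extremum_samples(times, phase)
    ct <- times %% 24
    dist <- function(target) pmin(abs(ct - target) %% 24,
                                  24 - abs(ct - target) %% 24)
    for (side in c("peak", "trough")) {
      target <- if (side == "peak") phase else (phase + 12) %% 24
      d <- dist(target)
      expect_equal(d[ext[[side]]], min(d), tolerance = 1e-9)
    }
  }
})

test_that("predicted fold change follows the 1.5-fold reference-wave comparison", {
  p <- params0
  ## worked case: phase-0 cosine, mean 120, ratio 2, samples CT 0/8/16/24
  times <- c(0, 8, 16, 24)
  series <- 120 + 40 * cos(2 * pi * times / 24)
  expect_equal(series, c(160, 100, 100, 160))
  expect_equal(predicted_fold_change(series, times, 0, p), 1.8)
  ## flat series fails
  expect_lt(predicted_fold_change(rep(50, 4), times, 0, p), 1.5)
  ## exactly 1.5-fold series sits on the boundary
  series15 <- 100 + 20 * cos(2 * pi * (times - 4) / 24)
  expect_equal(predicted_fold_change(series15, times, 4, p), 1.5)
  ## non-positive extremum value fails with 0
  bad <- series; bad[1] <- 0
  expect_equal(predicted_fold_change(bad, times, 0, p), 0)
  ## monotone in the true ratio for noiseless sines, both schedules
  for (times in list(seq(24, 68, by = 4), c(24, 32, 40, 48))) {
    for (phase in c(0, 5, 13)) {
      pfc <- sapply(c(1.4, 1.5, 1.6), function(ratio) {
        a <- 100 * (ratio - 1) / (ratio + 1)
        s <- 100 + a * cos(2 * pi * (times - phase) / 24)
        predicted_fold_change(s, times, phase, p)
      })
      expect_lt(pfc[1], 1.5 - 1e-9)
      expect_gte(pfc[2], 1.5 - 1e-9)
      expect_gte(pfc[3], 1.5)
      expect_true(all(diff(pfc) > 0))
    }
  }
})

test_that("absolute change criterion is a plain range threshold", {
  p25 <- rhythm_params(abs_change_multiplier = 2.5)
  p250 <- rhythm_params(abs_change_multiplier = 250)
  series <- c(100, 400, 150, 120)   # range 300
  expect_true(absolute_change_criterion(series, 100, p25))
  expect_false(absolute_change_criterion(series, 100, p250))
  expect_true(absolute_change_criterion(series, 100, params0))
})

test_that("classify_gene composes the criteria with correct failure reasons", {
  times <- seq(24, 68, by = 4)
  gm <- 100
  p <- rhythm_params(abs_change_multiplier = 2.5)
  ## clean rhythmic gene
  s <- 100 + 40 * cos(2 * pi * (times - 8) / 24)
  call <- classify_gene(s, times, gm, p)
  expect_true(call$rhythmic)
  expect_equal(call$phase, 8)
  expect_equal(call$failure_reason, "none")
  ## perfect but shallow sine: correlation passes, both amplitude tests fail
  s <- 100 + 100 * (1.2 - 1) / (1.2 + 1) * cos(2 * pi * (times - 8) / 24)
  call <- classify_gene(s, times, gm, p)
  expect_false(call$rhythmic)
  expect_equal(call$failure_reason, "fails_amplitude")
  expect_equal(call$r, 1, tolerance = 1e-12)
  ## flat gene
  call <- classify_gene(rep(7, 12), times, gm, p)
  expect_equal(call$failure_reason, "fails_correlation")
  expect_equal(call$p_value, 1)
  ## noise genes: reasons agree with independent recomputation
  set.seed(19)
  bank <- build_template_bank(times, p)
  for (i in 1:40) {
    s <- 100 + rnorm(12, sd = 15)
    call <- classify_gene(s, times, gm, p)
    r <- max(cor(s, bank$templates))
    pv <- 2 * pt(abs(r) * sqrt(10 / (1 - r^2)), 10, lower.tail = FALSE)
    expect_equal(call$p_value, pv, tolerance = 1e-12)
    if (pv >= 0.01) {
      expect_equal(call$failure_reason, "fails_correlation")
    } else {
      expect_true(call$failure_reason %in% c("none", "fails_amplitude"))
      passes <- call$predicted_fc >= 1.5 - 1e-9 ||
        diff(range(s)) >= 2.5 * gm
      expect_equal(call$rhythmic, passes)
    }
  }
  ## adding a constant never changes r or p (amplitude may change)
  s <- 100 + 30 * cos(2 * pi * (times - 3) / 24) + rnorm(12, sd = 5)
  c1 <- classify_gene(s, times, gm, p)
  c2 <- classify_gene(s + 500, times, gm, p)
  expect_equal(c1$r, c2$r)
  expect_equal(c1$p_value, c2$p_value)
})

test_that("classify_all matches classify_gene and is deterministic", {
  spec <- synthetic_dataset_spec(n_genes = 100, fraction_rhythmic = 0.5,
                                 peak_trough_ratio = 3, noise_sd_frac = 0,
                                 schedule = "white", seed = 21)
  sim <- simulate_expression(spec)
  p <- rhythm_params(abs_change_multiplier = 2.5)
  calls <- classify_all(sim$dataset, "white", "WT", p)
  ## noiseless: exactly the programmed rhythmic genes, exact phases
  expect_equal(sum(calls$rhythmic), 50)
  expect_equal(calls$rhythmic, sim$truth$rhythmic)
  expect_equal(calls$phase[calls$rhythmic],
               sim$truth$phase_h[sim$truth$rhythmic])
  ## per-gene path agrees with the vectorised path
  times <- sim$dataset$design$time_h
  for (i in c(1, 17, 60, 100)) {
    cg <- classify_gene(sim$dataset$values[i, ], times,
                        sim$dataset$grand_mean, p)
    expect_equal(cg$phase, calls$phase[i])
    expect_equal(cg$r, calls$r[i], tolerance = 1e-12)
    expect_equal(cg$rhythmic, calls$rhythmic[i])
  }
  ## repeated runs are identical; unknown group errors
  expect_identical(calls, classify_all(sim$dataset, "white", "WT", p))
  expect_error(classify_all(sim$dataset, "blue", "WT", p), "blue")
})
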