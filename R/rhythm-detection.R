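#' Rhythm-detection parameters
#'
#' Parameters of the sine-correlation rhythmicity classifier. A gene is
#' called rhythmic when (i) the best Pearson correlation against a bank of
#' 24-h cosine templates phased `phase_step_h` apart is significant at
#' `alpha` under a t-test for correlation, and (ii) it passes at least one
#' of two amplitude criteria: an extrapolated peak-to-trough fold change of
#' at least `fold_threshold`, or an absolute min-to-max change of at least
#' `abs_change_multiplier` times the grand mean expression of all probes
#' across all arrays.
#'
#' `abs_change_multiplier` has no default on purpose. Read literally, the
#' published threshold ("250 times the mean expression of all probes") would
#' exclude essentially every gene under typical normalized scales, so the
#' value must be chosen explicitly per run; `0` disables the absolute
#' criterion (the fold-change criterion then decides alone), `2.5` is a
#' plausible permissive reading, `250` the literal one.
#'
#' @param period_h Oscillation period in hours (fixed, not estimated).
#' @param phase_step_h Spacing of candidate template phases in hours; must
#'   divide the period evenly.
#' @param template_mean,template_amplitude Mean and amplitude of the
#'   templates. Pearson correlation is invariant to both, so they are
#'   cosmetic; the conventional value 60 is kept as the default.
#' @param alpha Significance level for the correlation t-test.
#' @param fold_threshold Minimum extrapolated peak-to-trough fold change.
#' @param abs_change_multiplier Multiple of the grand mean that the
#'   min-to-max change must reach for the absolute criterion. Required.
#' @param floor_fraction Expressed-gene floor as a fraction of the grand
#'   mean (consumed by [filter_expressed]; carried here so one object
#'   configures a whole run).
#' @param one_sided If `TRUE`, the correlation t-test is one-sided
#'   (`r > 0`); default two-sided.
#' @return A list of class `rhythm_params`.
#' @examples
#' rhythm_params(abs_change_multiplier = 2.5)
#' @export
rhythm_params <- function(period_h = 24, phase_step_h = 1,
                          template_mean = 60, template_amplitude = 60,
                          alpha = 0.01, fold_threshold = 1.5,
                          abs_change_multiplier, floor_fraction = 0.05,
                          one_sided = FALSE) {
  if (missing(abs_change_multiplier))
    stop2("'abs_change_multiplier' must be given explicitly ",
          "(0 disables the absolute-change criterion)")
  stopifnot(period_h > 0, phase_step_h > 0,
            alpha > 0, alpha < 1, fold_threshold > 1,
            abs_change_multiplier >= 0,
            floor_fraction >= 0, floor_fraction < 1)
  n_phase <- period_h / phase_step_h
  if (abs(n_phase - round(n_phase)) > 1e-9)
    stop2("'phase_step_h' must divide 'period_h' evenly")
  structure(list(period_h = period_h, phase_step_h = phase_step_h,
                 template_mean = template_mean,
                 template_amplitude = template_amplitude,
                 alpha = alpha, fold_threshold = fold_threshold,
                 abs_change_multiplier = abs_change_multiplier,
                 floor_fraction = floor_fraction, one_sided = one_sided),
            class = "rhythm_params")
}

#' @rdname rhythm_params
#' @param x,... Print method arguments.
#' @export
print.rhythm_params <- function(x, ...) {
  cat("rhythm_params: period ", x$period_h, " h, phase step ",
      x$phase_step_h, " h, alpha ", x$alpha, ", fold >= ",
      x$fold_threshold, ", abs change >= ", x$abs_change_multiplier,
      " x grand mean\n", sep = "")
  invisible(x)
}

#' Build the cosine template bank
#'
#' One template per candidate phase `p`, evaluated at the sample clock
#' times: `s_p(t) = mean + amplitude * cos(2*pi*(t - p)/period)`, so each
#' template peaks at circadian time equal to its phase label. Templates are
#' evaluated at clock time; for a pure 24-h cosine this is identical to
#' evaluating at circadian time.
#'
#' @param times_h Sample times in hours since transfer to constant light.
#' @param params A [rhythm_params] object.
#' @return List of class `sine_template_bank` with `times_h`, `phases` and
#'   `templates` (matrix, rows = times, columns = phases).
#' @export
build_template_bank <- function(times_h, params) {
  stopifnot(inherits(params, "rhythm_params"))
  ct <- circadian_time(times_h, params$period_h)
  if (length(unique(round(ct, 9))) < 3L)
    stop2("need >= 3 distinct circadian times among samples")
  phases <- seq(0, params$period_h - params$phase_step_h,
                by = params$phase_step_h)
  templates <- outer(times_h, phases, function(t, p)
    params$template_mean + params$template_amplitude *
      cos(2 * pi * (t - p) / params$period_h))
  colnames(templates) <- as.character(phases)
  structure(list(times_h = times_h, phases = phases, templates = templates,
                 period_h = params$period_h),
            class = "sine_template_bank")
}

#' Best-phase Pearson correlation
#'
#' Correlates a series against every template in the bank and returns the
#' phase whose template maximises Pearson r, ties broken by the smallest
#' phase label. A zero-variance series has no defined correlation and is
#' returned with `r = 0` (flagged via `degenerate = TRUE`) so that the
#' caller can route it down the arrhythmic path.
#'
#' @param series Numeric vector of expression values, one per sample.
#' @param bank A [build_template_bank] result.
#' @return List `phase`, `r`, `degenerate`.
#' @export
best_phase_correlation <- function(series, bank) {
  stopifnot(inherits(bank, "sine_template_bank"),
            length(series) == nrow(bank$templates))
  if (stats::sd(series) == 0)
    return(list(phase = bank$phases[1L], r = 0, degenerate = TRUE))
  r <- as.vector(stats::cor(series, bank$templates))
  best <- which.max(r)           # which.max takes the first of tied maxima
  list(phase = bank$phases[best], r = r[best], degenerate = FALSE)
}

#' t-test p-value for a Pearson correlation
#'
#' Tail probability of `t = r * sqrt((n - 2)/(1 - r^2))` under a t
#' distribution with `n - 2` degrees of freedom (H0: r = 0). Two-sided by
#' default; `|r| = 1` returns exactly 0.
#'
#' @param r Correlation in `[-1, 1]`.
#' @param n Number of paired observations actually correlated (>= 3).
#' @param one_sided One-sided upper-tail test if `TRUE`.
#' @return p-value in `[0, 1]`.
#' @export
correlation_pvalue <- function(r, n, one_sided = FALSE) {
  if (n < 3L) stop2("correlation t-test needs n >= 3")
  stopifnot(all(abs(r) <= 1 + 1e-12))
  r <- pmin(pmax(r, -1), 1)
  p <- ifelse(abs(r) == 1, 0, {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    if (one_sided) stats::pt(tt, df = n - 2, lower.tail = FALSE)
    else 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  })
  unname(p)
}

#' Smallest correlation reaching significance
#'
#' The minimum r for which [correlation_pvalue] falls below `alpha` at a
#' given sample count, from the t quantile: `r = t / sqrt(df + t^2)` with
#' `t = qt(1 - alpha/2, df)`, `df = n - 2`.
#'
#' @inheritParams correlation_pvalue
#' @param alpha Significance level.
#' @return Critical correlation value.
#' @export
min_significant_r <- function(n, alpha = 0.01, one_sided = FALSE) {
  if (n < 3L) stop2("needs n >= 3")
  df <- n - 2
  q <- if (one_sided) stats::qt(1 - alpha, df) else stats::qt(1 - alpha / 2, df)
  q / sqrt(df + q^2)
}

#' Sample points nearest the fitted peak and trough
#'
#' Identifies the samples whose circadian times are circularly closest to
#' the fitted peak phase and to the antiphase (phase + period/2). Ties are
#' broken by the earliest clock time of sampling, making the choice
#' deterministic on symmetric schedules.
#'
#' @param times_h Sample clock times (hours).
#' @param phase Fitted peak phase in `[0, period)`.
#' @param period_h Period in hours.
#' @return List `peak`, `trough` of sample indices.
#' @export
nearest_extremum_samples <- function(times_h, phase, period_h = 24) {
  stopifnot(length(times_h) >= 2L)
  ct <- circadian_time(times_h, period_h)
  nearest <- function(target) {
    d <- circ_dist(ct, target, period_h)
    cand <- which(d <= min(d) + 1e-9)
    cand[which.min(times_h[cand])]
  }
  list(peak = nearest(phase),
       trough = nearest((phase + period_h / 2) %% period_h))
}

#' Extrapolated peak-to-trough fold change
#'
#' Compares the observed fold change between the samples nearest the
#' fitted peak and trough with the fold change a reference sine of the
#' same phase, the same mean expression and an exact 1.5-fold
#' peak-to-trough ratio would show at those same sample points:
#' `predicted_fc = fold_threshold * FC_obs / FC_ref`. The amplitude
#' criterion passes when `predicted_fc >= fold_threshold`, i.e. when the
#' observed change at those points is at least that of the 1.5-fold
#' reference wave. A non-positive value at either extremum sample makes
#' the ratio meaningless; the criterion then fails with `predicted_fc = 0`.
#'
#' @param series Expression values.
#' @param times_h Sample clock times.
#' @param phase Fitted phase.
#' @param params A [rhythm_params].
#' @return `predicted_fc` (single number, >= 0).
#' @export
predicted_fold_change <- function(series, times_h, phase, params) {
  ext <- nearest_extremum_samples(times_h, phase, params$period_h)
  v_peak <- series[ext$peak]
  v_trough <- series[ext$trough]
  if (v_peak <= 0 || v_trough <= 0) return(0)
  fc_obs <- v_peak / v_trough
  ## reference wave: mean of the observed series, peak/trough exactly
  ## fold_threshold, so amplitude = mean * (f - 1)/(f + 1)
  m <- mean(series)
  a <- m * (params$fold_threshold - 1) / (params$fold_threshold + 1)
  ref <- function(t) m + a * cos(2 * pi * (t - phase) / params$period_h)
  fc_ref <- ref(times_h[ext$peak]) / ref(times_h[ext$trough])
  params$fold_threshold * fc_obs / fc_ref
}

#' Absolute min-to-max change criterion
#'
#' `TRUE` when `max(series) - min(series)` reaches
#' `abs_change_multiplier * grand_mean`. A multiplier of 0 disables the
#' criterion by passing everything.
#'
#' @inheritParams predicted_fold_change
#' @param grand_mean Grand mean of all probes across all arrays.
#' @return Logical.
#' @export
absolute_change_criterion <- function(series, grand_mean, params) {
  stopifnot(grand_mean > 0)
  diff(range(series)) >= params$abs_change_multiplier * grand_mean
}

## boundary tolerance for the fold criterion: a noiseless series at exactly
## the threshold ratio must pass despite floating-point rounding
.fc_eps <- 1e-9

#' Classify one gene
#'
#' Composes best-phase correlation, the correlation t-test, and the two
#' amplitude criteria into a rhythm call. `rhythmic` is `TRUE` iff
#' `p < alpha` and (`predicted_fc >= fold_threshold` or the absolute-change
#' criterion holds); `failure_reason` is `"fails_correlation"` when the
#' t-test fails (including degenerate flat series) and `"fails_amplitude"`
#' when only the amplitude tests fail.
#'
#' @param series Expression values for one gene.
#' @param times_h Sample clock times.
#' @param grand_mean Grand mean of the dataset at classification time.
#' @param params A [rhythm_params].
#' @param bank Optional precomputed template bank for `times_h`.
#' @return One-row `data.frame`: `phase`, `r`, `p_value`, `predicted_fc`,
#'   `abs_change`, `rhythmic`, `failure_reason`.
#' @export
classify_gene <- function(series, times_h, grand_mean, params,
                          bank = build_template_bank(times_h, params)) {
  bp <- best_phase_correlation(series, bank)
  n <- length(series)
  abs_change <- diff(range(series))
  if (bp$degenerate) {
    return(data.frame(phase = bp$phase, r = 0, p_value = 1,
                      predicted_fc = 0, abs_change = abs_change,
                      rhythmic = FALSE,
                      failure_reason = "fails_correlation"))
  }
  p <- correlation_pvalue(bp$r, n, one_sided = params$one_sided)
  pfc <- predicted_fold_change(series, times_h, bp$phase, params)
  amp_ok <- pfc >= params$fold_threshold - .fc_eps ||
    absolute_change_criterion(series, grand_mean, params)
  rhythmic <- p < params$alpha && amp_ok
  reason <- if (rhythmic) "none"
    else if (p >= params$alpha) "fails_correlation" else "fails_amplitude"
  data.frame(phase = bp$phase, r = bp$r, p_value = p, predicted_fc = pfc,
             abs_change = abs_change, rhythmic = rhythmic,
             failure_reason = reason)
}

#' Classify every probe of a group
#'
#' Runs the classifier over all probes of one (condition, genotype) group
#' of a dataset. The correlation step is vectorised across probes;
#' amplitude criteria and failure-reason attribution follow per probe.
#' The grand mean used by the absolute-change criterion is the dataset's
#' value current at call time.
#'
#' @param ds An [expression_dataset].
#' @param condition,genotype Group selector; must exist in the design.
#' @param params A [rhythm_params].
#' @param probes Probe ids to classify; default all probes of `ds`.
#' @return A `rhythm_calls` data.frame, one row per probe, with columns
#'   `probe_id`, `phase`, `r`, `p_value`, `predicted_fc`, `abs_change`,
#'   `rhythmic`, `failure_reason`; the parameters, grand mean, sample
#'   count and group are attached as attributes. A summary is logged.
#' @export
classify_all <- function(ds, condition, genotype, params,
                         probes = rownames(ds$values)) {
  stopifnot(inherits(ds, "expression_dataset"),
            inherits(params, "rhythm_params"))
  cols <- group_columns(ds, condition, genotype)
  times_h <- ds$design$time_h[cols]
  ord <- order(times_h)
  cols <- cols[ord]; times_h <- times_h[ord]
  bank <- build_template_bank(times_h, params)
  m <- ds$values[probes, cols, drop = FALSE]
  n <- length(times_h)

  sds <- apply(m, 1L, stats::sd)
  degen <- sds == 0
  ## vectorised best phase: cor() of every probe against every template
  rmat <- suppressWarnings(stats::cor(t(m), bank$templates))
  rmat[degen, ] <- 0
  best <- max.col(rmat, ties.method = "first")
  phase <- bank$phases[best]
  r <- rmat[cbind(seq_len(nrow(m)), best)]
  p <- ifelse(degen, 1, correlation_pvalue(r, n, one_sided = params$one_sided))

  pfc <- numeric(nrow(m))
  abs_change <- apply(m, 1L, function(x) diff(range(x)))
  for (i in seq_len(nrow(m))) {
    pfc[i] <- if (degen[i]) 0 else
      predicted_fold_change(m[i, ], times_h, phase[i], params)
  }
  amp_ok <- pfc >= params$fold_threshold - .fc_eps |
    abs_change >= params$abs_change_multiplier * ds$grand_mean
  rhythmic <- !degen & p < params$alpha & amp_ok
  reason <- ifelse(rhythmic, "none",
            ifelse(degen | p >= params$alpha, "fails_correlation",
                   "fails_amplitude"))
  calls <- data.frame(probe_id = rownames(m), phase = phase, r = r,
                      p_value = p, predicted_fc = pfc,
                      abs_change = abs_change, rhythmic = rhythmic,
                      failure_reason = reason, row.names = NULL)
  attr(calls, "params") <- params
  attr(calls, "grand_mean") <- ds$grand_mean
  attr(calls, "n_samples") <- n
  attr(calls, "group") <- c(condition = condition, genotype = genotype)
  class(calls) <- c("rhythm_calls", "data.frame")
  msg_log(sprintf(
    "classify_all [%s/%s]: %d/%d rhythmic (%.1f%%); failures: %d correlation, %d amplitude",
    condition, genotype, sum(rhythmic), nrow(calls),
    100 * mean(rhythmic), sum(reason == "fails_correlation"),
    sum(reason == "fails_amplitude")))
  calls
}

#' Write rhythm calls to TSV
#'
#' @param calls A `rhythm_calls` data.frame.
#' @param path Output file.
#' @export
write_rhythm_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read rhythm calls from TSV
#'
#' @param path File written by [write_rhythm_calls].
#' @return A `rhythm_calls` data.frame (without parameter attributes).
#' @export
read_rhythm_calls <- function(path) {
  calls <- read_delim_auto(path)
  class(calls) <- c("rhythm_calls", "data.frame")
  calls
}
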