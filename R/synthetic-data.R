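#' Sampling schedule presets
#'
#' `"white"`: two free-running cycles, 12 samples at 4-h intervals
#' starting 24 h after transfer to constant light (24, 28, ..., 68 h).
#' `"red"`: one cycle, 4 samples at 8-h intervals (24, 32, 40, 48 h).
#'
#' @param name `"white"` or `"red"`, or a numeric vector of times to pass
#'   through unchanged.
#' @return Numeric vector of sample times (hours since transfer).
#' @export
schedule_times <- function(name) {
  if (is.numeric(name)) {
    if (any(name < 0) || is.unsorted(name, strictly = TRUE))
      stop2("schedule times must be non-negative and strictly increasing")
    return(name)
  }
  switch(name,
         white = seq(24, 68, by = 4),
         red = c(24, 32, 40, 48),
         stop2("unknown schedule preset: ", name))
}

#' Specification of a synthetic circadian dataset
#'
#' Describes a cohort of genes with cosine-shaped expression: for gene g,
#' `value(g, t) = max(eps, m * (1 + a(t) * cos(2*pi*(t - phi)/24)) + noise)`
#' with relative amplitude `a(t) = a0 * exp(-damping * t/24)`,
#' `a0 = (ratio - 1)/(ratio + 1)` for peak-to-trough ratio `ratio`, and
#' additive Gaussian noise of sd `noise_sd_frac * m`. Arrhythmic genes
#' have ratio 1 (flat plus noise).
#'
#' @param n_genes Number of genes.
#' @param schedule Schedule preset name or numeric times
#'   (see [schedule_times]).
#' @param fraction_rhythmic Fraction of genes programmed rhythmic.
#' @param phases Optional vector of phases recycled over rhythmic genes;
#'   default phases drawn uniformly from the integer grid `0..23`.
#' @param mean_level Mean expression level(s), recycled over genes.
#' @param peak_trough_ratio Peak-to-trough ratio(s) for rhythmic genes.
#' @param noise_sd_frac Noise sd as a fraction of the gene mean.
#' @param damping_rate Fractional amplitude loss per 24 h (default 0).
#' @param condition,genotype Labels written into the design.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return List of class `synthetic_dataset_spec`.
#' @export
synthetic_dataset_spec <- function(n_genes = 1000L, schedule = "white",
                                   fraction_rhythmic = 0.5, phases = NULL,
                                   mean_level = 100,
                                   peak_trough_ratio = 2.5,
                                   noise_sd_frac = 0.1, damping_rate = 0,
                                   condition = "white", genotype = "WT",
                                   seed) {
  if (missing(seed)) stop2("'seed' is required")
  stopifnot(n_genes >= 1L, fraction_rhythmic >= 0, fraction_rhythmic <= 1,
            all(mean_level > 0), all(peak_trough_ratio >= 1),
            all(noise_sd_frac >= 0), all(damping_rate >= 0))
  structure(list(n_genes = as.integer(n_genes),
                 times_h = schedule_times(schedule),
                 fraction_rhythmic = fraction_rhythmic, phases = phases,
                 mean_level = mean_level,
                 peak_trough_ratio = peak_trough_ratio,
                 noise_sd_frac = noise_sd_frac, damping_rate = damping_rate,
                 condition = condition, genotype = genotype,
                 seed = as.integer(seed)),
            class = "synthetic_dataset_spec")
}

## evaluate the noiseless cosine model of one gene at times t
cosine_signal <- function(t, mean_level, phase, ratio, damping = 0,
                          period_h = 24) {
  a0 <- (ratio - 1) / (ratio + 1)
  at <- a0 * exp(-damping * t / period_h)
  mean_level * (1 + at * cos(2 * pi * (t - phase) / period_h))
}

#' Simulate a synthetic expression dataset with known truth
#'
#' @param spec A [synthetic_dataset_spec].
#' @param eps Positivity floor applied after adding noise (default 1e-6).
#' @return List with `dataset` (an [expression_dataset] with nuclear/AGI
#'   annotation throughout) and `truth` (per-gene data.frame of the
#'   programmed parameters: `gene_id`, `rhythmic`, `phase_h`,
#'   `mean_level`, `peak_trough_ratio`, `noise_sd_frac`, `damping_rate`).
#' @export
simulate_expression <- function(spec, eps = 1e-6) {
  stopifnot(inherits(spec, "synthetic_dataset_spec"))
  set.seed(spec$seed)
  n <- spec$n_genes
  n_rhy <- round(spec$fraction_rhythmic * n)
  rhythmic <- c(rep(TRUE, n_rhy), rep(FALSE, n - n_rhy))
  phases <- numeric(n)
  if (n_rhy > 0) {
    phases[seq_len(n_rhy)] <- if (is.null(spec$phases))
      sample(0:23, n_rhy, replace = TRUE)
    else rep_len(spec$phases, n_rhy)
  }
  truth <- data.frame(
    gene_id = sprintf("G%05d", seq_len(n)),
    rhythmic = rhythmic,
    phase_h = ifelse(rhythmic, phases, NA_real_),
    mean_level = rep_len(spec$mean_level, n),
    peak_trough_ratio = ifelse(rhythmic,
                               rep_len(spec$peak_trough_ratio, n), 1),
    noise_sd_frac = rep_len(spec$noise_sd_frac, n),
    damping_rate = rep_len(spec$damping_rate, n))
  list(dataset = render_dataset(truth, spec$times_h, spec$condition,
                                spec$genotype, eps),
       truth = truth)
}

## deterministic-given-RNG-state rendering of a truth table to a dataset
render_dataset <- function(truth, times_h, condition, genotype, eps = 1e-6) {
  n <- nrow(truth)
  signal <- t(vapply(seq_len(n), function(i)
    cosine_signal(times_h, truth$mean_level[i],
                  ifelse(is.na(truth$phase_h[i]), 0, truth$phase_h[i]),
                  truth$peak_trough_ratio[i], truth$damping_rate[i]),
    numeric(length(times_h))))
  noise <- matrix(stats::rnorm(n * length(times_h)), nrow = n) *
    truth$noise_sd_frac * truth$mean_level
  values <- signal + noise
  values[values < eps] <- eps
  sample_id <- sprintf("%s_%s_T%02.0f", condition, genotype, times_h)
  dimnames(values) <- list(truth$gene_id, sample_id)
  design <- data.frame(sample_id = sample_id, condition = condition,
                       genotype = genotype, time_h = times_h)
  annotation <- data.frame(probe_id = truth$gene_id,
                           agi_code = paste0("AT1G", sprintf("%05d",
                                             seq_len(n))),
                           compartment = "nuclear")
  expression_dataset(values, design, annotation)
}

#' Simulate a paired-condition dataset
#'
#' Condition B is derived from condition A's programmed parameters by
#' per-gene effects, emulating a change of light condition or genotype:
#' a phase delay, amplitude scaling (scaling the relative amplitude
#' `a0`, and so moving the peak-to-trough ratio toward 1), mean scaling,
#' and forced arrhythmicity (ratio set to 1).
#'
#' @param spec A [synthetic_dataset_spec] describing condition A.
#' @param effects List with any of `phase_delay_h`, `amplitude_scale`,
#'   `mean_scale` (scalars or per-gene vectors) and `affected` (logical
#'   or index vector of genes the effects apply to; default all), plus
#'   `force_arrhythmic` (logical/index vector of genes flattened in B).
#' @param condition_b,genotype_b Labels for condition B.
#' @return List `dataset_a`, `dataset_b`, `truth` (both parameter sets),
#'   and `combined` (single [expression_dataset] with both groups).
#' @export
simulate_paired <- function(spec, effects = list(), condition_b = "red",
                            genotype_b = spec$genotype) {
  sim_a <- simulate_expression(spec)
  truth_a <- sim_a$truth
  truth_b <- truth_a
  n <- nrow(truth_a)
  affected <- rep(FALSE, n)
  affected[effects$affected %||% seq_len(n)] <- TRUE

  if (!is.null(effects$phase_delay_h))
    truth_b$phase_h[affected] <- (truth_b$phase_h[affected] +
      rep_len(effects$phase_delay_h, n)[affected]) %% 24
  if (!is.null(effects$amplitude_scale)) {
    a0 <- (truth_b$peak_trough_ratio - 1) / (truth_b$peak_trough_ratio + 1)
    a0[affected] <- a0[affected] *
      rep_len(effects$amplitude_scale, n)[affected]
    truth_b$peak_trough_ratio <- (1 + a0) / (1 - a0)
  }
  if (!is.null(effects$mean_scale))
    truth_b$mean_level[affected] <- truth_b$mean_level[affected] *
      rep_len(effects$mean_scale, n)[affected]
  if (!is.null(effects$force_arrhythmic)) {
    flat <- rep(FALSE, n)
    flat[effects$force_arrhythmic] <- TRUE
    truth_b$peak_trough_ratio[flat] <- 1
    truth_b$rhythmic[flat] <- FALSE
    truth_b$phase_h[flat] <- NA_real_
  }
  ## RNG state continues past condition A, so B's noise is independent
  ds_b <- render_dataset(truth_b, spec$times_h, condition_b, genotype_b)
  ds_a <- sim_a$dataset
  combined <- expression_dataset(
    cbind(ds_a$values, ds_b$values),
    rbind(ds_a$design, ds_b$design),
    ds_a$annotation)
  truth <- truth_a
  names(truth)[-1L] <- paste0(names(truth_a)[-1L], "_a")
  truth <- cbind(truth, stats::setNames(truth_b[-1L],
                                        paste0(names(truth_b)[-1L], "_b")))
  list(dataset_a = ds_a, dataset_b = ds_b, combined = combined,
       truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate promoter sequences with phase-coupled motif placement
#'
#' Backgrounds are i.i.d. uniform A/C/G/T sequences; with a per-gene
#' probability set by its phase (via `phase_rates`) or by `base_rate`,
#' one concrete instance of the motif (degenerate positions resolved
#' uniformly at random) is planted at a uniform -- or fixed -- offset.
#'
#' @param truth Truth data.frame with `gene_id` and `phase_h` columns
#'   (from [simulate_expression]).
#' @param pattern IUPAC motif pattern to plant.
#' @param base_rate Planting probability for genes not covered by
#'   `phase_rates` (and for arrhythmic genes).
#' @param phase_rates Optional named numeric vector mapping phase labels
#'   (as characters) to planting probabilities.
#' @param length_bp Promoter length (default 500).
#' @param offset_bp Fixed offset (bp upstream of TSS, position of the
#'   match's 3'-most base) or `NULL` for uniform placement.
#' @param seed Integer seed.
#' @return List `promoters` (named character vector), `truth`
#'   (data.frame `gene_id`, `carrier`, `offset_bp`).
#' @export
simulate_promoters <- function(truth, pattern, base_rate = 0.1,
                               phase_rates = NULL, length_bp = 500L,
                               offset_bp = NULL, seed) {
  if (missing(seed)) stop2("'seed' is required")
  pattern <- check_iupac(pattern)
  k <- nchar(pattern)
  if (k > length_bp) stop2("motif longer than promoter")
  rates <- rep(base_rate, nrow(truth))
  if (!is.null(phase_rates)) {
    idx <- match(as.character(truth$phase_h), names(phase_rates))
    rates[!is.na(idx)] <- phase_rates[idx[!is.na(idx)]]
  }
  if (any(rates < 0 | rates > 1)) stop2("rates must lie in [0, 1]")
  set.seed(seed)
  iupac_sets <- list(A = "A", C = "C", G = "G", T = "T",
                     R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                     W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                     B = c("C", "G", "T"), D = c("A", "G", "T"),
                     H = c("A", "C", "T"), V = c("A", "C", "G"),
                     N = c("A", "C", "G", "T"))
  pat_chars <- strsplit(pattern, "")[[1L]]
  promoters <- character(nrow(truth))
  carrier <- stats::runif(nrow(truth)) < rates
  offsets <- rep(NA_integer_, nrow(truth))
  for (i in seq_len(nrow(truth))) {
    seq_chars <- sample(c("A", "C", "G", "T"), length_bp, replace = TRUE)
    if (carrier[i]) {
      inst <- vapply(iupac_sets[pat_chars], function(s)
        if (length(s) == 1L) s else sample(s, 1L), character(1))
      off <- if (is.null(offset_bp))
        sample(seq_len(length_bp - k + 1L), 1L) else as.integer(offset_bp)
      ## offset is bp upstream of TSS of the 3'-most base; the sequence is
      ## written 5'->3', TSS after the last base
      start <- length_bp - off - k + 2L
      seq_chars[start:(start + k - 1L)] <- inst
      offsets[i] <- off
    }
    promoters[i] <- paste(seq_chars, collapse = "")
  }
  names(promoters) <- truth$gene_id
  list(promoters = promoters,
       truth = data.frame(gene_id = truth$gene_id, carrier = carrier,
                          offset_bp = offsets))
}

#' Write promoters as FASTA
#'
#' @param promoters Named character vector of sequences.
#' @param path Output FASTA path.
#' @export
write_promoters <- function(promoters, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(promoters), path)
  invisible(path)
}
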