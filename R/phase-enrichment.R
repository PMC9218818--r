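#' Genes in a rolling four-phase window
#'
#' A window labelled by center `c` covers the circular phase labels
#' `{c-1, c, c+1, c+2}` (an even-width window has no exact centre; this
#' anchoring is the package convention and is configurable through
#' `width`/`offset` in [zscore_profile]). Windows roll by one phase
#' label, so each gene falls in exactly `width` windows.
#'
#' @param phases Phases of rhythmic genes (on the phase grid).
#' @param center Window centre label.
#' @param width Window width in phase labels (default 4).
#' @param period_h,phase_step_h Phase grid.
#' @return Logical vector: gene in window.
#' @export
window_membership <- function(phases, center, width = 4L, period_h = 24,
                              phase_step_h = 1) {
  n_lab <- period_h / phase_step_h
  start <- center / phase_step_h - floor((width - 1) / 2)
  labels <- ((start + seq_len(width) - 1L) %% n_lab) * phase_step_h
  phases %in% labels
}

#' Bootstrap null for a window's carrier count
#'
#' Draws `B` random groups of `group_size` genes, sampled without
#' replacement within each group from all rhythmic genes (the observed
#' window's genes included), and returns the mean and sample standard
#' deviation (denominator `B - 1`) of the number of element carriers per
#' group.
#'
#' @param carrier_flags Logical vector over all rhythmic genes.
#' @param group_size Number of genes in the observed window.
#' @param B Number of bootstrap groups (default 100).
#' @return List `mean`, `sd`; `group_size = 0` gives `(0, 0)`.
#' @export
bootstrap_null <- function(carrier_flags, group_size, B = 100L) {
  stopifnot(B >= 2L, group_size <= length(carrier_flags))
  if (group_size == 0L) return(list(mean = 0, sd = 0))
  counts <- vapply(seq_len(B), function(b)
    sum(sample(carrier_flags, group_size, replace = FALSE)), numeric(1))
  list(mean = mean(counts), sd = stats::sd(counts))
}

#' Three-point circular moving average
#'
#' Each entry is replaced by the mean of itself and its two circular
#' neighbours. `NA` entries (undefined z-scores from zero-sd windows)
#' stay `NA` and are excluded from their neighbours' means (reduced
#' denominator).
#'
#' @param z Numeric vector, length >= 3, possibly with `NA`s.
#' @return Smoothed vector of the same length.
#' @export
smooth3_circular <- function(z) {
  n <- length(z)
  if (n < 3L) stop2("smoothing needs length >= 3")
  prev <- z[c(n, seq_len(n - 1L))]
  nxt <- z[c(seq_len(n)[-1L], 1L)]
  out <- rowMeans(cbind(prev, z, nxt), na.rm = TRUE)
  out[is.na(z)] <- NA_real_
  out[is.nan(out)] <- NA_real_
  out
}

#' Rolling-window bootstrap z-score profile of phase enrichment
#'
#' For each phase label, counts the element-carrying genes among rhythmic
#' genes whose phase falls in the four-phase window at that label,
#' compares the count against a bootstrap null (`B` random same-size
#' groups drawn from all rhythmic genes), and reports
#' `z = (observed - null_mean)/null_sd`, its 3-point circular moving
#' average, and significance masks at the two-sided standard-normal 0.05
#' critical value 1.96 for both the raw and the smoothed z.
#'
#' @param calls `rhythm_calls` data.frame (only rhythmic genes are used).
#' @param carrier_flags Named logical vector: does each gene's promoter
#'   carry the element. Must cover every rhythmic gene.
#' @param window Window width in phase labels (default 4).
#' @param B Bootstrap groups per window (default 100).
#' @param seed Integer seed; required, so profiles are reproducible.
#' @param z_crit Significance threshold (default 1.96).
#' @param period_h,phase_step_h Phase grid.
#' @return A `phase_enrichment_profile` data.frame with one row per
#'   window: `center`, `n_window`, `observed`, `null_mean`, `null_sd`,
#'   `z`, `z_smoothed`, `significant_raw`, `significant` (smoothed mask).
#'   Zero-sd windows have `NA` z (flagged, never +/-Inf).
#' @export
zscore_profile <- function(calls, carrier_flags, window = 4L, B = 100L,
                           seed, z_crit = 1.96, period_h = 24,
                           phase_step_h = 1) {
  if (missing(seed)) stop2("'seed' is required for the bootstrap")
  rhythmic <- calls[calls$rhythmic, , drop = FALSE]
  if (nrow(rhythmic) == 0L) stop2("no rhythmic genes")
  miss <- setdiff(rhythmic$probe_id, names(carrier_flags))
  if (length(miss))
    stop2("carrier_flags missing for ", length(miss), " rhythmic gene(s)")
  flags <- as.logical(carrier_flags[rhythmic$probe_id])
  centers <- seq(0, period_h - phase_step_h, by = phase_step_h)

  set.seed(seed)
  res <- lapply(centers, function(cen) {
    memb <- window_membership(rhythmic$phase, cen, window, period_h,
                              phase_step_h)
    n_win <- sum(memb)
    obs <- sum(flags & memb)
    null <- bootstrap_null(flags, n_win, B)
    z <- if (n_win == 0L || null$sd == 0) NA_real_ else
      (obs - null$mean) / null$sd
    data.frame(center = cen, n_window = n_win, observed = obs,
               null_mean = null$mean, null_sd = null$sd, z = z)
  })
  prof <- do.call(rbind, res)
  prof$z_smoothed <- smooth3_circular(prof$z)
  prof$significant_raw <- !is.na(prof$z) & abs(prof$z) > z_crit
  prof$significant <- !is.na(prof$z_smoothed) & abs(prof$z_smoothed) > z_crit
  attr(prof, "window") <- window
  attr(prof, "B") <- B
  attr(prof, "seed") <- seed
  class(prof) <- c("phase_enrichment_profile", "data.frame")
  prof
}

#' Exact (hypergeometric) moments of the bootstrap null
#'
#' The infinite-B limit of [bootstrap_null]: drawing `n` genes without
#' replacement from `N` rhythmic genes of which `K` are carriers gives a
#' hypergeometric carrier count with mean `n*K/N` and variance
#' `n*(K/N)*(1-K/N)*(N-n)/(N-1)`. Used as a test oracle; the analysis
#' path always uses the bootstrap itself.
#'
#' @param N Number of rhythmic genes.
#' @param K Number of carriers among them.
#' @param n Window size.
#' @return List `mean`, `sd`.
#' @export
hypergeom_null_moments <- function(N, K, n) {
  m <- n * K / N
  v <- if (N > 1) n * (K / N) * (1 - K / N) * (N - n) / (N - 1) else 0
  list(mean = m, sd = sqrt(v))
}
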