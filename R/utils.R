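#' Circadian time of a sample
#'
#' Maps hours since transfer to constant light onto the circadian cycle.
#' Phase labels throughout the package refer to hours after subjective dawn,
#' where dawn is lights-on at the moment of transfer.
#'
#' @param t_h Hours since transfer to constant light (non-negative).
#' @param period_h Circadian period in hours (default 24).
#' @return Numeric in `[0, period_h)`.
#' @examples
#' circadian_time(c(24, 32, 68))
#' @export
circadian_time <- function(t_h, period_h = 24) {
  stopifnot(is.numeric(t_h), all(t_h >= 0), period_h > 0)
  t_h %% period_h
}

#' Minimal signed circular phase difference
#'
#' Signed difference `phase_b - phase_a` mapped into
#' `(-period/2, period/2]`; the antipodal case maps to `+period/2`.
#'
#' @param phase_a,phase_b Phases in `[0, period)`.
#' @param period_h Circadian period in hours.
#' @return Signed hours; positive means B peaks later than A.
#' @examples
#' circular_phase_shift(23, 1)   # +2, across midnight
#' circular_phase_shift(0, 12)   # +12 by convention
#' @export
circular_phase_shift <- function(phase_a, phase_b, period_h = 24) {
  d <- (phase_b - phase_a) %% period_h
  ifelse(d > period_h / 2, d - period_h, d)
}

## circular distance between two circadian times, in [0, period/2]
circ_dist <- function(a, b, period_h = 24) {
  d <- abs(a - b) %% period_h
  pmin(d, period_h - d)
}

## circular median of signed phase shifts: the shift minimising the summed
## circular distance to all shifts, restricted to observed values (ties ->
## smallest value), then re-signed into (-period/2, period/2]
circular_median_shift <- function(shifts, period_h = 24) {
  if (length(shifts) == 0L) return(NA_real_)
  ang <- shifts %% period_h
  cand <- sort(unique(ang))
  cost <- vapply(cand, function(c) sum(circ_dist(ang, c, period_h)), numeric(1))
  best <- cand[which.min(cost)]
  circular_phase_shift(0, best, period_h)
}

stop2 <- function(...) stop(..., call. = FALSE)

msg_log <- function(..., verbose = getOption("circadiome.verbose", TRUE)) {
  if (isTRUE(verbose)) message(...)
}
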