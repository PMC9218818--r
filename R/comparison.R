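#' Compare two circadiomes
#'
#' Partitions the union of rhythmic genes in two call sets into genes
#' rhythmic only in A, only in B, and in both; attributes the loss of
#' rhythmicity of A-only genes to the failing criterion in B (correlation
#' vs amplitude); cross-tabulates phases over the shared set; and reports
#' the circular median phase shift B - A.
#'
#' @param calls_a,calls_b `rhythm_calls` data.frames sharing a probe
#'   universe (at least in part; fully disjoint universes are an error).
#' @param period_h,phase_step_h Phase grid for the cross-tab.
#' @return A `circadiome_comparison` list: `set_a_only`, `set_b_only`,
#'   `set_both` (probe ids), `failure_breakdown` (named fractions for the
#'   lost set), `phase_crosstab`, `phase_shift_median_h`, `n_rhythmic_a`,
#'   `n_rhythmic_b`.
#' @export
compare_rhythm_sets <- function(calls_a, calls_b, period_h = 24,
                                phase_step_h = 1) {
  common <- intersect(calls_a$probe_id, calls_b$probe_id)
  if (length(common) == 0L) stop2("call sets share no probes")
  rhythmic_a <- calls_a$probe_id[calls_a$rhythmic]
  rhythmic_b <- calls_b$probe_id[calls_b$rhythmic]
  set_both <- intersect(rhythmic_a, rhythmic_b)
  set_a_only <- setdiff(rhythmic_a, rhythmic_b)
  set_b_only <- setdiff(rhythmic_b, rhythmic_a)

  lost <- calls_b[match(intersect(set_a_only, calls_b$probe_id),
                        calls_b$probe_id), , drop = FALSE]
  breakdown <- if (nrow(lost) == 0L) {
    c(fails_correlation = NA_real_, fails_amplitude = NA_real_)
  } else {
    c(fails_correlation = mean(lost$failure_reason == "fails_correlation"),
      fails_amplitude = mean(lost$failure_reason == "fails_amplitude"))
  }

  crosstab <- phase_crosstab(calls_a, calls_b, set_both, period_h,
                             phase_step_h)
  shifts <- circular_phase_shift(
    calls_a$phase[match(set_both, calls_a$probe_id)],
    calls_b$phase[match(set_both, calls_b$probe_id)], period_h)
  cmp <- structure(
    list(set_a_only = set_a_only, set_b_only = set_b_only,
         set_both = set_both, failure_breakdown = breakdown,
         phase_crosstab = crosstab,
         phase_shifts = shifts,
         phase_shift_median_h = circular_median_shift(shifts, period_h),
         n_rhythmic_a = length(rhythmic_a),
         n_rhythmic_b = length(rhythmic_b)),
    class = "circadiome_comparison")
  msg_log(sprintf(
    "compare_rhythm_sets: %d rhythmic in A, %d in B, %d shared (%.0f%% of A)",
    length(rhythmic_a), length(rhythmic_b), length(set_both),
    if (length(rhythmic_a)) 100 * length(set_both) / length(rhythmic_a) else 0))
  cmp
}

#' @export
print.circadiome_comparison <- function(x, ...) {
  cat("circadiome_comparison\n")
  cat("  rhythmic in A: ", x$n_rhythmic_a, ", in B: ", x$n_rhythmic_b,
      ", both: ", length(x$set_both), "\n", sep = "")
  if (!anyNA(x$failure_breakdown))
    cat(sprintf("  A-only genes failing in B: %.0f%% correlation, %.0f%% amplitude\n",
                100 * x$failure_breakdown[["fails_correlation"]],
                100 * x$failure_breakdown[["fails_amplitude"]]))
  cat("  median phase shift (B - A): ",
      format(x$phase_shift_median_h, digits = 3), " h\n", sep = "")
  invisible(x)
}

#' Phase cross-tabulation of shared rhythmic genes
#'
#' Entry `(i, j)` counts the genes with phase label `i` in A and `j` in B;
#' entries sum to the size of the shared set.
#'
#' @inheritParams compare_rhythm_sets
#' @param shared Probe ids rhythmic in both call sets.
#' @return Integer matrix, phases A (rows) x phases B (columns).
#' @export
phase_crosstab <- function(calls_a, calls_b, shared, period_h = 24,
                           phase_step_h = 1) {
  phases <- seq(0, period_h - phase_step_h, by = phase_step_h)
  pa <- factor(calls_a$phase[match(shared, calls_a$probe_id)],
               levels = phases)
  pb <- factor(calls_b$phase[match(shared, calls_b$probe_id)],
               levels = phases)
  if (anyNA(pa) || anyNA(pb))
    stop2("shared probes must be rhythmic (with on-grid phases) in both sets")
  unclass(table(phase_a = pa, phase_b = pb))
}

#' Histogram of phases among rhythmic genes
#'
#' @param calls A `rhythm_calls` data.frame.
#' @param period_h,phase_step_h Phase grid.
#' @return Named integer vector, one count per phase label; sums to the
#'   number of rhythmic genes.
#' @export
phase_histogram <- function(calls, period_h = 24, phase_step_h = 1) {
  phases <- seq(0, period_h - phase_step_h, by = phase_step_h)
  p <- factor(calls$phase[calls$rhythmic], levels = phases)
  c(unclass(table(p)))
}

#' Mean-expression change between two groups by phase
#'
#' For each gene, the log2 ratio of its mean expression in group B to
#' group A; genes are binned over (phase in the reference group A,
#' log2-change bin with log2-progression edges). Gene sets changing at
#' least `fold` up (`mean_B >= fold * mean_A`) or down
#' (`mean_B <= mean_A / fold`) are returned alongside.
#'
#' @param ds An [expression_dataset] containing both groups.
#' @param group_a,group_b Named vectors/lists with `condition`, `genotype`.
#' @param genes Probe ids to profile (typically rhythmic in A).
#' @param phase_source `rhythm_calls` supplying each gene's phase in the
#'   reference group A.
#' @param fold Fold-change threshold for the up/down sets (default 1.5).
#' @param log2_edges Interior bin edges for the log2 change, mirrored
#'   around 0 with open outer bins.
#' @return An `expression_change_profile` list: `log2_change` (named),
#'   `histogram` (phase x change-bin counts), `up_set`, `down_set`,
#'   `skipped` (genes with non-positive means).
#' @export
expression_change_profile <- function(ds, group_a, group_b, genes,
                                      phase_source, fold = 1.5,
                                      log2_edges = c(0.25, 0.5, 1, 2, 4)) {
  stopifnot(inherits(ds, "expression_dataset"))
  cols_a <- group_columns(ds, group_a[["condition"]], group_a[["genotype"]])
  cols_b <- group_columns(ds, group_b[["condition"]], group_b[["genotype"]])
  genes <- intersect(genes, rownames(ds$values))
  mean_a <- rowMeans(ds$values[genes, cols_a, drop = FALSE])
  mean_b <- rowMeans(ds$values[genes, cols_b, drop = FALSE])
  bad <- mean_a <= 0 | mean_b <= 0
  skipped <- genes[bad]
  if (any(bad))
    warning(sum(bad), " gene(s) skipped: non-positive group mean",
            call. = FALSE)
  genes <- genes[!bad]; mean_a <- mean_a[!bad]; mean_b <- mean_b[!bad]
  lfc <- log2(mean_b / mean_a)
  names(lfc) <- genes

  edges <- c(-Inf, -rev(log2_edges), log2_edges, Inf)
  bins <- cut(lfc, breaks = edges, right = TRUE)
  phase <- phase_source$phase[match(genes, phase_source$probe_id)]
  phases <- sort(unique(phase_source$phase))
  hist2 <- unclass(table(phase = factor(phase, levels = phases),
                         change = bins))
  profile <- structure(
    list(log2_change = lfc, histogram = hist2,
         up_set = genes[mean_b >= fold * mean_a],
         down_set = genes[mean_b <= mean_a / fold],
         skipped = skipped),
    class = "expression_change_profile")
  msg_log(sprintf(
    "expression_change_profile: %d genes, %d up >= %.2g-fold, %d down",
    length(genes), length(profile$up_set), fold, length(profile$down_set)))
  profile
}
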