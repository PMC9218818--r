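---
title: "Detecting and comparing circadian transcriptomes with sine-template correlation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and comparing circadian transcriptomes with sine-template correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circadiome)
options(circadiome.verbose = FALSE)
```

## The problem and the model

Constant-light ("free-running") expression time courses in plants are
typically short and sparsely sampled — here, two schedules: twelve
samples at 4-h intervals over two cycles (the "white" design) and four
samples at 8-h intervals over a single cycle (the "red" design). With 4
data points per gene, periodogram- or harmonic-regression-based
rhythm detectors have no room to work; the approach implemented here
instead asks a simpler, well-posed question: *how well does each gene's
profile correlate with a 24-h cosine, and at which phase?*

The template family is

$$ s_p(t) = \mu + A \cos\left(\frac{2\pi (t - p)}{T}\right),\qquad
   p \in \{0, 1, \ldots, T-1\},\ T = 24\ \mathrm{h}, $$

evaluated at the sample clock times. Each template peaks at circadian
time $p$ (hours after subjective dawn, dawn = lights-on at transfer),
so the best-correlating template's label *is* the gene's phase of peak
expression. Because Pearson correlation is invariant to the template's
location and scale, $\mu$ and $A$ are cosmetic; the conventional value
60 is kept as a default and the test suite asserts that calls are
identical with $\mu = A = 0.001$.

A gene is called **rhythmic** when both of the following hold.

1. *Correlation.* The maximal $r$ over the 24 phases is significant
   under a $t$-test for correlation, $t = r\sqrt{(n-2)/(1-r^2)}$ with
   $n - 2$ degrees of freedom, at $\alpha = 0.01$. $n$ is the number of
   samples correlated (12 or 4), not the number of distinct circadian
   times. The test is two-sided by default even though the max-over-
   phases construction makes $r \ge 0$ in practice; a one-sided switch
   exists. No multiplicity correction is applied across genes or across
   the 24 scanned phases — the acceptance suite *measures* the resulting
   inflation of the per-gene false-positive rate (scanning 24 templates
   on pure noise yields an empirical rate above the nominal 1%) instead
   of silently correcting a procedure whose published form does not
   correct it.
2. *Amplitude.* At least one of:
   - **Extrapolated fold change.** The observed fold change between the
     samples nearest the fitted peak and trough is compared with the
     fold change a reference cosine of the same phase, mean equal to the
     series mean, and an exact 1.5 peak-to-trough ratio would show *at
     those same samples*; `predicted_fc = 1.5 * FC_obs / FC_ref` and the
     criterion is `predicted_fc >= 1.5`. Defining it this way makes the
     pass condition read exactly as "a predicted 1.5-fold change".
   - **Absolute change.** `max - min >= k * grand_mean`, the grand mean
     being the mean of all retained probe values across all arrays.

Failure attribution is two-valued: `fails_correlation` when criterion 1
fails (including degenerate flat series, recorded with $r = 0$,
$p = 1$), otherwise `fails_amplitude`.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `period_h` | 24 | h | fixed, never estimated; the method is a fixed-period classifier |
| `phase_step_h` | 1 | h | phase resolution of the template bank; must divide the period |
| `alpha` | 0.01 | — | correlation significance level |
| `fold_threshold` | 1.5 | fold | peak/trough ratio of the reference wave |
| `abs_change_multiplier` | *required* | × grand mean | see below |
| `floor_fraction` | 0.05 | × grand mean | expressed-gene floor |

`abs_change_multiplier` deliberately has **no default**. The published
procedure states an absolute-change threshold of "250 times" the grand
mean, which on any normalized scale would exclude essentially every
gene; whether 250 is a multiplier, a raw-unit threshold on a particular
scanner scale, or a typo cannot be resolved from the published description. The package
therefore refuses to guess: `rhythm_params()` errors unless a value is
given. `0` disables the criterion (the fold-change test then decides
alone), `2.5` is a plausible permissive reading, `250` the literal one.

Two numerical choices are load-bearing:

- the fold-criterion comparison uses `>= fold_threshold - 1e-9`, so a
  noiseless series with a peak/trough ratio of exactly 1.5 — for which
  `FC_obs` and `FC_ref` are equal by construction — passes at the
  boundary instead of failing to floating-point rounding;
- all tie-breaks are deterministic (smallest phase label at equal $r$,
  earliest sampling time at equal circular distance to an extremum), so
  runs are bit-reproducible.

Circadian time is derived (`t mod 24`) and never stored; templates are
evaluated at clock time, which is identical for a pure 24-h cosine.

## Filtering

Before classification, probes without a gene assignment and probes for
mitochondrially or chloroplast-encoded genes are dropped
(`filter_annotation`), and non-expressed probes are removed: a probe is
discarded only when its mean expression is below 5% of the grand mean in
*every* (condition, genotype) group considered (`filter_expressed`).
The grand mean is recomputed after each filtering step, and the value
the amplitude criterion sees is the one current at classification time;
the published procedure does not state which snapshot it used, and with the filters
applied in the documented order the difference is a few percent of a
threshold the user sets anyway. Missing values are an ingestion error,
never imputed. `rescale_arrays()` offers per-array median equalisation
as a convenience and logs loudly that it is *not* model-based array
normalization, which is out of scope.

## Circadiome comparison

`compare_rhythm_sets` partitions the union of two rhythm sets into
A-only / B-only / shared, attributes each lost gene to the criterion it
failed in B, cross-tabulates phases over the shared set, and reports the
circular median of the signed phase shifts $B - A$ mapped into
$(-12, 12]$ (the antipodal case maps to $+12$ by convention).
`expression_change_profile` bins per-gene log2 mean-expression changes
against phase in the reference condition, with symmetric log2-
progression bin edges at ±{0.25, 0.5, 1, 2, 4} (open outer bins — the
published description states only that bins "follow a log2 progression") and 1.5-fold
up/down gene sets. The reference condition for phases is always group A.

## Promoter elements and phase enrichment

Scanning covers the 500 bp upstream of the TSS, both strands, exact
IUPAC matching with overlaps, offsets reported as bp upstream of the TSS
(1-based, measured at the match's TSS-nearest base; the promoter is
supplied 5'→3' on the gene's strand, last base adjacent to the TSS).
Degenerate bases in the *promoter* never match. Matching is delegated to
Biostrings (`vmatchPattern(fixed = "subject")`), with an independent
regular-expression oracle in the test suite; element presence (not
count) feeds enrichment statistics, since presence is what the original
analysis reports. The recognised element set is the evening element
AAAATATC, the TBS sites GGTCC/GGACC and GGCCCA/TGGGCC, the G-box CACGTG,
the fbs CACGCGC, the GA motifs GAGAGAGAGA and RRAGAAGAAG, and the
morning element — for which no consensus sequence accompanies the published element list; the
field-standard consensus CCACAC is used and flagged as this package's
choice.

Phase enrichment of element carriers uses a rolling window of four
phases. A four-wide window has no exact centre: the convention here is
that the window labelled $c$ covers $\{c-1, c, c+1, c+2\}$ circularly
(configurable), so each gene lies in exactly four windows. For each
window, 100 random groups of the same size are drawn without replacement
from all rhythmic genes (window genes included), and
$z = (\mathrm{observed} - \mathrm{null\ mean})/\mathrm{null\ sd}$ with
the $B-1$ sd denominator. Zero-sd windows yield an explicit NA flag,
never ±Inf. Profiles carry both the raw and the 3-point circularly
smoothed $z$ (NA entries excluded from neighbours' means), and both
±1.96 significance masks, because whether the original ±1.96 test was
applied before or after smoothing is not stated. The bootstrap is the
analysis path; the hypergeometric closed form of its infinite-$B$ limit
is provided only as a test oracle (`hypergeom_null_moments`).

A property worth knowing before trusting the mask: under a null in which
carrier status is independent of phase but carriers are *sparse* (a few
chance matches among hundreds of genes), some window exceeds
$|z_{smoothed}| > 1.96$ in roughly a third of runs — 24 correlated
windows at a per-window level near 5% make an any-window false positive
common. The acceptance report measures this rate
(`c6_chance_carrier_spurious_rate`) rather than hiding it; single-window
significance calls from this procedure should be treated as descriptive.

## The synthetic world

`simulate_expression` generates
$y_g(t) = \max\{\varepsilon,\ m[1 + a(t)\cos(2\pi(t-\varphi)/24)] + \epsilon_t\}$
with relative amplitude $a(t) = a_0 e^{-\lambda t/24}$,
$a_0 = (\rho-1)/(\rho+1)$ for peak/trough ratio $\rho$, additive
Gaussian noise of sd `noise_sd_frac`·$m$, and $\varepsilon = 10^{-6}$ as
a positivity floor. Defaults state the world the analysis assumes:
the two published sampling schedules as presets, mean level 100,
peak/trough ratio 2.5 (a mid-range rhythmic gene), 10% noise, no
damping. Noise is additive on the linear scale because the classifier
operates on that scale; a damping term exists because damped oscillation
is the central biological phenomenon the comparison machinery is asked
to detect. Restricted to zero noise and zero damping the signal family
*is* the classifier's template family, so exact recovery there is a
consistency check, not evidence of power. What the generator does not
emulate — probe-level microarray error structure, cross-hybridization,
normalization artifacts, non-sinusoidal waveforms — bounds what a green
test establishes: correctness of the procedure, not field performance on
arrays.

`simulate_paired` derives a second condition by per-gene phase delays,
relative-amplitude scaling, mean scaling and forced arrhythmicity;
`simulate_promoters` plants one concrete motif instance per carrier
(degenerate codes resolved uniformly) into i.i.d. uniform-base 500-bp
backgrounds at phase-coupled rates. In the paired acceptance scenario
the amplitude-loss genes use `amplitude_scale = 0.15` with 2% noise:
chosen so the residual oscillation still correlates significantly
(the loss is attributed to the *amplitude* criterion, as programmed)
while falling far below the 1.5-fold threshold — i.e. the scenario the
failure-attribution machinery exists to distinguish.

## Known limitations

- Fixed 24-h period; no period estimation, harmonics, or replicates.
- The 24-phase scan inflates the per-gene type-I error above $\alpha$
  (measured in the acceptance suite); comparisons between two call sets
  made with the same procedure remain interpretable, absolute rhythmic
  fractions less so.
- With 4-point schedules the critical correlation is ≈0.990: calls are
  driven almost entirely by the amplitude criteria, and phase resolution
  is effectively 8 h despite the 1-h label grid.
- The headline gene counts of the original array study depend on its
  accession data and normalization and are not reproduced here; every
  number this package's documentation states is computed by its own
  tests or acceptance script on synthetic data.
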