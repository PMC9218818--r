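Package: circadiome
Title: Circadian Transcriptome Rhythmicity Analysis by Sine-Template Correlation
Version: 0.1.0
Authors@R:
    person("Circadiome", "Maintainers", email = "maintainers@circadiome.org",
           role = c("aut", "cre"))
Description: Detects circadian rhythmicity in gene expression time courses
    sampled under constant light using phase-scanned sine-template Pearson
    correlation combined with dual peak-to-trough amplitude criteria, and
    assigns a phase of peak expression to each rhythmic gene. Provides
    machinery to compare circadiomes between light conditions or genotypes
    (shared/lost gene sets with failure-reason attribution, phase cross-tabs
    and histograms, mean-expression-change profiles), to scan 500-bp promoter
    sequences for IUPAC cis-regulatory elements on both strands, and to test
    phase-specific over-representation of element-carrying genes with a
    rolling-window bootstrap z-score. A fully parameterised synthetic-data
    generator with known ground truth (cosine signal, additive noise,
    amplitude damping, paired-condition effects, phase-coupled promoter
    motif placement) makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
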