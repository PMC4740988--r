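Package: histoneptm
Title: Quantitative Histone PTM Profiling and Differential ChIP Peak Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for bottom-up mass-spectrometry quantification of
    combinatorial histone peptidoforms (extracted ion chromatograms at ppm
    tolerance, isobaric apportionment, per-family relative ratios),
    derivation of single-mark and acetyl-state abundance profiles with
    technical-replicate averaging and row z-scoring, time-course ANOVA and
    treatment t-test statistics with log2 fold changes, PCA of PTM
    profiles, and classification of ChIP-seq peaks into population-specific
    versus constitutive classes from RPM-normalized binned coverage.
    Includes a ground-truthed synthetic-data generator (peptidoform
    libraries from derivatization rules, log-normally noisy peak areas over
    a time-course design, centroid spectra, Poisson ChIP coverage) so the
    whole pipeline runs end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
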