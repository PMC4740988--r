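---
title: "Quantifying combinatorial histone PTMs and differential ChIP peaks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying combinatorial histone PTMs and differential ChIP peaks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histoneptm)
```

## The problem

Bottom-up histone proteomics measures the abundance of post-translational
modifications (PTMs) — acetylation (`ac`) and mono-, di- and tri-methylation
(`me1/2/3`) of lysines — on short tryptic peptides of histones H3 and H4.
Because one peptide can carry several modifiable lysines, the measured unit
is the *peptidoform*: one combinatorial modification state of one peptide
backbone. The H4 peptide spanning residues 4–17 (`GKGGKGLGKGGAKR`) carries
all four H4 acetylation sites (K5, K8, K12, K16), so its sixteen forms
resolve the degree of multiple acetylation — the binding substrate of
bromodomain readers such as Brd4 — which single-mark assays like Western
blotting cannot.

This package implements the full quantitative workflow on such data, from
centroided spectra to differential statistics, together with a companion
genomic stage that classifies ChIP-seq peaks of two cell populations into
population-specific and constitutive sets. Every stage runs against a
ground-truthed synthetic-data generator, so the whole pipeline is testable
end to end without any external download.

## Derivatization chemistry and masses

Histones are derivatized with propionic anhydride before and after trypsin
digestion. The mass model therefore propionylates (+56.026215 Da) the
peptide N-terminus and the side chain of every lysine that is unmodified or
monomethylated; acetylated, dimethylated and trimethylated lysines block
the reaction. A consequence worth knowing when reading m/z tables: relative
to the propionylated unmodified lysine, *acetylation reduces* the form's
mass by 56.026215 − 42.010565 = 14.01565 Da. Monoisotopic residue and
modification masses are embedded as a single table with standard
IUPAC/Unimod values. Neutral masses are exact sums; m/z at charge $z$ is
$(M + z \cdot 1.007276)/z$.

```{r}
lib <- default_histone_library()
lib[c(1, 2, 16), c("key", "neutral_mass", "n_acetyl")]
```

The stock library holds three families: H4 4–17 (16 forms), H3 3–8 (K4
methylation, 4 forms) and H3 9–17 (K9 × K14, 10 forms). Positional acetyl
isomers (e.g. the four singly acetylated H4 forms) are isobaric and are
assigned to one co-eluting m/z group.

## Quantification model

For each target m/z an extracted ion chromatogram (EIC) sums, per scan, all
centroid intensities within a ±10 ppm window (boundary inclusive, with a
relative epsilon guard of 1e−9 so a centroid placed exactly on the boundary
matches despite floating-point rounding). The peak area is the trapezoidal
integral over the elution window, taken as apex ±3 elution widths, which
captures 99.73% of a Gaussian elution profile — the source of the ≤1%
quadrature tolerance quoted by the end-to-end tests. Isobar groups share one
EIC; the shared area is split linearly in proportion to each form's
unique-fragment intensity. This linear rule is a deliberate simplification
of fragment-ratio deconvolution as practised by dedicated histone software;
with noiseless fragment summaries it is exact, and the package documents it
as its own convention rather than a reimplementation of any particular tool.

The *relative ratio* of a form is its area divided by the total area of its
peptide family (all forms sharing backbone and span) in the same sample.
Missing forms count as zero area; a family whose total is zero yields
undefined ratios for that sample, reported but never imputed. Defined
ratios sum to one per family and sample by construction, and the test suite
holds this to 1e−9 over a thousand random tables.

## Profiles and normalization

Sample IDs follow `<time>.<bio>.<tech>` with the default design of 5 time
points × 2 biological × 3 technical replicates. Downstream displays average
the three technical replicates first (arithmetic mean on the ratio scale,
excluding undefined cells), then compute:

* **single-mark abundances** — the marginal sum of ratios of every form in
  the mark's family carrying that mark (e.g. `H3K9me2` sums `K9me2_K14un`
  and `K9me2_K14ac`);
* **acetyl-state profiles** — sums by exact acetyl count (0–4) on H4 4–17,
  an exact partition of unity per sample;
* **row z-scores** — per row, $(x - \bar x)/s$ with the sample (n−1)
  standard deviation, for heatmap display. Constant rows become zeros with
  a warning rather than NaNs.

Averaging is done on ratios, not areas, and before z-scoring; whether the
original displays z-scored before or after technical averaging is not
determinable, so the averaged-first order is fixed here and the transposed
order can be had by composing the exported functions the other way.

## Statistics

*Time course.* Each feature gets a classical one-way fixed-effects ANOVA
across time points (`stats::oneway.test`, `var.equal = TRUE`). The
observations are replicate-level ratios; the function accepts either the
technical-replicate matrix (6 observations per time point under the default
design) or the biological-mean matrix (2 per time point). The power
property below is stated for replicate-level observations: with only two
biological means per group, each group variance carries a single degree of
freedom and the F-statistic's lower tail grows heavy enough that a 5-fold
effect is detected at p < 0.01 in only ~88% of runs, versus ~100% with
replicate-level observations under identical noise. Degenerate inputs are
flagged: zero within-group variance with unequal means returns the p → 0
limit, an all-constant feature returns p = 1.

*Treatment contrast.* The BET-inhibitor comparison uses the pooled-variance
two-tailed t-test with `log2_fc = log2(mean_treated/mean_control)`.
Significance is `p < 0.05`, equivalently `−log2 p > 4.32` (strict: p
exactly 0.05 is not significant). Raw p-values drive all flags, matching
the fixed-threshold convention of the source workflow; Benjamini–Hochberg
q-values are reported alongside as a clearly labelled extension. Fold
changes over a non-positive arm mean are left undefined rather than
pseudocounted. Concordance between two doses is the Pearson correlation of
log2 fold changes over the shared features; with a shared true effect of
variance $\sigma^2_e$ and independent per-dose noise $\sigma^2_n$, the
expected correlation is the attenuation ratio
$\sigma^2_e/(\sigma^2_e+\sigma^2_n)$, which the test suite verifies by
simulation.

*PCA* is covariance PCA (feature-centred, unscaled) via `stats::prcomp`,
returning scores, loadings and explained-variance fractions.

## ChIP peak classification

Coverage is handled as binned counts (default 50 bp bins) normalized to
reads per million mapped reads and multiplied by a global scale of 10. The
"10 reads per million" convention is ambiguous between a 10-RPM target and
reads-per-ten-million; both are monotone rescalings that cancel in every
ratio, so the package implements standard RPM × configurable scale and
leaves the scale at 10.

A peak is *specific* to population A when any 200 bp window inside it has
`(mean_A + c)/(mean_B + c) > 4` (pseudocount c = 0.1 RPM), *specific* to B
for the inverse, and *constitutive* otherwise. Windows are placed at
bin-size steps plus the two windows flush to the peak edges; because both
window means are piecewise-linear in the offset (for windows that are a
multiple of the bin size) and a ratio of linear functions is monotone
between grid crossings, this candidate set attains the exact maximum over
*all* integer offsets — the property the brute-force every-offset oracle in
the tests confirms on random fixtures. Peaks shorter than the window are
evaluated as a single window over themselves. If both directions exceed the
threshold in different windows the larger maximum wins and the peak is
flagged ambiguous. Raising the fold threshold can only shrink the specific
classes (monotonicity, tested).

Replicate peak calls are combined as a coalesced union (book-ended
intervals merge); an intersection mode is available. "Within 1 kbp" for
TF-binding-site overlap means minimal edge-to-edge distance ≤ 1000 bp with
overlap counting as zero — the generous reading, fixed here because the
source convention is unstated. All coordinates are 0-based half-open (BED);
bedGraph values are bin means.

## The synthetic generator: what it emulates and what it does not

Observed areas are `scale × true_ratio × LN_bio × LN_tech` with mean-one
lognormal multipliers — multiplicative noise is the natural choice for
strictly positive, right-skewed peak areas, and the biological draw is
shared across the technical replicates of one biological sample. The noise
magnitudes of real histone MS runs are not published for this workflow;
the defaults (technical CV 5%, biological CV 15%) are stated placeholders
chosen as ordinary values for targeted label-free quantification, not
inferred estimates. Time-course effects multiply the true abundances of
selected forms by per-time-point factors before renormalization, so
configured trajectories survive the ratio transform exactly in the
zero-noise limit (a test holds this to 1e−12).

Spectra are Gaussian elution profiles sampled on a 0.05 min grid with
elution width 0.2 min (plumbing defaults chosen for well-sampled peaks: 4
grid points per sigma); isobars co-elute by construction, distinct m/z
groups are spaced 2 min apart. ChIP coverage is Poisson per bin at a
background rate scaled by per-population enrichment factors inside truth
peaks.

The generator deliberately omits isotope envelopes, charge-state
distributions, chromatographic drift, peak-shape asymmetry, interfering
background ions, read mappability and GC bias. Passing tests therefore
demonstrate the *computational* correctness of the pipeline under its
stated statistical model, not robustness to every artefact of real
instruments or sequencers.

## Problem sizes and reproducibility

All simulation-backed checks use deliberately compact studies: the 30-form
stock library over the 5 × 2 × 3 design, 100 seeded recovery runs, 1000
null simulations for calibration, 100 random fixtures per brute-force
oracle, and 200 simulated ChIP peaks — sizes at which every property is
measurable in seconds while keeping Monte-Carlo error well inside the
asserted bands. Every stochastic stage takes an explicit seed, and equal
seeds reproduce byte-identical outputs; `scripts/acceptance.R` re-derives
all headline quantities from scratch for any seed.

## Known limitations

* Isobar apportionment is linear in one scalar fragment intensity per form;
  real fragment-level deconvolution uses many fragments with their own
  noise.
* No retention-time alignment: the quantifier trusts the elution map it is
  given, as appropriate for targeted acquisition.
* The hierarchical design (technical within biological) is analysed by
  plain ANOVA/t-tests, not mixed models — a faithful choice, with the
  caveats about observation units above.
* HOMER-style peak calling, read alignment and GO enrichment are upstream
  and downstream of this package's scope; peaks arrive as BED input.
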