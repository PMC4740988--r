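# histoneptm

Quantitative profiling of combinatorial histone post-translational
modifications (PTMs) from bottom-up mass spectrometry, with a companion
differential ChIP-seq peak classifier — the analysis stack behind studies of
chromatin-state dynamics during stem-cell differentiation, runnable end to
end on a ground-truthed synthetic data generator.

## Who this is for

Proteomics and epigenomics analysts who quantify propionylated tryptic
histone H3/H4 peptides by label-free extracted ion chromatography and need
the downstream arithmetic to be explicit, tested and reproducible:
peptidoform relative ratios, single-mark marginals, acetyl-state
distributions, time-course and treatment statistics, and
specific-versus-constitutive ChIP peak calls.

## The model in brief

* **Peptidoform quantification.** For a peptidoform with neutral
  monoisotopic mass *M* at charge *z*, the target is
  *m/z = (M + z·1.007276)/z*; derivatization adds a propionyl group
  (+56.026215 Da) to the N-terminus and to every unmodified or monomethyl
  lysine. The extracted ion chromatogram (EIC) sums centroid intensities
  within ±10 ppm per scan; its trapezoidal integral over the elution window
  is the peak area *A*. Co-eluting isobars split their shared area in
  proportion to unique-fragment intensities.
* **Relative ratio.** For form *i* in peptide family *F* (same backbone and
  span): *r_i = A_i / Σ_{j∈F} A_j*, so ratios sum to 1 per family and
  sample. A single mark's abundance is the marginal Σ of ratios over forms
  carrying it; H4 acetyl states sum ratios by exact acetyl count 0–4.
* **Statistics.** One-way fixed-effects ANOVA across time points per
  feature; pooled-variance two-tailed t-tests with
  log2 FC = log2(mean_treated/mean_control), significant iff p < 0.05
  (−log2 p > 4.32); Pearson concordance of fold changes between doses;
  covariance PCA of profiles.
* **ChIP classification.** Binned coverage → reads per million (×10 global
  scale); a peak is specific to a population if any 200 bp window inside it
  exceeds a 4-fold pseudocounted coverage ratio, else constitutive;
  replicate calls merge as a coalesced union; a TF site is "near" a peak if
  its edge-to-edge distance is ≤ 1 kbp.

## Worked example

```r
library(histoneptm)
rep <- run_demo_pipeline(seed = 1)
print(rep)
#> Histone PTM pipeline report (seed 1)
#>   peptidoforms: 30 in 3 families
#>   samples: 30 (5 time points x 2 bio x 3 tech)
#>   ANOVA: 6/12 marks change across the time course (p < 0.05)
#>   tetra-ac H4 trajectory: 0.058 -> 0.052 -> 0.029 -> 0.023 -> 0.014
#>   JQ1 dose concordance r = 0.829
#>   ChIP labels: constitutive=10, specific_A=10, specific_B=10 (accuracy 1.00)
#>   TF sites within 1000 bp of a peak: 0.50
```

The report composes every stage on one synthetic study. The tetra-acetyl H4
line is the mean relative abundance of the fully acetylated
`GKGGKGLGKGGAKR` (H4 4–17) peptidoform at each time point — the configured
monotone decline of hyperacetylated H4 recovered from the noisy simulated
areas. Drilling in:

```r
round(rep$acetyl_states[, c("ESC.1", "RA7d.1")], 4)
#>      ESC.1 RA7d.1
#> 0ac 0.0585 0.0811
#> 1ac 0.2491 0.6012
#> 2ac 0.3859 0.1968
#> 3ac 0.2447 0.1056
#> 4ac 0.0618 0.0153
```

Each column partitions 1 over acetyl counts: singly acetylated H4 rises
while the doubly/triply/tetra-acetylated states fall. The time-course ANOVA
table ranks marks by evidence of change
(`rep$anova`: e.g. `H4K8ac F = 18.6, p = 0.0033`), and the inhibitor
contrast returns per-mark fold changes with the −log2 p significance flag
(`rep$jq1$diff_200`: e.g. `H3K14ac log2FC = −0.44, −log2 p = 8.7`).

Individual stages are plain exported functions —
`build_peptidoform_library()`, `simulate_area_table()`,
`extract_ion_chromatogram()`, `relative_ratios()`,
`single_mark_abundance()`, `anova_timecourse()`, `classify_peaks()`,
`overlap_fraction()`, … — see the vignette in `vignettes/` for the model,
its assumptions and every numerical convention.

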