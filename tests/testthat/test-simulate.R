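lib <- default_histone_library()

test_that("ground-truth ratios partition each family and respect effects", {
  des <- sample_design()
  eff <- list(effect_spec(trajectory = c(1, .8, .6, .4, .2),
                          histone = "H4", acetyl_count = 4))
  sim <- simulate_area_table(lib, des, eff, tech_cv = 0, bio_cv = 0, seed = 7)
  fam <- histoneptm:::family_of(rownames(sim$truth))
  for (f in unique(fam)) {
    sums <- colSums(sim$truth[fam == f, , drop = FALSE])
    expect_true(all(abs(sums - 1) <= 1e-12))
  }
  # the targeted form's truth declines monotonically
  tetra <- sim$truth["H4:4-17:K5ac_K8ac_K12ac_K16ac", ]
  expect_true(all(diff(tetra) < 0))
})

test_that("zero-noise areas reproduce ground truth exactly via relative_ratios", {
  sim <- simulate_area_table(lib, sample_design(), list(),
                             tech_cv = 0, bio_cv = 0, seed = 1)
  ratios <- relative_ratios(sim$areas)
  tp <- parse_sample_ids(colnames(ratios))$time
  for (j in seq_len(ncol(ratios)))
    expect_equal(unname(ratios[, j]), unname(sim$truth[, tp[j]]),
                 tolerance = 1e-12)
})

test_that("identical seeds give byte-identical simulations", {
  a <- simulate_area_table(lib, sample_design(), demo_effects(), seed = 42)
  b <- simulate_area_table(lib, sample_design(), demo_effects(), seed = 42)
  expect_identical(a$areas, b$areas)
  s1 <- simulate_centroid_spectra(a$areas[, 1], lib, mz_jitter_ppm = 2, seed = 9)
  s2 <- simulate_centroid_spectra(a$areas[, 1], lib, mz_jitter_ppm = 2, seed = 9)
  expect_identical(s1$spectra, s2$spectra)
  pk <- data.frame(chrom = "chrT", start = 100L, end = 700L,
                   factor_a = 8, factor_b = 1)
  c1 <- simulate_chip_data(c(chrT = 5000L), pk, seed = 3)
  c2 <- simulate_chip_data(c(chrT = 5000L), pk, seed = 3)
  expect_identical(c1$track_a$counts, c2$track_a$counts)
})

test_that("a configured H3K4me1 decline is recovered in expectation", {
  # marginal trajectory ~17.1% -> ~13.0% across the course, as a fraction of
  # the K4 peptide family
  des <- sample_design(n_bio = 20, n_tech = 2)  # many replicates: this tests
  # the generator's expectation, so the mean must stand clear of the noise
  base <- stats::setNames(rep(NA_real_, nrow(lib)), lib$key)
  fam <- histoneptm:::family_of(lib$key)
  for (f in unique(fam)) base[fam == f] <- 1 / sum(fam == f)
  # weight the K4 family (me1 vs 3 other forms at weight 1 each) so the ESC
  # marginal is exactly 17.1%, and pick the end factor for a 13.0% marginal
  base[c("H3:3-8:K4un", "H3:3-8:K4me2", "H3:3-8:K4me3")] <- 1
  base["H3:3-8:K4me1"] <- 0.171 * 3 / (1 - 0.171)
  target_end <- 0.130
  w <- base[["H3:3-8:K4me1"]]
  f_end <- target_end * 3 / (1 - target_end) / w
  eff <- list(effect_spec(trajectory = seq(1, f_end, length.out = 5),
                          mark = "H3K4me1"))
  sim <- simulate_area_table(lib, des, eff, baseline = base,
                             tech_cv = 0.05, bio_cv = 0.15, seed = 11)
  marks <- single_mark_abundance(relative_ratios(sim$areas), lib)
  tp <- parse_sample_ids(colnames(marks))$time
  first <- mean(marks["H3K4me1", tp == "ESC"])
  last <- mean(marks["H3K4me1", tp == "RA7d"])
  expect_equal(first, 0.171, tolerance = 0.10)
  expect_equal(last, 0.130, tolerance = 0.10)
  expect_lt(last, first)
})

test_that("spectra generation conserves area and honors edge cases", {
  areas <- c("H4:4-17:K5ac_K8ac_K12ac_K16ac" = 5000)
  ss <- simulate_centroid_spectra(areas, lib, rt_grid = 0.01)
  el <- ss$elution[ss$elution$key == names(areas), ]
  chrom <- extract_ion_chromatogram(ss$spectra, el$mz, 10)
  area <- integrate_area(chrom, c(el$rt_mean - 3 * el$rt_width,
                                  el$rt_mean + 3 * el$rt_width))
  expect_gt(area / 5000, 0.99)
  expect_lt(area / 5000, 1.01)

  # zero-area forms emit no centroids
  ss0 <- simulate_centroid_spectra(c("H4:4-17:K5ac_K8ac_K12ac_K16ac" = 0), lib)
  expect_equal(nrow(ss0$spectra), 0)
})

test_that("chip simulation validates peaks and labels truth from factors", {
  sizes <- c(chrT = 10000L)
  expect_error(simulate_chip_data(sizes, data.frame(
    chrom = "chrT", start = 9500L, end = 10500L, factor_a = 2, factor_b = 1)),
    "outside chromosome bounds")
  pk <- data.frame(chrom = "chrT", start = c(0L, 2000L), end = c(1000L, 3000L),
                   factor_a = c(8, 2), factor_b = c(1, 2))
  sim <- simulate_chip_data(sizes, pk, seed = 5)
  expect_equal(sim$peaks$truth, c("specific_A", "constitutive"))
  empty <- simulate_chip_data(sizes, pk[0, ], background_rate = 20, seed = 5)
  expect_equal(length(empty$track_a$counts$chrT), 200)
  expect_true(all(empty$track_a$counts$chrT >= 0))
})
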