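make_track <- function(values, bin = 50L, sizes = c(chrT = length(values) * 50L),
                       total = 1e6) {
  coverage_track(list(chrT = values), bin, sizes, total_mapped_reads = total)
}

test_that("RPM normalization scales bins by 1e6/total times the global scale", {
  tr <- make_track(c(40, 0, 10), total = 2e7)
  expect_equal(rpm_normalize(tr, scale = 1)$counts$chrT, c(2, 0, 0.5))
  expect_equal(rpm_normalize(tr, scale = 10)$counts$chrT, c(20, 0, 5))
  empty <- make_track(rep(0, 5), total = 1e6)
  expect_equal(rpm_normalize(empty)$counts$chrT, rep(0, 5))
  expect_error(rpm_normalize(make_track(c(1, 2), total = 0)), "zero mapped")
})

test_that("constant-coverage peaks classify by the pseudocounted fold", {
  a <- make_track(rep(8, 20)); b <- make_track(rep(1, 20))
  pk <- data.frame(chrom = "chrT", start = 100L, end = 700L)
  res <- classify_peaks(pk, a, b, window = 200, fold = 4, pseudocount = 0.1)
  expect_equal(res$label, "specific_A")
  expect_equal(res$max_fold_a, 8.1 / 1.1, tolerance = 1e-12)
  same <- classify_peaks(pk, a, a, window = 200)
  expect_equal(same$label, "constitutive")
  expect_equal(same$max_window_fold, 1)
})

test_that("short peaks are evaluated as a single window over themselves", {
  a <- make_track(c(10, 0, 0, 0)); b <- make_track(c(1, 1, 1, 1))
  pk <- data.frame(chrom = "chrT", start = 10L, end = 40L)  # 30 bp < window
  res <- classify_peaks(pk, a, b, window = 200)
  expect_equal(res$window_end - res$window_start, 30)
  expect_equal(res$label, "specific_A")  # (10+.1)/(1+.1) > 4
})

test_that("raising the fold threshold never converts constitutive to specific", {
  set.seed(601)
  a <- make_track(rpois(40, 30)); b <- make_track(rpois(40, 30))
  pk <- data.frame(chrom = "chrT", start = c(0L, 500L), end = c(400L, 1500L))
  for (f1 in c(2, 3)) {
    r1 <- classify_peaks(pk, a, b, fold = f1)
    r2 <- classify_peaks(pk, a, b, fold = f1 + 2)
    conv <- r1$label == "constitutive" & r2$label != "constitutive"
    expect_false(any(conv))
  }
})

test_that("classification agrees with the every-offset brute-force oracle", {
  set.seed(602)
  bin <- 50L
  for (rep in 1:100) {
    n_bin <- 40L
    va <- rpois(n_bin, sample(c(5, 30), 1)) * runif(1, 0.5, 2)
    vb <- rpois(n_bin, sample(c(5, 30), 1)) * runif(1, 0.5, 2)
    a <- make_track(va, bin); b <- make_track(vb, bin)
    s <- sample(0:800, 1); e <- s + sample(c(150, 300, 600, 900), 1)
    pk <- data.frame(chrom = "chrT", start = s, end = e)
    mine <- classify_peaks(pk, a, b, window = 200, fold = 4, pseudocount = 0.1)
    oracle <- oracle_classify_one(pk, va, vb, bin, 200, 4, 0.1)
    expect_equal(mine$label, oracle)
  }
})

test_that("replicate merging coalesces overlapping and book-ended intervals", {
  r1 <- data.frame(chrom = "chrT", start = 100L, end = 300L)
  r2 <- data.frame(chrom = "chrT", start = c(250L, 300L), end = c(400L, 450L))
  m <- merge_replicate_peaks(r1, r2)
  expect_equal(m, data.frame(chrom = "chrT", start = 100L, end = 450L))
  disjoint <- merge_replicate_peaks(
    data.frame(chrom = "chrT", start = 500L, end = 600L),
    data.frame(chrom = "chrT", start = 100L, end = 200L))
  expect_equal(disjoint$start, c(100L, 500L))
  expect_error(merge_replicate_peaks(
    data.frame(chrom = "chrT", start = 10L, end = 5L)), "malformed")
  inter <- merge_replicate_peaks(r1, r2, mode = "intersection")
  expect_equal(inter, data.frame(chrom = "chrT", start = 250L, end = 300L))
})

test_that("merging matches the base-mask oracle on random fixtures", {
  set.seed(603)
  for (rep in 1:100) {
    mk <- function(n) {
      s <- sample(0:900, n)
      data.frame(chrom = "chrT", start = s, end = s + sample(20:150, n, TRUE))
    }
    d1 <- mk(sample(1:6, 1)); d2 <- mk(sample(1:6, 1))
    mine <- merge_replicate_peaks(d1, d2)
    oracle <- oracle_merge(d1, d2, 1200)
    expect_equal(mine$start, oracle$start)
    expect_equal(mine$end, oracle$end)
  }
})

test_that("TF-site overlap uses edge-to-edge distance with overlap = 0", {
  peaks <- data.frame(chrom = "chrT", start = 5000L, end = 6000L)
  sites <- data.frame(chrom = "chrT",
                      start = c(5500L, 6900L, 9000L), end = c(5520L, 6920L, 9020L))
  expect_equal(overlap_fraction(sites, peaks, 1000), 2 / 3)
  inside <- data.frame(chrom = "chrT", start = c(5100L, 5900L),
                       end = c(5120L, 5920L))
  expect_equal(overlap_fraction(inside, peaks), 1)
  expect_warning(nv <- overlap_fraction(sites[0, ], peaks), "empty")
  expect_true(is.na(nv))
})

test_that("overlap fractions match the all-pairs distance oracle", {
  set.seed(604)
  for (rep in 1:100) {
    mk <- function(n, chroms = c("chr1", "chr2")) {
      s <- sample(0:50000, n)
      data.frame(chrom = sample(chroms, n, TRUE), start = s,
                 end = s + sample(10:500, n, TRUE))
    }
    sites <- mk(sample(2:8, 1)); peaks <- mk(sample(1:10, 1))
    expect_equal(overlap_fraction(sites, peaks, 1000),
                 oracle_overlap_fraction(sites, peaks, 1000))
  }
})

test_that("simulated enriched peaks are recovered against background", {
  sizes <- c(chrT = 60000L)
  starts <- seq(1000L, by = 2800L, length.out = 20)
  pk <- data.frame(chrom = "chrT", start = starts, end = starts + 600L,
                   factor_a = rep(c(8, 1, 1, 1), 5),
                   factor_b = rep(c(1, 8, 1, 1), 5))
  sim <- simulate_chip_data(sizes, pk, background_rate = 50, seed = 9)
  na <- rpm_normalize(sim$track_a); nb <- rpm_normalize(sim$track_b)
  res <- classify_peaks(sim$peaks, na, nb)
  expect_true(all(res$label == sim$peaks$truth))
  expect_setequal(unique(res$label),
                  c("specific_A", "specific_B", "constitutive"))
})
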