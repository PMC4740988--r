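test_that("one-way ANOVA matches the textbook sum-of-squares oracle", {
  set.seed(501)
  for (rep in 1:20) {
    x <- rnorm(9)
    g <- rep(c("a", "b", "c"), each = 3)
    m <- matrix(x, 1, dimnames = list("f", paste(g, 1:3, sep = ".")))
    res <- anova_timecourse(m, groups = g)
    oracle <- oracle_anova(x, g)
    expect_equal(res$F, oracle$F, tolerance = 1e-10)
    expect_equal(res$p_value, oracle$p, tolerance = 1e-10)
  }
})

test_that("two-group ANOVA equals the homoscedastic t-test (F = t^2)", {
  set.seed(502)
  x <- rnorm(4, 1); y <- rnorm(4, 2)
  m <- matrix(c(x, y), 1,
              dimnames = list("f", c(paste0("a.", 1:4), paste0("b.", 1:4))))
  a <- anova_timecourse(m)
  t <- ttest_fold_change(x, y)
  expect_equal(a$p_value, t$p_value, tolerance = 1e-12)
})

test_that("degenerate ANOVA inputs are flagged", {
  m <- matrix(c(1, 1, 2, 2), 1,
              dimnames = list("f", c("a.1", "a.2", "b.1", "b.2")))
  res <- anova_timecourse(m)
  expect_equal(res$p_value, 0)
  expect_equal(res$flag, "zero_within_var")
  mc <- matrix(3, 1, 4, dimnames = list("f", c("a.1", "a.2", "b.1", "b.2")))
  resc <- anova_timecourse(mc)
  expect_equal(resc$p_value, 1)
  expect_equal(resc$flag, "constant")
})

test_that("t-test fold changes and significance semantics", {
  x <- c(1, 2, 3)
  same <- ttest_fold_change(x, x)
  expect_equal(same$log2_fc, 0)
  expect_equal(same$p_value, 1)
  expect_false(same$significant)

  halved <- ttest_fold_change(c(2, 4, 6), c(1, 2, 3))
  expect_equal(halved$log2_fc, -1)

  neg <- ttest_fold_change(c(-1, 0, 1), c(1, 2, 3))
  expect_true(is.na(neg$log2_fc))
  expect_true(is.finite(neg$p_value))
  expect_match(neg$flag, "nonpositive_mean")
})

test_that("the significance flag is exactly p < 0.05 on the -log2 scale", {
  expect_equal(neglog2_cutoff(), 4.321928, tolerance = 1e-6)
  expect_equal(round(neglog2_cutoff(), 2), 4.32)
  set.seed(503)
  res <- ttest_fold_change(matrix(rnorm(200), 20), matrix(rnorm(200), 20))
  expect_equal(res$significant, res$p_value < 0.05)
  expect_equal(res$significant, res$neglog2_p > neglog2_cutoff())
  expect_true(all(res$neglog2_p >= 0))
})

test_that("dose concordance joins on features and handles extremes", {
  set.seed(504)
  d1 <- ttest_fold_change(matrix(rlnorm(40), 10,
                                 dimnames = list(paste0("m", 1:10), NULL)),
                          matrix(rlnorm(40), 10,
                                 dimnames = list(paste0("m", 1:10), NULL)))
  same <- dose_concordance(d1, d1)
  expect_equal(same$correlation, 1)
  flip <- d1; flip$log2_fc <- -flip$log2_fc
  expect_equal(dose_concordance(d1, flip)$correlation, -1)
  expect_warning(tiny <- dose_concordance(d1[1:2, ], d1[1:2, ]), "fewer than 3")
  expect_true(is.na(tiny$correlation))
})

test_that("shared-effect concordance matches the closed-form attenuation", {
  # log2 fc observed = true shared effect + independent noise in each dose;
  # cor -> var(effect) / (var(effect) + var(noise))
  set.seed(505)
  n <- 60; sd_eff <- 1; sd_noise <- 0.5
  reps <- replicate(200, {
    eff <- rnorm(n, 0, sd_eff)
    cor(eff + rnorm(n, 0, sd_noise), eff + rnorm(n, 0, sd_noise))
  })
  expected <- sd_eff^2 / (sd_eff^2 + sd_noise^2)
  expect_equal(mean(reps), expected, tolerance = 0.03)
})

test_that("PCA separates constructed clusters and normalizes variance", {
  set.seed(506)
  m <- rbind(matrix(rnorm(40, 0, 0.1), 4), matrix(rnorm(40, 5, 0.1), 4))
  rownames(m) <- paste0("s", 1:8)
  pc <- pca_profiles(m)
  expect_equal(sum(pc$explained_variance), 1, tolerance = 1e-12)
  expect_gt(pc$explained_variance[1], 0.95)
  expect_true(all(pc$scores[1:4, 1] * pc$scores[5:8, 1] < 0))
  dup <- rbind(m, m[1, , drop = FALSE])
  pd <- pca_profiles(dup)
  expect_equal(unname(pd$scores[1, ]), unname(pd$scores[9, ]), tolerance = 1e-9)
  expect_error(pca_profiles(matrix(1, 3, 3)), "rank-0")
})
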