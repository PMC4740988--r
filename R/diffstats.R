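#' Significance threshold on the -log2 p scale
#'
#' The pipeline flags a change as significant when its two-tailed p-value is
#' below `alpha` = 0.05, i.e. when -log2(p) exceeds -log2(0.05) = 4.32
#' (strict inequality; p exactly at the cutoff is not significant).
#'
#' @param alpha Significance level.
#' @return The cutoff on the -log2 scale.
#' @export
neglog2_cutoff <- function(alpha = 0.05) -log2(alpha)

#' One-way ANOVA across time points, per feature
#'
#' Classical fixed-effects one-way F-test of equal means across the time
#' points, applied row-wise. Observations are replicate-level values; by the
#' package's convention these are biological-replicate means (columns
#' `"<time>.<bio>"` after [average_technical_replicates()]), but any matrix
#' whose column names start with `"<time>."` works, so technical replicates
#' can be used as independent observations instead.
#'
#' @param mat Feature x sample matrix; column names `"<time>.<rest>"`.
#' @param groups Optional explicit group factor overriding the column-name
#'   parsing.
#' @return Data frame `feature`, `F`, `p_value`, `flag`. Degenerate rows are
#'   flagged: zero within-group variance with unequal means gives the p -> 0
#'   limit (`flag = "zero_within_var"`); an all-identical row gives p = 1
#'   (`flag = "constant"`).
#' @export
anova_timecourse <- function(mat, groups = NULL) {
  if (is.null(groups))
    groups <- vapply(strsplit(colnames(mat), ".", fixed = TRUE), `[`, "", 1L)
  groups <- factor(groups, levels = unique(groups))
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("each group needs at least 2 values")

  res <- lapply(seq_len(nrow(mat)), function(i) {
    x <- as.numeric(mat[i, ])
    within_var <- stats::ave(x, groups, FUN = stats::var)
    if (all(within_var == 0, na.rm = TRUE)) {
      if (stats::var(x) == 0)
        return(list(F = NA_real_, p = 1, flag = "constant"))
      return(list(F = Inf, p = 0, flag = "zero_within_var"))
    }
    ft <- stats::oneway.test(x ~ groups, var.equal = TRUE)
    list(F = unname(ft$statistic), p = unname(ft$p.value), flag = "")
  })
  data.frame(feature = rownames(mat),
             F = vapply(res, function(r) r$F, 0),
             p_value = vapply(res, function(r) r$p, 0),
             flag = vapply(res, function(r) r$flag, ""),
             stringsAsFactors = FALSE)
}

#' Homoscedastic two-tailed t-test with log2 fold change, per feature
#'
#' Pooled-variance two-sample t-test of treated against control, with
#' `log2_fc = log2(mean(treated) / mean(control))` and the significance flag
#' `-log2(p) > -log2(alpha)` (equivalently `p < alpha`, strict).
#' Benjamini-Hochberg q-values are reported alongside as an extension; the
#' significance flags always use the raw p-values.
#'
#' @param control,treated Matrices (features x replicates) with identical row
#'   order, or bare numeric vectors for a single feature.
#' @param alpha Significance level for the flag.
#' @return Data frame of class `diff_result`: `feature`, `log2_fc`,
#'   `p_value`, `neglog2_p`, `significant`, `q_value`, `flag`. A non-positive
#'   arm mean leaves `log2_fc` undefined (`NA`, flagged) while the p-value is
#'   still reported; two identical constant arms give p = 1.
#' @export
ttest_fold_change <- function(control, treated, alpha = 0.05) {
  if (is.null(dim(control))) control <- matrix(control, 1,
                                               dimnames = list("feature", NULL))
  if (is.null(dim(treated))) treated <- matrix(treated, 1,
                                               dimnames = list("feature", NULL))
  stopifnot(nrow(control) == nrow(treated))
  if (ncol(control) < 2 || ncol(treated) < 2)
    stop("each arm needs at least 2 values")

  one <- function(x, y) {  # x = control, y = treated
    mx <- mean(x); my <- mean(y)
    sp2 <- (sum((x - mx)^2) + sum((y - my)^2)) / (length(x) + length(y) - 2)
    flag <- ""
    if (sp2 == 0) {
      p <- if (mx == my) 1 else 0
      if (mx != my) flag <- "zero_var"
    } else {
      p <- stats::t.test(y, x, var.equal = TRUE)$p.value
    }
    fc <- if (mx > 0 && my > 0) log2(my / mx) else {
      flag <- paste0(flag, if (nzchar(flag)) ";", "nonpositive_mean")
      NA_real_
    }
    list(fc = fc, p = p, flag = flag)
  }
  res <- lapply(seq_len(nrow(control)), function(i)
    one(as.numeric(control[i, ]), as.numeric(treated[i, ])))
  p <- vapply(res, function(r) r$p, 0)
  out <- data.frame(
    feature = if (!is.null(rownames(control))) rownames(control)
              else as.character(seq_along(res)),
    log2_fc = vapply(res, function(r) r$fc, 0),
    p_value = p,
    neglog2_p = -log2(p),
    significant = p < alpha,
    q_value = stats::p.adjust(p, method = "BH"),
    flag = vapply(res, function(r) r$flag, ""),
    stringsAsFactors = FALSE)
  class(out) <- c("diff_result", "data.frame")
  out
}

#' Fold-change concordance between two treatments
#'
#' Inner-joins two differential results on their feature keys and reports the
#' Pearson correlation of the log2 fold changes — the dose-concordance
#' scatter summary for e.g. two inhibitor concentrations.
#'
#' @param diff_a,diff_b `diff_result` data frames.
#' @return List: `pairs` (data frame `feature`, `log2_fc_a`, `log2_fc_b`),
#'   `correlation` (Pearson; `NA` with a warning when fewer than 3 complete
#'   shared features).
#' @export
dose_concordance <- function(diff_a, diff_b) {
  shared <- intersect(diff_a$feature, diff_b$feature)
  pairs <- data.frame(
    feature = shared,
    log2_fc_a = diff_a$log2_fc[match(shared, diff_a$feature)],
    log2_fc_b = diff_b$log2_fc[match(shared, diff_b$feature)],
    stringsAsFactors = FALSE)
  ok <- stats::complete.cases(pairs)
  if (sum(ok) < 3) {
    warning("fewer than 3 shared features: correlation undefined")
    return(list(pairs = pairs, correlation = NA_real_))
  }
  list(pairs = pairs,
       correlation = stats::cor(pairs$log2_fc_a[ok], pairs$log2_fc_b[ok]))
}

#' PCA of PTM abundance profiles
#'
#' Feature-centred principal component analysis of a samples x features
#' matrix (covariance PCA, no scaling), as used to check that time-point
#' profiles separate.
#'
#' @param mat Samples x features matrix (>= 2 samples, >= 2 features).
#' @return List: `scores` (samples x PCs), `loadings`, `explained_variance`
#'   (fractions summing to 1).
#' @export
pca_profiles <- function(mat) {
  if (nrow(mat) < 2 || ncol(mat) < 2) stop("need >= 2 samples and features")
  centred <- scale(mat, center = TRUE, scale = FALSE)
  if (all(centred == 0)) stop("rank-0 matrix: all samples identical")
  pc <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  list(scores = pc$x, loadings = pc$rotation,
       explained_variance = pc$sdev^2 / sum(pc$sdev^2))
}
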