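# Independent brute-force oracles. Each is written directly from first
# principles (per-residue summation, per-centroid filtering, per-base arrays,
# all-pairs scans) and shares no code with the implementation it checks.

# --- residue-mass summation oracle ------------------------------------------
# Independent monoisotopic mass table (IUPAC standard values).
ORACLE_AA <- list(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, K = 128.09496, R = 156.10111, L = 113.08406, Q = 128.05858)
ORACLE_MOD <- list(un = 0, me1 = 14.01565, me2 = 28.0313, me3 = 42.04695,
                   ac = 42.010565)
ORACLE_H2O <- 18.010565
ORACLE_PR <- 56.026215

oracle_mass <- function(sequence, codes_by_pos) {
  # codes_by_pos: named by 1-based position IN THE PEPTIDE
  aa <- strsplit(sequence, "")[[1]]
  m <- ORACLE_H2O + ORACLE_PR  # water + N-terminal propionyl
  for (i in seq_along(aa)) {
    m <- m + ORACLE_AA[[aa[i]]]
    code <- if (as.character(i) %in% names(codes_by_pos))
      codes_by_pos[[as.character(i)]] else "un"
    m <- m + ORACLE_MOD[[code]]
    if (aa[i] == "K" && code %in% c("un", "me1")) m <- m + ORACLE_PR
  }
  m
}

# --- brute-force EIC matching oracle ----------------------------------------
oracle_eic <- function(spectra, target_mz, ppm_tol) {
  rts <- unique(spectra$rt)
  ints <- numeric(length(rts))
  for (k in seq_along(rts)) {
    tot <- 0
    for (i in which(spectra$rt == rts[k])) {
      if (abs(spectra$mz[i] - target_mz) / target_mz * 1e6 <= ppm_tol)
        tot <- tot + spectra$intensity[i]
    }
    ints[k] <- tot
  }
  data.frame(rt = rts, intensity = ints)
}

# --- independent trapezoid quadrature ---------------------------------------
oracle_trapz <- function(rt, intensity, lo, hi) {
  keep <- which(rt >= lo & rt <= hi)
  if (length(keep) < 2) return(0)
  s <- 0
  for (i in keep[-length(keep)]) {
    j <- i + 1
    s <- s + (rt[j] - rt[i]) * (intensity[i] + intensity[j]) / 2
  }
  s
}

# --- exhaustive every-offset sliding-window classification oracle -----------
# Expands tracks to per-base arrays and tries every 1-bp window offset.
oracle_classify_one <- function(peak, va, vb, bin, window, fold, pseudo) {
  per_base <- function(v, n_bases) rep(v, each = bin)[seq_len(n_bases)]
  n_bases <- length(va) * bin
  a <- per_base(va, n_bases); b <- per_base(vb, n_bases)
  s <- peak$start; e <- peak$end
  w <- min(window, e - s)
  best_a <- best_b <- 0
  for (o in s:(e - w)) {
    ma <- mean(a[(o + 1):(o + w)]) + pseudo
    mb <- mean(b[(o + 1):(o + w)]) + pseudo
    best_a <- max(best_a, ma / mb)
    best_b <- max(best_b, mb / ma)
  }
  if (best_a > fold && (best_b <= fold || best_a >= best_b)) "specific_A"
  else if (best_b > fold) "specific_B"
  else "constitutive"
}

# --- base-mask interval union oracle ----------------------------------------
oracle_merge <- function(df1, df2, n_bases) {
  mask <- rep(FALSE, n_bases)
  for (df in list(df1, df2)) for (i in seq_len(nrow(df)))
    mask[(df$start[i] + 1):df$end[i]] <- TRUE
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = starts[r$values], end = ends[r$values])
}

# --- all-pairs edge distance oracle -----------------------------------------
oracle_overlap_fraction <- function(sites, peaks, max_dist) {
  near <- logical(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    dmin <- Inf
    for (j in seq_len(nrow(peaks))) {
      if (sites$chrom[i] != peaks$chrom[j]) next
      if (sites$end[i] > peaks$start[j] && sites$start[i] < peaks$end[j]) d <- 0
      else d <- max(peaks$start[j] - sites$end[i], sites$start[i] - peaks$end[j])
      dmin <- min(dmin, d)
    }
    near[i] <- dmin <= max_dist
  }
  mean(near)
}

# --- textbook one-way ANOVA sum-of-squares oracle ---------------------------
oracle_anova <- function(values, groups) {
  groups <- as.character(groups)
  grand <- mean(values)
  ss_between <- 0; ss_within <- 0
  for (g in unique(groups)) {
    x <- values[groups == g]
    ss_between <- ss_between + length(x) * (mean(x) - grand)^2
    ss_within <- ss_within + sum((x - mean(x))^2)
  }
  df1 <- length(unique(groups)) - 1
  df2 <- length(values) - length(unique(groups))
  F <- (ss_between / df1) / (ss_within / df2)
  list(F = F, p = stats::pf(F, df1, df2, lower.tail = FALSE))
}

# small random toy spectra for oracle comparisons
random_spectra <- function(n = 60) {
  df <- data.frame(rt = sort(round(runif(n, 0, 10), 3)),
                   mz = runif(n, 499.9, 500.1),
                   intensity = runif(n, 0, 1000))
  df
}
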