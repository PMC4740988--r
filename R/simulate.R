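#' Time-course sample design
#'
#' @param time_points Ordered character labels of the differentiation time
#'   points. Labels must not contain `"."` (the sample-ID separator).
#' @param n_bio Biological replicates per time point.
#' @param n_tech Technical replicates per biological replicate.
#' @return A `sample_design` list with a `sample_ids` component in the
#'   interchange convention `"<time>.<bio>.<tech>"`.
#' @export
sample_design <- function(time_points = c("ESC", "EB", "RA", "RA4d", "RA7d"),
                          n_bio = 2L, n_tech = 3L) {
  stopifnot(length(time_points) >= 1, n_bio >= 1, n_tech >= 1)
  if (any(grepl(".", time_points, fixed = TRUE)))
    stop("time point labels must not contain '.'")
  # order: time slowest, then bio, then tech
  grid <- expand.grid(tech = seq_len(n_tech), bio = seq_len(n_bio),
                      time = time_points, stringsAsFactors = FALSE)
  ids <- paste(grid$time, grid$bio, grid$tech, sep = ".")
  structure(list(time_points = time_points, n_bio = as.integer(n_bio),
                 n_tech = as.integer(n_tech), sample_ids = ids),
            class = "sample_design")
}

#' Split interchange sample IDs into design coordinates
#'
#' @param ids Character vector of `"<time>.<bio>.<tech>"` sample IDs.
#' @return Data frame with columns `time`, `bio`, `tech`.
#' @export
parse_sample_ids <- function(ids) {
  parts <- strsplit(ids, ".", fixed = TRUE)
  if (any(lengths(parts) != 3L))
    stop("sample IDs must have the form <time>.<bio>.<tech>")
  data.frame(time = vapply(parts, `[`, "", 1L),
             bio = as.integer(vapply(parts, `[`, "", 2L)),
             tech = as.integer(vapply(parts, `[`, "", 3L)),
             stringsAsFactors = FALSE)
}

#' Declare a time-course effect on a subset of peptidoforms
#'
#' An effect multiplies the true (pre-normalization) abundance of the selected
#' peptidoforms by a per-time-point factor; selection is by exact key, by
#' carried mark, or by acetyl count within a histone.
#'
#' @param trajectory Positive multiplicative factor per time point, in design
#'   order.
#' @param key,mark,acetyl_count,histone Selectors; at least one must be given.
#'   `acetyl_count` may be a vector (e.g. `2:4` for multiply acetylated forms)
#'   and combines with `histone`.
#' @return An `effect_spec` object for [simulate_area_table()].
#' @export
effect_spec <- function(trajectory, key = NULL, mark = NULL,
                        acetyl_count = NULL, histone = NULL) {
  if (any(trajectory <= 0)) stop("trajectory factors must be positive")
  if (is.null(key) && is.null(mark) && is.null(acetyl_count))
    stop("effect_spec needs a selector (key, mark or acetyl_count)")
  structure(list(trajectory = trajectory, key = key, mark = mark,
                 acetyl_count = acetyl_count, histone = histone),
            class = "effect_spec")
}

select_forms <- function(lib, eff) {
  sel <- rep(TRUE, nrow(lib))
  if (!is.null(eff$key)) sel <- sel & lib$key %in% eff$key
  if (!is.null(eff$mark)) {
    marks <- peptidoform_marks(lib)
    sel <- sel & vapply(marks, function(m) any(eff$mark %in% m), NA)
  }
  if (!is.null(eff$acetyl_count)) sel <- sel & lib$n_acetyl %in% eff$acetyl_count
  if (!is.null(eff$histone)) sel <- sel & lib$histone %in% eff$histone
  sel
}

# mean-one lognormal multiplier; cv = 0 gives exactly 1
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}

#' Simulate a peak-area table with known ground truth
#'
#' True per-family relative ratios at each time point are the baseline weights
#' multiplied by every applicable effect trajectory, renormalized to sum to 1
#' within each peptide family. Observed areas are
#' `scale * true_ratio * lognormal(bio) * lognormal(tech)`, with the
#' biological noise draw shared across the technical replicates of one
#' biological sample. Both noise multipliers have unit mean so that ratios are
#' recovered in expectation.
#'
#' @param lib A `peptidoform_library`.
#' @param design A [sample_design()].
#' @param effects List of [effect_spec()] objects (may be empty).
#' @param baseline Named baseline weights per peptidoform key; default uniform
#'   within each family.
#' @param scale Positive area scale (arbitrary intensity-minute units).
#' @param tech_cv,bio_cv Lognormal coefficients of variation of the technical
#'   and biological noise; `0` disables the component.
#' @param seed Optional integer seed; identical seeds give identical output.
#' @return A list of class `sim_area`: `areas` (peptidoform x sample matrix),
#'   `truth` (peptidoform x time point matrix of true ratios), `lib`, `design`.
#' @export
simulate_area_table <- function(lib, design = sample_design(), effects = list(),
                                baseline = NULL, scale = 1e6,
                                tech_cv = 0.05, bio_cv = 0.15, seed = NULL) {
  if (nrow(lib) == 0) stop("empty peptidoform library")
  if (scale <= 0) stop("scale must be positive")
  if (tech_cv < 0 || bio_cv < 0) stop("noise CVs must be >= 0")
  if (!is.null(seed)) set.seed(seed)

  fam <- family_of(lib$key)
  if (is.null(baseline)) {
    baseline <- stats::setNames(rep(NA_real_, nrow(lib)), lib$key)
    for (f in unique(fam)) baseline[fam == f] <- 1 / sum(fam == f)
  } else {
    if (!all(lib$key %in% names(baseline)))
      stop("baseline must name every peptidoform key")
    baseline <- baseline[lib$key]
  }
  if (any(baseline < 0)) stop("baseline weights must be non-negative")

  tp <- design$time_points
  for (eff in effects) {
    if (length(eff$trajectory) != length(tp))
      stop("effect trajectory length must equal the number of time points")
    if (!any(select_forms(lib, eff)))
      stop("effect selects no peptidoform in the library")
  }

  truth <- matrix(baseline, nrow = nrow(lib), ncol = length(tp),
                  dimnames = list(lib$key, tp))
  for (eff in effects) {
    sel <- select_forms(lib, eff)
    truth[sel, ] <- truth[sel, , drop = FALSE] *
      matrix(eff$trajectory, sum(sel), length(tp), byrow = TRUE)
  }
  for (f in unique(fam)) {
    rows <- fam == f
    tot <- colSums(truth[rows, , drop = FALSE])
    truth[rows, ] <- sweep(truth[rows, , drop = FALSE], 2, tot, "/")
  }

  ids <- design$sample_ids
  coords <- parse_sample_ids(ids)
  areas <- matrix(0, nrow(lib), length(ids), dimnames = list(lib$key, ids))
  for (t in tp) for (b in seq_len(design$n_bio)) {
    bio_mult <- rlnorm_cv(nrow(lib), bio_cv)
    cols <- which(coords$time == t & coords$bio == b)
    for (j in cols) {
      areas[, j] <- scale * truth[, t] * bio_mult * rlnorm_cv(nrow(lib), tech_cv)
    }
  }
  structure(list(areas = areas, truth = truth, lib = lib, design = design),
            class = "sim_area")
}

#' Assign elution coordinates and target m/z values to a library
#'
#' Peptidoforms with indistinguishable m/z (positional isomers, e.g. the
#' singly acetylated H4 forms) are isobaric: they share one elution group and
#' co-elute by construction. Distinct m/z groups are spaced well apart on the
#' retention-time axis.
#'
#' @param lib A `peptidoform_library`.
#' @param charge Charge state used for the precursor m/z (default 2, typical
#'   for short propionylated histone peptides).
#' @param rt_start First group's elution apex (minutes).
#' @param rt_spacing Apex spacing between m/z groups (minutes).
#' @param rt_width Gaussian elution sigma (minutes).
#' @return Data frame `key`, `mz`, `rt_mean`, `rt_width`, `mz_group`.
#' @export
assign_elution <- function(lib, charge = 2L, rt_start = 5, rt_spacing = 2,
                           rt_width = 0.2) {
  stopifnot(rt_width > 0, rt_spacing > 0)
  mz <- vapply(lib$neutral_mass, compute_mz, 0, charge = charge)
  grp <- match(round(mz, 4), sort(unique(round(mz, 4))))
  data.frame(key = lib$key, mz = mz,
             rt_mean = rt_start + (grp - 1) * rt_spacing,
             rt_width = rt_width, mz_group = grp,
             stringsAsFactors = FALSE)
}

#' Simulate centroided spectra for one sample from its peak areas
#'
#' Each peptidoform elutes as a Gaussian profile sampled on a regular
#' retention-time grid; the emitted intensities are density-scaled so the
#' extracted-ion-chromatogram integral of a form recovers its area (to
#' quadrature tolerance). Isobaric forms co-elute and their centroids stack at
#' the same m/z. Unique-fragment intensity summaries (one scalar per form,
#' proportional to its abundance) accompany the spectra so isobar groups can
#' be apportioned downstream.
#'
#' @param areas Named numeric vector of one sample's areas, names =
#'   peptidoform keys.
#' @param lib The `peptidoform_library` the keys come from.
#' @param elution Optional output of [assign_elution()]; computed if omitted.
#' @param rt_grid Grid spacing in minutes.
#' @param mz_jitter_ppm Gaussian ppm jitter applied to each centroid m/z.
#' @param seed Optional integer seed.
#' @return List of class `sim_spectra`: `spectra` (data frame `rt`, `mz`,
#'   `intensity`, sorted by rt), `elution`, `fragments` (named vector).
#' @export
simulate_centroid_spectra <- function(areas, lib, elution = NULL,
                                      rt_grid = 0.05, mz_jitter_ppm = 0,
                                      seed = NULL) {
  stopifnot(rt_grid > 0, mz_jitter_ppm >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(elution)) elution <- assign_elution(lib)
  if (!all(names(areas) %in% elution$key))
    stop("areas name peptidoforms missing from the elution map")
  el <- elution[match(names(areas), elution$key), ]

  pieces <- lapply(seq_along(areas), function(i) {
    a <- areas[i]
    if (a <= 0) return(NULL)  # zero-area forms emit nothing
    mu <- el$rt_mean[i]; sg <- el$rt_width[i]
    rts <- seq(floor((mu - 4 * sg) / rt_grid), ceiling((mu + 4 * sg) / rt_grid)) * rt_grid
    int <- a * stats::dnorm(rts, mu, sg)
    mz <- rep(el$mz[i], length(rts))
    if (mz_jitter_ppm > 0)
      mz <- mz * (1 + stats::rnorm(length(rts), 0, mz_jitter_ppm) * 1e-6)
    data.frame(rt = rts, mz = mz, intensity = int)
  })
  spectra <- do.call(rbind, pieces)
  if (is.null(spectra))
    spectra <- data.frame(rt = numeric(0), mz = numeric(0), intensity = numeric(0))
  spectra <- spectra[order(spectra$rt, spectra$mz), , drop = FALSE]
  rownames(spectra) <- NULL
  structure(list(spectra = spectra, elution = elution,
                 fragments = areas),
            class = "sim_spectra")
}

#' Binned coverage track
#'
#' @param counts Named list, one numeric vector of per-bin read counts per
#'   chromosome.
#' @param bin_size Bin width in bp.
#' @param chrom_sizes Named vector of chromosome lengths in bp.
#' @param total_mapped_reads Library size; defaults to the sum of all counts.
#' @return A `coverage_track` object.
#' @export
coverage_track <- function(counts, bin_size, chrom_sizes,
                           total_mapped_reads = sum(unlist(counts))) {
  stopifnot(bin_size >= 1, all(names(counts) %in% names(chrom_sizes)))
  for (chrom in names(counts)) {
    expected <- ceiling(chrom_sizes[[chrom]] / bin_size)
    if (length(counts[[chrom]]) != expected)
      stop("track length for ", chrom, " must be ", expected, " bins")
    if (any(counts[[chrom]] < 0)) stop("negative counts in ", chrom)
  }
  structure(list(counts = counts, bin_size = as.integer(bin_size),
                 chrom_sizes = chrom_sizes,
                 total_mapped_reads = total_mapped_reads),
            class = "coverage_track")
}

#' Simulate ChIP coverage for two cell populations over labelled true peaks
#'
#' Per-bin read counts are Poisson draws at `background_rate` scaled, inside
#' each peak, by that population's enrichment factor (overlap-weighted for
#' bins partially covered). Truth labels follow the classification rule the
#' pipeline is meant to recover: an enrichment-factor ratio above `fold` in
#' either direction makes a peak population-specific, anything else is
#' constitutive.
#'
#' @param chrom_sizes Named vector of chromosome lengths (bp).
#' @param true_peaks Data frame `chrom`, `start`, `end` (0-based half-open),
#'   `factor_a`, `factor_b` (positive enrichment factors per population).
#' @param background_rate Expected background reads per bin.
#' @param bin_size Bin width in bp.
#' @param fold Truth-label fold threshold (default 4).
#' @param seed Optional integer seed.
#' @return List of class `sim_chip`: `track_a`, `track_b`
#'   ([coverage_track()]s), `peaks` (input plus a `truth` label column).
#' @export
simulate_chip_data <- function(chrom_sizes, true_peaks, background_rate = 50,
                               bin_size = 50L, fold = 4, seed = NULL) {
  stopifnot(background_rate > 0)
  if (!is.null(seed)) set.seed(seed)
  if (nrow(true_peaks) > 0) {
    if (any(true_peaks$factor_a <= 0 | true_peaks$factor_b <= 0))
      stop("enrichment factors must be positive")
    if (any(!true_peaks$chrom %in% names(chrom_sizes)))
      stop("peak on unknown chromosome")
    if (any(true_peaks$start < 0 |
            true_peaks$end > chrom_sizes[true_peaks$chrom]))
      stop("peak outside chromosome bounds")
    if (any(true_peaks$start >= true_peaks$end))
      stop("malformed peak interval (start >= end)")
  }

  lambda_for <- function(which_factor) {
    lapply(names(chrom_sizes), function(chrom) {
      nbin <- ceiling(chrom_sizes[[chrom]] / bin_size)
      lam <- rep(background_rate, nbin)
      pk <- true_peaks[true_peaks$chrom == chrom, , drop = FALSE]
      if (nrow(pk) > 0) for (i in seq_len(nrow(pk))) {
        f <- pk[[which_factor]][i]
        b0 <- pk$start[i] %/% bin_size + 1L
        b1 <- (pk$end[i] - 1L) %/% bin_size + 1L
        for (b in b0:b1) {
          ov <- min(pk$end[i], b * bin_size) - max(pk$start[i], (b - 1L) * bin_size)
          lam[b] <- lam[b] + background_rate * (f - 1) * ov / bin_size
        }
      }
      lam
    })
  }
  draw <- function(lams) {
    counts <- lapply(lams, function(l) stats::rpois(length(l), l))
    names(counts) <- names(chrom_sizes)
    coverage_track(counts, bin_size, chrom_sizes)
  }
  lam_a <- lambda_for("factor_a"); lam_b <- lambda_for("factor_b")
  track_a <- draw(lam_a); track_b <- draw(lam_b)

  peaks <- true_peaks
  if (nrow(peaks) > 0) {
    ratio <- peaks$factor_a / peaks$factor_b
    peaks$truth <- ifelse(ratio > fold, "specific_A",
                          ifelse(1 / ratio > fold, "specific_B", "constitutive"))
  } else peaks$truth <- character(0)
  structure(list(track_a = track_a, track_b = track_b, peaks = peaks),
            class = "sim_chip")
}
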