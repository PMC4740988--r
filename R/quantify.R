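#' Extract an ion chromatogram at ppm tolerance
#'
#' For every scan (unique retention time) the intensities of all centroids
#' whose m/z lies within `ppm_tol` of `target_mz` are summed; the boundary is
#' inclusive. Scans with no matching centroid contribute intensity 0, so the
#' trace always spans every scan in the input.
#'
#' @param spectra Data frame `rt`, `mz`, `intensity` of centroided spectra
#'   (long format, one row per centroid).
#' @param target_mz Target m/z in Th.
#' @param ppm_tol Mass tolerance in ppm (default 10, the standard setting for
#'   high-resolution Orbitrap histone runs).
#' @return A `chromatogram`: data frame `rt`, `intensity` with strictly
#'   increasing `rt`, plus `target_mz`/`ppm_tol` attributes.
#' @export
extract_ion_chromatogram <- function(spectra, target_mz, ppm_tol = 10) {
  if (ppm_tol <= 0) stop("ppm_tol must be positive")
  if (nrow(spectra) == 0) stop("empty spectra series")
  if (is.unsorted(spectra$rt)) stop("spectra must be sorted by retention time")
  scan_rt <- unique(spectra$rt)
  # boundary-inclusive, with a relative epsilon so a centroid placed exactly
  # at +/- ppm_tol is matched despite floating-point rounding
  hit <- abs(spectra$mz - target_mz) / target_mz * 1e6 <= ppm_tol * (1 + 1e-9)
  int <- rep(0, length(scan_rt))
  if (any(hit)) {
    sums <- tapply(spectra$intensity[hit], match(spectra$rt[hit], scan_rt), sum)
    int[as.integer(names(sums))] <- as.numeric(sums)
  }
  out <- data.frame(rt = scan_rt, intensity = int)
  attr(out, "target_mz") <- target_mz
  attr(out, "ppm_tol") <- ppm_tol
  class(out) <- c("chromatogram", "data.frame")
  out
}

#' Trapezoidal peak area of a chromatogram over a retention-time window
#'
#' @param chrom A [extract_ion_chromatogram()] result (or any `rt`/`intensity`
#'   data frame).
#' @param rt_window Numeric `c(start, end)` in minutes, `start < end`.
#' @return The trapezoidal integral of the restricted trace; 0 when fewer
#'   than two points fall inside the window.
#' @export
integrate_area <- function(chrom, rt_window) {
  if (length(rt_window) != 2 || rt_window[1] >= rt_window[2])
    stop("rt_window must be c(start, end) with start < end")
  keep <- chrom$rt >= rt_window[1] & chrom$rt <= rt_window[2]
  if (sum(keep) < 2) return(0)
  pracma::trapz(chrom$rt[keep], chrom$intensity[keep])
}

#' Apportion a shared isobar-group area by unique-fragment intensities
#'
#' Co-eluting isobaric peptidoforms are indistinguishable at the precursor
#' level; the shared extracted area is split linearly in proportion to each
#' form's unique MS/MS fragment intensity.
#'
#' @param shared_area Non-negative total area of the isobar group.
#' @param unique_fragment_intensity Named non-negative intensities, one per
#'   form in the group.
#' @return Named per-form areas summing to `shared_area`. If all intensities
#'   are zero the split is undefined: every form gets `NA` and a warning is
#'   raised.
#' @export
apportion_isobaric <- function(shared_area, unique_fragment_intensity) {
  if (shared_area < 0) stop("shared_area must be >= 0")
  w <- unique_fragment_intensity
  if (any(w < 0)) stop("fragment intensities must be >= 0")
  if (sum(w) == 0) {
    warning("all-zero fragment intensities: isobar split undefined")
    return(stats::setNames(rep(NA_real_, length(w)), names(w)))
  }
  shared_area * w / sum(w)
}

#' Quantify one sample's peptidoform areas from centroid spectra
#'
#' For every distinct library m/z an ion chromatogram is extracted at
#' `ppm_tol` and integrated over the elution window (apex +/- `rt_k` sigma);
#' groups containing several isobaric forms are apportioned by their
#' unique-fragment intensities.
#'
#' @param spectra Data frame `rt`, `mz`, `intensity`.
#' @param lib A `peptidoform_library`.
#' @param elution Output of [assign_elution()] (must match what generated or
#'   accompanies the spectra).
#' @param fragments Named unique-fragment intensities per form; required only
#'   for m/z groups with more than one member.
#' @param ppm_tol Mass tolerance in ppm.
#' @param rt_k Integration half-width in units of the elution sigma.
#' @return Named numeric vector of areas, one per library key.
#' @export
quantify_sample <- function(spectra, lib, elution = assign_elution(lib),
                            fragments = NULL, ppm_tol = 10, rt_k = 3) {
  areas <- stats::setNames(rep(0, nrow(lib)), lib$key)
  el <- elution[match(lib$key, elution$key), ]
  for (g in unique(el$mz_group)) {
    members <- which(el$mz_group == g)
    target <- el$mz[members[1]]
    mu <- el$rt_mean[members[1]]; sg <- el$rt_width[members[1]]
    chrom <- extract_ion_chromatogram(spectra, target, ppm_tol)
    shared <- integrate_area(chrom, c(mu - rt_k * sg, mu + rt_k * sg))
    if (length(members) == 1L) {
      areas[members] <- shared
    } else {
      keys <- lib$key[members]
      w <- if (is.null(fragments)) {
        stats::setNames(rep(1, length(keys)), keys)
      } else fragments[keys]
      w[is.na(w)] <- 0
      if (shared == 0) {
        areas[members] <- 0
      } else {
        areas[members] <- apportion_isobaric(shared, w)
      }
    }
  }
  areas
}

#' Per-family relative abundance ratios from a peak-area table
#'
#' Each peptidoform's area is divided by the total area of its peptide family
#' (all forms sharing backbone sequence and span) in the same sample. Missing
#' areas are treated as 0 (the form was not observed); a family whose total is
#' zero in a sample yields undefined (`NA`) ratios for that family/sample, and
#' the number of such cases is reported via a message.
#'
#' @param areas Matrix of areas, rownames = peptidoform keys
#'   (`histone:span:modstring`), colnames = sample IDs.
#' @return Matrix of the same shape with ratios in `[0, 1]`; within each
#'   family and sample the defined ratios sum to 1.
#' @export
relative_ratios <- function(areas) {
  if (is.null(rownames(areas)) || anyDuplicated(rownames(areas)))
    stop("areas must have unique peptidoform row keys")
  if (any(areas < 0, na.rm = TRUE)) stop("negative peak areas")
  areas[is.na(areas)] <- 0
  fam <- family_of(rownames(areas))
  out <- areas
  n_undefined <- 0L
  for (f in unique(fam)) {
    rows <- fam == f
    tot <- colSums(areas[rows, , drop = FALSE])
    zero <- tot == 0
    n_undefined <- n_undefined + sum(zero)
    tot[zero] <- NA_real_
    out[rows, ] <- sweep(areas[rows, , drop = FALSE], 2, tot, "/")
  }
  if (n_undefined > 0)
    message(n_undefined, " family/sample cell(s) have zero total area; ",
            "ratios undefined")
  out
}

#' Quantify a whole simulated run back to an area table
#'
#' Convenience wrapper: applies [simulate_centroid_spectra()] +
#' [quantify_sample()] per sample of a [simulate_area_table()] result,
#' returning the re-quantified area matrix aligned with the input.
#'
#' @param sim A `sim_area` object.
#' @param ppm_tol,rt_k Passed to [quantify_sample()].
#' @param mz_jitter_ppm,rt_grid Passed to [simulate_centroid_spectra()].
#' @param seed Optional integer seed for the spectra generation.
#' @return Matrix of quantified areas (peptidoform x sample).
#' @export
quantify_run <- function(sim, ppm_tol = 10, rt_k = 3, mz_jitter_ppm = 0,
                         rt_grid = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  elution <- assign_elution(sim$lib)
  out <- sim$areas
  out[] <- NA_real_
  for (j in seq_len(ncol(sim$areas))) {
    ss <- simulate_centroid_spectra(sim$areas[, j], sim$lib, elution = elution,
                                    rt_grid = rt_grid,
                                    mz_jitter_ppm = mz_jitter_ppm)
    out[, j] <- quantify_sample(ss$spectra, sim$lib, elution = elution,
                                fragments = ss$fragments, ppm_tol = ppm_tol,
                                rt_k = rt_k)
  }
  out
}
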