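#' Normalize a coverage track to reads per million mapped reads
#'
#' Each bin is scaled by `1e6 / total_mapped_reads`, then by a global scale
#' factor (default 10, the convention of reporting coverage per ten million
#' mapped reads while keeping the RPM name).
#'
#' @param track A [coverage_track()].
#' @param scale Global multiplier applied after the per-million scaling.
#' @return A `coverage_track` in (scaled) RPM units; `total_mapped_reads` is
#'   kept for reference.
#' @export
rpm_normalize <- function(track, scale = 10) {
  if (track$total_mapped_reads <= 0) stop("zero mapped reads")
  k <- 1e6 / track$total_mapped_reads * scale
  out <- track
  out$counts <- lapply(track$counts, function(x) x * k)
  out$normalized <- TRUE
  out
}

# mean track value over [start, end) (0-based, bp), overlap-weighted per bin
window_mean <- function(values, bin_size, start, end) {
  b0 <- start %/% bin_size + 1L
  b1 <- (end - 1L) %/% bin_size + 1L
  bins <- b0:b1
  ov <- pmin(end, bins * bin_size) - pmax(start, (bins - 1L) * bin_size)
  sum(values[bins] * ov) / (end - start)
}

#' Classify peaks as population-specific or constitutive
#'
#' Slides a window of `window` bp across each peak at bin-size steps (with
#' windows flush to both peak edges always included) and computes, per
#' window, the pseudocounted coverage ratio between the two populations. A
#' peak is `specific_A` if any window's A/B fold exceeds `fold`, `specific_B`
#' if any window's B/A fold exceeds it, and `constitutive` otherwise. If both
#' directions exceed the threshold in different windows, the larger maximum
#' wins and the peak is flagged ambiguous. Peaks shorter than the window are
#' evaluated as a single window over the peak itself.
#'
#' Both tracks must be normalized identically (see [rpm_normalize()]) and
#' share the bin grid.
#'
#' @param peaks Data frame `chrom`, `start`, `end` (0-based half-open).
#' @param track_a,track_b Normalized [coverage_track()]s.
#' @param window Window width in bp (default 200).
#' @param fold Fold threshold (default 4, strict `>`).
#' @param pseudocount Added to both window means before the ratio (RPM
#'   units), guarding zero-coverage denominators.
#' @return Data frame: the input peaks plus `label`, `max_fold_a`,
#'   `max_fold_b`, `max_window_fold`, `window_start`, `window_end` (the
#'   winning window), `ambiguous`.
#' @export
classify_peaks <- function(peaks, track_a, track_b, window = 200L, fold = 4,
                           pseudocount = 0.1) {
  stopifnot(track_a$bin_size == track_b$bin_size)
  bin <- track_a$bin_size
  if (window < bin) stop("window must be >= bin_size")

  n <- nrow(peaks)
  label <- character(n); mfa <- mfb <- numeric(n)
  ws <- we <- integer(n); amb <- logical(n)
  for (i in seq_len(n)) {
    chrom <- peaks$chrom[i]
    s <- peaks$start[i]; e <- peaks$end[i]
    va <- track_a$counts[[chrom]]; vb <- track_b$counts[[chrom]]
    if (is.null(va) || is.null(vb)) stop("peak on chromosome absent from track")
    w <- min(window, e - s)
    # candidate offsets: bin-grid-aligned starts inside the peak plus the two
    # flush-to-edge windows; the ratio of two piecewise-linear window means is
    # monotone between grid crossings, so these offsets attain the maximum
    first_grid <- ceiling(s / bin) * bin
    grid_offsets <- if (first_grid <= e - w)
      seq(first_grid, e - w, by = bin) else numeric(0)
    offsets <- unique(c(s, grid_offsets, e - w))
    offsets <- offsets[offsets >= s & offsets + w <= e]
    fa <- fb <- 0
    best_a <- best_b <- c(s, s + w)
    for (o in offsets) {
      ma <- window_mean(va, bin, o, o + w) + pseudocount
      mb <- window_mean(vb, bin, o, o + w) + pseudocount
      if (ma / mb > fa) { fa <- ma / mb; best_a <- c(o, o + w) }
      if (mb / ma > fb) { fb <- mb / ma; best_b <- c(o, o + w) }
    }
    mfa[i] <- fa; mfb[i] <- fb
    a_hit <- fa > fold; b_hit <- fb > fold
    amb[i] <- a_hit && b_hit
    if (a_hit && (!b_hit || fa >= fb)) {
      label[i] <- "specific_A"; ws[i] <- best_a[1]; we[i] <- best_a[2]
    } else if (b_hit) {
      label[i] <- "specific_B"; ws[i] <- best_b[1]; we[i] <- best_b[2]
    } else {
      label[i] <- "constitutive"
      if (fa >= fb) { ws[i] <- best_a[1]; we[i] <- best_a[2] }
      else { ws[i] <- best_b[1]; we[i] <- best_b[2] }
    }
  }
  out <- peaks
  out$label <- label
  out$max_fold_a <- mfa
  out$max_fold_b <- mfb
  out$max_window_fold <- pmax(mfa, mfb)
  out$window_start <- ws
  out$window_end <- we
  out$ambiguous <- amb
  out
}

peaks_to_granges <- function(peaks, seqlevels = unique(peaks$chrom)) {
  GenomicRanges::GRanges(factor(peaks$chrom, levels = seqlevels),
                         IRanges::IRanges(start = peaks$start + 1L,
                                          end = peaks$end))
}

granges_to_peaks <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Combine replicate peak calls into a single set
#'
#' Union of the two interval sets with overlapping or book-ended intervals
#' coalesced; the result is sorted and non-overlapping.
#'
#' @param rep1,rep2 Peak data frames (`chrom`, `start`, `end`, 0-based
#'   half-open). `rep2` may be omitted to merely coalesce one set.
#' @param mode `"union"` (default) or `"intersection"` (regions covered by
#'   both replicates).
#' @return Sorted, non-overlapping peak data frame.
#' @export
merge_replicate_peaks <- function(rep1, rep2 = NULL, mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  check_intervals <- function(p) {
    if (nrow(p) > 0 && any(p$start >= p$end)) stop("malformed interval (start >= end)")
    if (nrow(p) > 0 && any(p$start < 0)) stop("negative interval start")
  }
  check_intervals(rep1)
  chroms <- sort(unique(c(rep1$chrom, rep2$chrom)))
  g1 <- peaks_to_granges(rep1, chroms)
  if (is.null(rep2)) {
    out <- GenomicRanges::reduce(GenomicRanges::sort(g1))
  } else {
    check_intervals(rep2)
    g2 <- peaks_to_granges(rep2, chroms)
    out <- if (mode == "union") {
      GenomicRanges::reduce(GenomicRanges::sort(c(g1, g2)))
    } else {
      GenomicRanges::reduce(GenomicRanges::intersect(g1, g2))
    }
  }
  granges_to_peaks(out)
}

#' Fraction of TF binding sites near a peak set
#'
#' A site counts as "near" when its minimal edge-to-edge distance to any peak
#' is at most `max_dist` bp; overlap counts as distance 0.
#'
#' @param tf_sites,peaks Peak data frames (0-based half-open).
#' @param max_dist Distance cutoff in bp (default 1000).
#' @return Fraction in `[0, 1]`; `NA` with a warning for an empty site set.
#' @export
overlap_fraction <- function(tf_sites, peaks, max_dist = 1000) {
  if (nrow(tf_sites) == 0) {
    warning("empty TF site set: overlap fraction undefined")
    return(NA_real_)
  }
  if (nrow(peaks) == 0) return(0)
  chroms <- unique(c(tf_sites$chrom, peaks$chrom))
  gs <- peaks_to_granges(tf_sites, chroms)
  gp <- peaks_to_granges(peaks, chroms)
  hits <- GenomicRanges::distanceToNearest(gs, gp)
  near <- rep(FALSE, length(gs))
  near[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance <= max_dist
  mean(near)
}
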