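# Interchange dialect: tab-separated, UTF-8, '#' comment lines.

#' Read a BED file of intervals
#'
#' Accepts 3-6 column BED (chrom, start, end, name, score, strand), 0-based
#' half-open. Invalid rows abort with their line number.
#'
#' @param path File path.
#' @param chrom_sizes Optional named vector of chromosome lengths; when given,
#'   unknown chromosomes and out-of-bounds intervals are rejected.
#' @return Data frame with the columns present in the file, `start`/`end`
#'   integer.
#' @export
read_bed <- function(path, chrom_sizes = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (length(fields) == 0) stop("empty BED file: ", path)
  if (any(ncols < 3))
    stop("line ", idx[which(ncols < 3)[1]], ": fewer than 3 BED columns")
  nc <- min(ncols)
  cols <- c("chrom", "start", "end", "name", "score", "strand")[seq_len(min(nc, 6))]
  out <- as.data.frame(do.call(rbind, lapply(fields, `[`, seq_along(cols))),
                       stringsAsFactors = FALSE)
  names(out) <- cols
  out$start <- suppressWarnings(as.integer(out$start))
  out$end <- suppressWarnings(as.integer(out$end))
  bad <- which(is.na(out$start) | is.na(out$end))
  if (length(bad) > 0) stop("line ", idx[bad[1]], ": non-integer coordinates")
  bad <- which(out$start >= out$end | out$start < 0)
  if (length(bad) > 0)
    stop("line ", idx[bad[1]], ": invalid interval (start >= end or negative)")
  if (!is.null(chrom_sizes)) {
    bad <- which(!out$chrom %in% names(chrom_sizes))
    if (length(bad) > 0)
      stop("line ", idx[bad[1]], ": unknown chromosome ", out$chrom[bad[1]])
    bad <- which(out$end > chrom_sizes[out$chrom])
    if (length(bad) > 0)
      stop("line ", idx[bad[1]], ": interval beyond chromosome end")
  }
  if ("score" %in% names(out)) out$score <- as.numeric(out$score)
  out
}

#' Write intervals as BED
#'
#' Writes exactly the columns present (up to chrom, start, end, name, score,
#' strand), tab-separated with no header, so that read -> write round-trips
#' byte-stably for valid input.
#'
#' @param peaks Interval data frame.
#' @param path Output path.
#' @export
write_bed <- function(peaks, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(peaks))
  df <- peaks[, cols, drop = FALSE]
  if ("score" %in% cols) df$score <- format(df$score, trim = TRUE,
                                            scientific = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a chrom.sizes file
#'
#' @param path Two-column (name, length) tab-separated file.
#' @return Named integer vector.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  stats::setNames(as.integer(df[[2]]), df[[1]])
}

#' Read/write peptidoform tables (areas or ratios)
#'
#' Tables are TSV with a leading `key` column (`histone:span:modstring` row
#' keys) and one column per sample ID.
#'
#' @param mat Matrix with row and column names.
#' @param path File path.
#' @return `read_area_table` returns the matrix; `write_area_table` the path,
#'   invisibly.
#' @export
write_area_table <- function(mat, path) {
  df <- data.frame(key = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_area_table
#' @export
read_area_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          comment.char = "#", stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$key
  mat
}

#' Read/write centroid spectra as rt/mz/intensity triplets
#'
#' @param spectra Data frame `rt`, `mz`, `intensity`.
#' @param path File path.
#' @export
write_spectra <- function(spectra, path) {
  utils::write.table(spectra[, c("rt", "mz", "intensity")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra
#' @export
read_spectra <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          comment.char = "#", stringsAsFactors = FALSE)
  df[order(df$rt, df$mz), c("rt", "mz", "intensity")]
}

#' Write a coverage track as bedGraph
#'
#' One line per bin (0-based half-open), value = bin mean.
#'
#' @param track A [coverage_track()].
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  rows <- lapply(names(track$counts), function(chrom) {
    v <- track$counts[[chrom]]
    n <- length(v)
    starts <- (seq_len(n) - 1L) * track$bin_size
    ends <- pmin(starts + track$bin_size, track$chrom_sizes[[chrom]])
    data.frame(chrom = chrom, start = starts, end = ends, value = v)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph file into a coverage track
#'
#' Bins must be regular and non-overlapping; the bin size is inferred.
#'
#' @param path bedGraph path.
#' @param chrom_sizes Named chromosome lengths.
#' @param total_mapped_reads Library size to attach (default: sum of values).
#' @return A [coverage_track()].
#' @export
read_bedgraph <- function(path, chrom_sizes, total_mapped_reads = NULL) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "value"))
  bin <- max(df$end - df$start)
  counts <- lapply(names(chrom_sizes), function(chrom) {
    n <- ceiling(chrom_sizes[[chrom]] / bin)
    v <- rep(0, n)
    rows <- df[df$chrom == chrom, , drop = FALSE]
    if (nrow(rows) > 0) v[rows$start %/% bin + 1L] <- rows$value
    v
  })
  names(counts) <- names(chrom_sizes)
  if (is.null(total_mapped_reads)) total_mapped_reads <- sum(df$value)
  coverage_track(counts, bin, chrom_sizes, total_mapped_reads)
}
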