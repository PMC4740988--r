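#' Average technical replicates
#'
#' Collapses sample columns `"<time>.<bio>.<tech>"` to `"<time>.<bio>"` by the
#' arithmetic mean over technical replicates. Undefined (`NA`) cells are
#' excluded from the mean; a cell that is undefined in every technical
#' replicate stays undefined. Inconsistent replicate counts across groups are
#' reported but not fatal.
#'
#' @param mat Ratio or mark-profile matrix with interchange sample IDs as
#'   column names.
#' @return Matrix with one column per (time point, biological replicate).
#' @export
average_technical_replicates <- function(mat) {
  coords <- parse_sample_ids(colnames(mat))
  grp <- paste(coords$time, coords$bio, sep = ".")
  groups <- unique(grp)
  counts <- table(grp)
  if (length(unique(counts)) > 1)
    message("unequal technical replicate counts across groups: ",
            paste(range(counts), collapse = "-"))
  out <- sapply(groups, function(g)
    rowMeans(mat[, grp == g, drop = FALSE], na.rm = TRUE))
  out[is.nan(out)] <- NA_real_
  out <- matrix(out, nrow = nrow(mat),
                dimnames = list(rownames(mat), groups))
  out
}

#' Single-mark marginal abundances
#'
#' The abundance of a single PTM (e.g. `H3K9me2`) in a sample is the sum of
#' the relative ratios of all peptidoforms in that mark's family that carry
#' the mark — the marginal over the combinatorial states.
#'
#' @param ratios Relative-abundance matrix (peptidoform keys x samples).
#' @param lib The `peptidoform_library` defining which marks each row carries.
#' @return Mark x sample matrix with cells in `[0, 1]`, rows sorted by label.
#' @export
single_mark_abundance <- function(ratios, lib) {
  if (!all(rownames(ratios) %in% lib$key))
    stop("ratio rows missing from the library")
  marks_by_form <- peptidoform_marks(lib)
  names(marks_by_form) <- lib$key
  all_marks <- sort(unique(unlist(marks_by_form)))
  if (length(all_marks) == 0)
    return(matrix(numeric(0), 0, ncol(ratios),
                  dimnames = list(NULL, colnames(ratios))))
  out <- do.call(rbind, lapply(all_marks, function(m) {
    carriers <- names(marks_by_form)[vapply(marks_by_form,
                                            function(x) m %in% x, NA)]
    carriers <- intersect(carriers, rownames(ratios))
    colSums(ratios[carriers, , drop = FALSE])
  }))
  dimnames(out) <- list(all_marks, colnames(ratios))
  out
}

#' Acetyl-state profile of a peptide family
#'
#' Sums relative ratios by the exact number of acetylated lysines, yielding
#' the 0..K acetylation-state distribution of (by default) the H4 aa 4-17
#' peptide that carries all four H4 acetylation sites. Columns are exact
#' partitions of unity wherever the family's ratios are defined.
#'
#' @param ratios Relative-abundance matrix.
#' @param lib The `peptidoform_library`.
#' @param histone,span Family selector (histone name and
#'   `c(start_res, end_res)`).
#' @return Acetyl-count x sample matrix, rownames `"0ac"`, `"1ac"`, ...
#' @export
acetyl_state_profile <- function(ratios, lib, histone = "H4", span = c(4, 17)) {
  sel <- lib$histone == histone & lib$start_res == span[1] & lib$end_res == span[2]
  if (!any(sel)) stop("family ", histone, " ", span[1], "-", span[2],
                      " absent from library")
  keys <- intersect(lib$key[sel], rownames(ratios))
  if (length(keys) == 0) stop("family absent from ratio table")
  nac <- lib$n_acetyl[match(keys, lib$key)]
  states <- 0:max(lib$n_acetyl[sel])
  out <- t(vapply(states, function(k)
    colSums(ratios[keys[nac == k], , drop = FALSE]),
    numeric(ncol(ratios))))
  dimnames(out) <- list(paste0(states, "ac"), colnames(ratios))
  out
}

#' Row-wise z-score normalization
#'
#' Standard heatmap preprocessing: each row is centred by its mean and scaled
#' by its sample standard deviation (denominator n - 1). Rows with zero
#' spread are set to all zeros with a warning.
#'
#' @param mat Numeric matrix.
#' @return Matrix of z-scores with the same dimnames.
#' @export
zscore_rows <- function(mat) {
  mu <- rowMeans(mat)
  sd <- apply(mat, 1, stats::sd)
  flat <- sd == 0 | is.na(sd)
  if (any(flat)) {
    warning(sum(flat), " constant row(s) set to zero in z-scoring")
    sd[flat] <- 1
  }
  out <- sweep(sweep(mat, 1, mu, "-"), 1, sd, "/")
  out[flat, ] <- 0
  out
}

#' Long-format export of a profile matrix
#'
#' @param mat Matrix with row and column names.
#' @return Data frame `row`, `sample`, `value` (heatmap-ready long format).
#' @export
profile_long <- function(mat) {
  data.frame(row = rep(rownames(mat), ncol(mat)),
             sample = rep(colnames(mat), each = nrow(mat)),
             value = as.vector(mat),
             stringsAsFactors = FALSE)
}
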