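# Monoisotopic residue masses (Da), standard IUPAC/Unimod values for the 20
# proteinogenic amino acids (residue = amino acid minus water).
RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

# Modification delta masses (Da), Unimod monoisotopic values.
MOD_MASS <- c(
  un  = 0,
  me1 = 14.015650,
  me2 = 28.031300,
  me3 = 42.046950,
  ac  = 42.010565
)

WATER_MASS <- 18.010565
PROPIONYL_MASS <- 56.026215
PROTON_MASS <- 1.007276

MOD_CODES <- names(MOD_MASS)

#' Neutral monoisotopic mass of a derivatized histone peptidoform
#'
#' Computes the neutral mass of a tryptic histone peptide carrying a given
#' combinatorial modification state, under propionic-anhydride derivatization
#' chemistry: the peptide N-terminus is always propionylated, and every lysine
#' that is unmodified or monomethylated additionally carries a propionyl group
#' on its side chain. Acetylated, dimethylated and trimethylated lysines block
#' propionylation.
#'
#' @param sequence Amino-acid string (one-letter codes) of the peptide.
#' @param mods Named numeric-to-code map: names are protein residue numbers
#'   (as character), values are modification codes among
#'   `"un"`, `"me1"`, `"me2"`, `"me3"`, `"ac"`. May be empty.
#' @param start_res 1-based protein residue number of the first peptide
#'   residue, used to translate residue numbers to positions in `sequence`.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' peptidoform_mass("GKGGKGLGKGGAKR", c("5" = "ac", "8" = "un",
#'                                      "12" = "un", "16" = "un"), start_res = 4)
#' @export
peptidoform_mass <- function(sequence, mods = c(), start_res = 1L) {
  aa <- strsplit(sequence, "")[[1]]
  bad <- setdiff(aa, names(RESIDUE_MASS))
  if (length(bad) > 0)
    stop("unknown amino acid(s): ", paste(unique(bad), collapse = ", "))
  end_res <- start_res + length(aa) - 1L
  mass <- sum(RESIDUE_MASS[aa]) + WATER_MASS + PROPIONYL_MASS  # N-terminal pr

  mod_res <- as.integer(names(mods))
  if (any(is.na(mod_res)))
    stop("modification residue numbers must be integers")
  if (any(mod_res < start_res | mod_res > end_res))
    stop("modified residue outside peptide span [", start_res, ", ", end_res, "]")
  if (anyDuplicated(mod_res))
    stop("a residue carries more than one modification code")

  codes <- as.character(mods)
  unknown <- setdiff(codes, MOD_CODES)
  if (length(unknown) > 0)
    stop("unknown modification code(s): ", paste(unique(unknown), collapse = ", "))
  mass <- mass + sum(MOD_MASS[codes])

  # side-chain propionylation of free / monomethyl lysines
  for (i in seq_along(aa)) {
    if (aa[i] != "K") next
    res <- start_res + i - 1L
    code <- if (res %in% mod_res) codes[match(res, mod_res)] else "un"
    if (code %in% c("un", "me1")) mass <- mass + PROPIONYL_MASS
  }
  mass
}

#' m/z of a peptidoform at a given charge state
#'
#' @param p A peptidoform row (from [build_peptidoform_library()]) or a bare
#'   neutral mass in Da.
#' @param charge Positive integer charge state.
#' @return m/z in Thomson: `(neutral_mass + charge * proton) / charge`.
#' @export
compute_mz <- function(p, charge) {
  if (length(charge) != 1L || is.na(charge) || charge < 1 || charge != round(charge))
    stop("charge must be a positive integer")
  mass <- if (is.numeric(p)) p else p$neutral_mass
  (mass + charge * PROTON_MASS) / charge
}

mod_string <- function(residues, codes) {
  paste0("K", residues, codes, collapse = "_")
}

#' Build the combinatorial peptidoform library for a set of histone peptides
#'
#' Expands each peptide definition into the full cross-product of allowed
#' modification states per modifiable residue, applies the derivatization
#' rules and computes neutral masses. Row keys follow the interchange
#' convention `histone:start-end:K<res><code>_K<res><code>_...`.
#'
#' @param histone_spec A list of peptide definitions. Each definition is a
#'   list with elements `histone` (e.g. `"H4"`), `sequence`, `start_res`, and
#'   `sites`, a named list mapping residue numbers (character names) to the
#'   vector of allowed codes at that residue (subset of
#'   `un`, `me1`, `me2`, `me3`, `ac`).
#' @return A data frame of class `peptidoform_library` with one row per
#'   peptidoform: `key`, `histone`, `start_res`, `end_res`, `sequence`,
#'   `mods` (the mod string), `neutral_mass`, and `n_acetyl`.
#' @seealso [default_histone_library()] for the stock H3/H4 definitions.
#' @export
build_peptidoform_library <- function(histone_spec) {
  if (length(histone_spec) == 0) stop("empty histone_spec")
  rows <- lapply(histone_spec, function(def) {
    stopifnot(is.character(def$sequence), length(def$sites) > 0)
    start_res <- as.integer(def$start_res)
    end_res <- start_res + nchar(def$sequence) - 1L
    res_nums <- as.integer(names(def$sites))
    if (any(is.na(res_nums)))
      stop("site names must be residue numbers")
    if (any(res_nums < start_res | res_nums > end_res))
      stop("modifiable residue outside peptide span for ", def$histone,
           " ", start_res, "-", end_res)
    for (codes in def$sites) {
      if (length(codes) == 0) stop("empty allowed-code set")
      if (!all(codes %in% MOD_CODES))
        stop("unknown modification code(s): ",
             paste(setdiff(codes, MOD_CODES), collapse = ", "))
    }
    grid <- expand.grid(def$sites, stringsAsFactors = FALSE)
    ord <- order(res_nums)
    do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
      codes <- as.character(grid[i, ])
      mods <- stats::setNames(codes, as.character(res_nums))
      mods <- mods[order(as.integer(names(mods)))]
      data.frame(
        key = paste0(def$histone, ":", start_res, "-", end_res, ":",
                     mod_string(names(mods), as.character(mods))),
        histone = def$histone,
        start_res = start_res,
        end_res = end_res,
        sequence = def$sequence,
        mods = mod_string(names(mods), as.character(mods)),
        neutral_mass = peptidoform_mass(def$sequence, mods, start_res),
        n_acetyl = sum(mods == "ac"),
        stringsAsFactors = FALSE
      )
    }))
  })
  lib <- do.call(rbind, rows)
  rownames(lib) <- NULL
  if (anyDuplicated(lib$key)) stop("duplicate peptidoform keys")
  class(lib) <- c("peptidoform_library", "data.frame")
  lib
}

#' Stock histone H3/H4 peptide definitions
#'
#' Three tryptic peptide families covering the marks this package profiles by
#' default: H4 aa 4-17 (`GKGGKGLGKGGAKR`, all four H4 acetylation sites K5,
#' K8, K12, K16), H3 aa 3-8 (`TKQTAR`, K4 methylation states) and H3 aa 9-17
#' (`KSTGGKAPR`, K9 methylation/acetylation x K14 acetylation).
#'
#' @return A `histone_spec` list suitable for [build_peptidoform_library()].
#' @export
default_histone_spec <- function() {
  list(
    list(histone = "H4", sequence = "GKGGKGLGKGGAKR", start_res = 4,
         sites = list("5" = c("un", "ac"), "8" = c("un", "ac"),
                      "12" = c("un", "ac"), "16" = c("un", "ac"))),
    list(histone = "H3", sequence = "TKQTAR", start_res = 3,
         sites = list("4" = c("un", "me1", "me2", "me3"))),
    list(histone = "H3", sequence = "KSTGGKAPR", start_res = 9,
         sites = list("9" = c("un", "me1", "me2", "me3", "ac"),
                      "14" = c("un", "ac")))
  )
}

#' @rdname default_histone_spec
#' @export
default_histone_library <- function() {
  build_peptidoform_library(default_histone_spec())
}

# family id = histone + span; the unit within which relative ratios normalize
family_of <- function(keys) {
  sub("^([^:]+:[^:]+):.*$", "\\1", keys)
}

# parse "K5ac_K8un_..." into a named code vector
parse_mods <- function(modstr) {
  parts <- strsplit(modstr, "_", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^K([0-9]+)([a-z0-9]+)$", parts))
  stats::setNames(vapply(m, `[`, "", 3L), vapply(m, `[`, "", 2L))
}

#' Single-mark labels carried by each library entry
#'
#' A mark label is `"<histone>K<residue><code>"` (e.g. `H3K9me2`, `H4K16ac`)
#' for every non-`un` code in the peptidoform's modification state.
#'
#' @param lib A `peptidoform_library`.
#' @return A list, parallel to the library rows, of character vectors of marks.
#' @export
peptidoform_marks <- function(lib) {
  lapply(seq_len(nrow(lib)), function(i) {
    mods <- parse_mods(lib$mods[i])
    mods <- mods[mods != "un"]
    if (length(mods) == 0) return(character(0))
    paste0(lib$histone[i], "K", names(mods), unname(mods))
  })
}
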