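# Monoisotopic (most abundant isotope) atomic masses, Da, 6 decimals.
# Covers the elements expected in TMS-derivatized metabolites.
.ISOTOPE_MASS <- c(
  H  = 1.007825,
  C  = 12.000000,
  N  = 14.003074,
  O  = 15.994915,
  F  = 18.998403,
  Na = 22.989770,
  Si = 27.976927,
  P  = 30.973762,
  S  = 31.972071,
  Cl = 34.968853,
  K  = 38.963707,
  Br = 78.918338,
  I  = 126.904473
)

#' Parse a molecular formula into element counts
#'
#' @param formula A Hill-style molecular formula such as `"C4H12OSi"`.
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("C4H12OSi")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  if (nzchar(gsub("([A-Z][a-z]?)([0-9]*)", "", formula)))
    stop("malformed molecular formula: ", formula)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  toks <- toks[nzchar(toks)]
  el <- sub("^([A-Z][a-z]?).*$", "\\1", toks)
  n <- as.integer(sub("^[A-Z][a-z]?", "", paste0(toks, "")))
  n[is.na(n)] <- 1L
  counts <- tapply(n, el, sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

#' Monoisotopic mass of a molecular formula
#'
#' Sums most-abundant-isotope atomic masses over the element counts of a
#' formula. Used by [monoisotopic_mass()] after the formula of a parsed
#' structure is derived.
#'
#' @param formula Molecular formula string (implicit hydrogens already
#'   resolved), e.g. `"C2H6O"`.
#' @return Mass in Da.
#' @examples
#' mass_from_formula("H2O")
#' @export
mass_from_formula <- function(formula) {
  counts <- parse_formula(formula)
  unknown <- setdiff(names(counts), names(.ISOTOPE_MASS))
  if (length(unknown))
    stop("no tabulated isotope mass for element(s): ",
         paste(unknown, collapse = ", "))
  sum(.ISOTOPE_MASS[names(counts)] * counts)
}
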