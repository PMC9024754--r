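# SMILES parsing and substructure utilities, backed by OpenBabel through
# ChemmineOB. Molecules are parsed in batch; a failed parse anywhere in a
# batch is retried molecule-by-molecule so the offender can be reported.

# SMARTS for one trimethylsilyl group: Si bonded to exactly three methyl
# carbons and one heteroatom (O, N or S). Pure-carbon silanes do not count;
# trimethylsilylation replaces the acidic proton of hydroxyl, carboxyl,
# amino or thiol groups.
.TMS_SMARTS <- "[Si]([CH3])([CH3])([CH3])[#7,#8,#16]"

# Parse a character vector of SMILES into OpenBabel molecule references.
# Returns a list of OBMol refs; stops naming the first invalid SMILES.
parse_molecules <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  res <- try(suppressWarnings(
    ChemmineOB::forEachMol("SMILES", paste(smiles, collapse = "\n"), identity)
  ), silent = TRUE)
  if (!inherits(res, "try-error") && length(res) == length(smiles)) return(res)
  for (i in seq_along(smiles)) {
    one <- try(suppressWarnings(
      ChemmineOB::forEachMol("SMILES", smiles[i], identity)), silent = TRUE)
    if (inherits(one, "try-error") || length(one) != 1L)
      stop("invalid SMILES at position ", i, ": ", smiles[i])
  }
  stop("SMILES batch failed to parse")
}

# TRUE for each SMILES that OpenBabel parses to a non-empty molecule.
smiles_is_valid <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(FALSE)
    one <- try(suppressWarnings(
      ChemmineOB::forEachMol("SMILES", s, identity)), silent = TRUE)
    if (inherits(one, "try-error") || length(one) != 1L) return(FALSE)
    m <- try(suppressWarnings(ChemmineOB::exactMass_OB(one)), silent = TRUE)
    !inherits(m, "try-error") && is.finite(m) && m > 0
  }, logical(1), USE.NAMES = FALSE)
}

#' Count trimethylsilyl groups in a structure
#'
#' Counts non-overlapping TMS substructures: a silicon carrying three methyl
#' groups and bonded to O, N or S.
#'
#' @param smiles Character vector of SMILES.
#' @return Integer vector of TMS-group counts.
#' @examples
#' \donttest{
#' count_tms_groups(c("CCO", "CO[Si](C)(C)C"))
#' }
#' @export
count_tms_groups <- function(smiles) {
  mols <- parse_molecules(smiles)
  n <- ChemmineOB::smartsSearch_OB(mols, .TMS_SMARTS, uniqueMatches = TRUE)
  as.integer(n)
}

#' Monoisotopic mass of a molecule
#'
#' Derives the molecular formula of each parsed structure (implicit
#' hydrogens filled in) and sums most-abundant-isotope atomic masses from
#' the embedded isotope table.
#'
#' @param smiles Character vector of SMILES.
#' @return Numeric vector of masses in Da.
#' @examples
#' \donttest{
#' monoisotopic_mass("O")  # water, 18.01056
#' }
#' @export
monoisotopic_mass <- function(smiles) {
  mols <- parse_molecules(smiles)
  forms <- ChemmineOB::prop_OB(mols)$formula
  vapply(forms, mass_from_formula, numeric(1), USE.NAMES = FALSE)
}
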