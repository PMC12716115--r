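# Monoisotopic residue masses for the 20 proteinogenic amino acids, and the
# neutral adjustments used when turning a residue chain into fragment masses.
# Residue mass = mass of the amino acid minus one water (peptide-bond loss).
AA_MONO <- c(
  G = 57.02146372, A = 71.03711378, S = 87.03202840, P = 97.05276384,
  V = 99.06841390, T = 101.04767846, C = 103.00918495, L = 113.08406396,
  I = 113.08406396, N = 114.04292744, D = 115.02694302, Q = 128.05857750,
  K = 128.09496301, E = 129.04259308, M = 131.04048508, H = 137.05891186,
  F = 147.06841390, R = 156.10111102, Y = 163.06332852, W = 186.07931294
)

WATER_MONO <- 18.01056468
PROTON_MASS <- 1.00727646688

#' Monoisotopic residue masses
#'
#' Returns the table of monoisotopic residue masses (amino acid minus water,
#' in Daltons) used throughout the package for theoretical fragment masses.
#'
#' @return A named numeric vector over the 20-letter amino-acid alphabet.
#' @export
#' @examples
#' residue_masses()[c("A", "G")]
residue_masses <- function() {
  AA_MONO
}

#' Theoretical prefix (b-type) fragment masses of a sequence
#'
#' Computes the neutral monoisotopic N-terminal prefix masses at every
#' cleavage site of an unmodified proteoform, together with its neutral
#' proteoform mass (residue masses plus one water). Suffix (y-type) masses
#' are complements: `proteoform_mass - prefix_masses`.
#'
#' @param sequence Amino-acid string over the 20-letter alphabet, length >= 2.
#' @return A list with elements `prefix_masses` (numeric, length
#'   `nchar(sequence) - 1`, strictly increasing) and `proteoform_mass` (Da).
#' @export
#' @examples
#' theoretical_prefix_masses("AG")
theoretical_prefix_masses <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  residues <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (length(residues) < 2L) {
    abort("sequence must have length >= 2 (no cleavage sites otherwise)")
  }
  masses <- AA_MONO[residues]
  if (anyNA(masses)) {
    bad <- unique(residues[is.na(masses)])
    abort(paste0("illegal residue(s): ", paste(bad, collapse = ", ")))
  }
  cums <- cumsum(unname(masses))
  list(
    prefix_masses = cums[-length(cums)],
    proteoform_mass = cums[length(cums)] + WATER_MONO
  )
}
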