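# Tab-separated result tables. Column sets are fixed so downstream tooling
# can rely on them:
#   PrSM:   spectrum_id, precursor_rank, accession, is_decoy, proteoform_mass,
#           shift_count, shift_da, matched_count, nnmfm, evalue
#   groups: group_id, accession, is_decoy, representative_mass, best_evalue,
#           n_members, spectrum_ids (';'-separated)
#   truth:  spectrum_id, base_accession, additive_accession, base_shift_da,
#           additive_shift_da, base_frag_count, additive_frag_count

PRSM_TSV_COLS <- c(
  "spectrum_id", "precursor_rank", "accession", "is_decoy", "proteoform_mass",
  "shift_count", "shift_da", "matched_count", "nnmfm", "evalue"
)

#' Write a PrSM table
#'
#' @param prsms A PrSM tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_prsm_tsv <- function(prsms, path) {
  out <- as_tibble(prsms)[, PRSM_TSV_COLS, drop = FALSE]
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a PrSM table written by [write_prsm_tsv()]
#'
#' @param path TSV path.
#' @return A PrSM tibble (without matched-mass sets).
#' @export
read_prsm_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    spectrum_id = readr::col_character(),
    precursor_rank = readr::col_integer(),
    accession = readr::col_character(),
    is_decoy = readr::col_logical(),
    proteoform_mass = readr::col_double(),
    shift_count = readr::col_integer(),
    shift_da = readr::col_double(),
    matched_count = readr::col_integer(),
    nnmfm = readr::col_double(),
    evalue = readr::col_double()
  ))
}

#' Write a proteoform-group table
#'
#' @param groups A proteoform-group tibble from [group_proteoforms()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_groups_tsv <- function(groups, path) {
  out <- tibble(
    group_id = groups$group_id,
    accession = groups$accession,
    is_decoy = groups$is_decoy,
    representative_mass = groups$representative_mass,
    best_evalue = groups$best_evalue,
    n_members = groups$n_members,
    spectrum_ids = map_chr(groups$spectrum_ids, paste, collapse = ";")
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write a ground-truth table
#'
#' @param truth A ground-truth tibble (from the simulator or the
#'   pseudo-multiplexed generators).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  out <- tibble(
    spectrum_id = truth$spectrum_id,
    base_accession = truth$base_accession,
    additive_accession = truth$additive_accession,
    base_shift_da = truth$base_shift_da,
    additive_shift_da = truth$additive_shift_da,
    base_frag_count = truth$base_frag_count,
    additive_frag_count = truth$additive_frag_count
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a ground-truth table
#'
#' @param path TSV path written by [write_ground_truth()].
#' @return A ground-truth tibble.
#' @export
read_ground_truth <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    spectrum_id = readr::col_character(),
    base_accession = readr::col_character(),
    additive_accession = readr::col_character(),
    base_shift_da = readr::col_double(),
    additive_shift_da = readr::col_double(),
    base_frag_count = readr::col_integer(),
    additive_frag_count = readr::col_integer()
  ))
}
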