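DECOY_PREFIX <- "DECOY_"

#' Read a protein database
#'
#' Reads a FASTA file into a protein tibble. The accession is the first
#' whitespace-delimited token of each header; sequences are uppercased and
#' must use only the 20-letter amino-acid alphabet. Accessions starting with
#' `DECOY_` are flagged as decoys.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `accession`, `sequence`, `is_decoy`.
#' @export
read_fasta <- function(path) {
  seqs <- withCallingHandlers(
    Biostrings::readAAStringSet(path),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w))) {
        lines <- readLines(path)
        rec <- cumsum(startsWith(lines, ">"))
        ids <- sub("\\s.*$", "", sub("^>", "", lines[startsWith(lines, ">")]))
        bad <- unique(rec[!startsWith(lines, ">") & grepl("[^A-Za-z]", lines)])
        abort(paste0("illegal residue in record(s): ",
                     paste(ids[bad], collapse = ", ")))
      }
      invokeRestart("muffleWarning")
    }
  )
  if (length(seqs) == 0L) abort("empty FASTA file")
  accession <- sub("\\s.*$", "", names(seqs))
  sequence <- toupper(as.character(seqs))
  dup <- accession[duplicated(accession)]
  if (length(dup)) {
    abort(paste0("duplicate accession(s): ", paste(unique(dup), collapse = ", ")))
  }
  ok <- grepl(paste0("^[", paste(names(AA_MONO), collapse = ""), "]+$"), sequence)
  if (!all(ok)) {
    abort(paste0("illegal residue in record(s): ",
                 paste(accession[!ok], collapse = ", ")))
  }
  tibble(
    accession = unname(accession),
    sequence = unname(sequence),
    is_decoy = startsWith(accession, DECOY_PREFIX)
  )
}

#' Write a protein database
#'
#' @param proteins A protein tibble (`accession`, `sequence`).
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  seqs <- Biostrings::AAStringSet(setNames(proteins$sequence, proteins$accession))
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' Append a shuffled decoy database
#'
#' Builds one decoy per target protein by a seeded uniform shuffle of its
#' residues, with accession `DECOY_<target accession>`. The concatenated
#' target-decoy tibble (targets first) is returned; decoys preserve each
#' target's residue composition and therefore its proteoform mass.
#'
#' @param db Target protein tibble.
#' @param seed Integer seed; the same seed reproduces identical decoys.
#' @return A tibble with `2 * nrow(db)` rows.
#' @export
build_decoy_db <- function(db, seed = 1L) {
  if (any(db$is_decoy)) abort("db already contains decoys")
  decoy_seq <- withr::with_seed(as.integer(seed), {
    vapply(db$sequence, function(s) {
      paste(sample(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
    }, character(1), USE.NAMES = FALSE)
  })
  bind_rows(
    db,
    tibble(
      accession = paste0(DECOY_PREFIX, db$accession),
      sequence = decoy_seq,
      is_decoy = TRUE
    )
  )
}
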