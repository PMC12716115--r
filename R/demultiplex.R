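# Core demultiplexing stages: multiplexed classification, error-prone
# detection, NNMFM-based primary-precursor selection, and the two-round
# search-and-subtract identification.

#' Isolation-window precursor intensity
#'
#' Sums the intensities of the feature peaks that fall inside the isolation
#' window — the definition of a precursor's intensity used for multiplexed
#' classification. Provided for callers that have MS1 feature peaks; files
#' read by [read_spectra()] already carry this value per precursor.
#'
#' @param feature_peaks A data frame with columns `mz` and `intensity`
#'   (all peaks of one proteoform feature in the relevant MS1 scan).
#' @param iso_lo,iso_hi Isolation-window m/z bounds.
#' @return The summed intensity (0 when no peak falls in the window).
#' @export
#' @examples
#' peaks <- data.frame(mz = c(900.1, 900.9, 1101.2),
#'                     intensity = c(500, 300, 200))
#' precursor_intensity(peaks, 899.5, 902.5)
precursor_intensity <- function(feature_peaks, iso_lo, iso_hi) {
  inside <- feature_peaks$mz >= iso_lo & feature_peaks$mz <= iso_hi
  sum(feature_peaks$intensity[inside])
}

#' Classify a spectrum as multiplexed or single
#'
#' A spectrum with two candidate precursors is multiplexed when the
#' intensity ratio of the second- to the highest-intensity precursor is at
#' least `alpha` (inclusive boundary); otherwise — including when only one
#' precursor exists — it is treated as single and only the top precursor is
#' retained for identification.
#'
#' @param spectrum One row of a spectra tibble.
#' @param alpha Intensity-ratio threshold in \[0, 1\].
#' @return `"multiplexed"` or `"single"`.
#' @export
classify_spectrum <- function(spectrum, alpha) {
  pr <- spectrum$precursors[[1]]
  if (nrow(pr) < 2L) return("single")
  i1 <- pr$intensity[1]
  i2 <- pr$intensity[2]
  if (i1 <= 0) {
    inform(paste0("spectrum ", spectrum$spectrum_id,
                  ": zero top precursor intensity; treated as single"))
    return("single")
  }
  if (i2 / i1 >= alpha) "multiplexed" else "single"
}

#' Ratio of shared matched fragment masses
#'
#' `|M1 n M2| / min(|M1|, |M2|)` for two matched-mass sets from the same
#' spectrum (masses compared exactly; both sets are literal spectrum
#' entries). Defined as 0 when either set is empty.
#'
#' @param m1,m2 Numeric vectors of matched experimental masses.
#' @return A fraction in \[0, 1\].
#' @export
shared_match_ratio <- function(m1, m2) {
  if (!length(m1) || !length(m2)) {
    inform("empty matched-mass set; shared ratio defined as 0")
    return(0)
  }
  length(intersect(m1, m2)) / min(length(m1), length(m2))
}

#' Detect an error-prone spectrum
#'
#' A multiplexed spectrum whose two PFPS identifications hit the same
#' protein, or share at least a fraction `beta` (inclusive) of their matched
#' fragment masses, likely contains a precursor selection error.
#'
#' @param prsm1,prsm2 One-row PrSM tibbles from the two PFPSs of one
#'   spectrum.
#' @param beta Shared-ratio threshold in \[0, 1\].
#' @return `TRUE` when the spectrum is error-prone.
#' @export
detect_error_prone <- function(prsm1, prsm2, beta) {
  if (prsm1$accession == prsm2$accession) return(TRUE)
  shared_match_ratio(prsm1$matched_masses[[1]], prsm2$matched_masses[[1]]) >= beta
}

#' Normalized matched fragment mass count (NNMFM)
#'
#' `x - y * delta - z * gamma`: the matched-fragment count penalized by
#' `delta` per unknown mass shift and by `gamma` when the PrSM belongs to
#' the second-highest-intensity precursor (`z = 1`). May be negative.
#'
#' @param x Matched fragment count.
#' @param y Number of unknown mass shifts (0 or 1 here).
#' @param z 0 for the highest-intensity precursor, 1 for the second.
#' @param delta,gamma Penalties in fragment-count units.
#' @return The NNMFM score.
#' @export
#' @examples
#' nnmfm(20, 1, 1, 5, 4)
nnmfm <- function(x, y, z, delta, gamma) {
  stopifnot(all(x >= 0), all(y >= 0))
  x - y * delta - z * gamma
}

#' Select the primary precursor of a multiplexed spectrum
#'
#' Builds the two PFPSs (each candidate precursor paired with all fragment
#' masses), searches both, and picks the precursor searched first in the
#' two-round identification: the only identified precursor when just one
#' PFPS yields a PrSM; the top-intensity precursor when both yield PrSMs
#' that are not error-prone (order is then immaterial) or when neither
#' yields one; and the precursor of the higher-NNMFM PrSM for error-prone
#' spectra (ties favor the top-intensity precursor).
#'
#' @param spectrum One row of a spectra tibble, classified multiplexed.
#' @param db Protein tibble or [build_search_index()] object.
#' @param cfg A [demux_config()].
#' @return A list: `primary_rank` (0 = top-intensity precursor), `prsm1`,
#'   `prsm2` (PrSMs of the rank-0/rank-1 PFPSs or `NULL`) and `error_prone`.
#' @export
select_primary <- function(spectrum, db, cfg = demux_config()) {
  index <- build_search_index(db)
  pr <- spectrum$precursors[[1]]
  frags <- spectrum$frag_masses[[1]]
  prsm1 <- search_pfps(pr[1, ], frags, index, cfg)
  prsm2 <- if (nrow(pr) >= 2L) search_pfps(pr[2, ], frags, index, cfg) else NULL
  error_prone <- FALSE
  if (is.null(prsm1) && is.null(prsm2)) {
    primary <- 0L
  } else if (is.null(prsm2)) {
    primary <- 0L
  } else if (is.null(prsm1)) {
    primary <- 1L
  } else {
    error_prone <- detect_error_prone(prsm1, prsm2, cfg$beta)
    primary <- if (!error_prone) 0L else if (prsm2$nnmfm > prsm1$nnmfm) 1L else 0L
  }
  list(primary_rank = primary, prsm1 = prsm1, prsm2 = prsm2,
       error_prone = error_prone)
}

#' Two-round search-and-subtract identification
#'
#' Searches the primary precursor against all fragment masses; when a PrSM
#' is found, its matched experimental masses are removed and the secondary
#' precursor is searched against the remainder. When both rounds identify
#' the same protein, only the lower-E-value PrSM is kept. For single
#' (non-multiplexed) spectra only round 1 runs.
#'
#' @param spectrum One row of a spectra tibble.
#' @param db Protein tibble or [build_search_index()] object.
#' @param cfg A [demux_config()].
#' @param primary_rank 0-based rank of the primary precursor.
#' @param run_round2 Whether a second round should run (multiplexed spectra
#'   with two precursors).
#' @param round1_prsm Optional precomputed round-1 PrSM (as returned by
#'   [select_primary()] for the primary PFPS) to avoid a repeated search.
#' @return A PrSM tibble with 0-2 rows and a `round` column.
#' @export
two_round_search <- function(spectrum, db, cfg = demux_config(),
                             primary_rank = 0L, run_round2 = TRUE,
                             round1_prsm = NULL) {
  index <- build_search_index(db)
  pr <- spectrum$precursors[[1]]
  frags <- spectrum$frag_masses[[1]]
  if (nrow(pr) < 2L) run_round2 <- FALSE
  prim <- primary_rank + 1L
  sec <- if (prim == 1L) 2L else 1L

  prsm_a <- if (is.null(round1_prsm)) {
    search_pfps(pr[prim, ], frags, index, cfg)
  } else {
    round1_prsm
  }
  remaining <- frags
  if (!is.null(prsm_a)) {
    prsm_a$round <- 1L
    remaining <- setdiff(frags, prsm_a$matched_masses[[1]])
  }
  prsm_b <- NULL
  if (run_round2) {
    prsm_b <- search_pfps(pr[sec, ], remaining, index, cfg)
    if (!is.null(prsm_b)) prsm_b$round <- 2L
  }
  if (!is.null(prsm_a) && !is.null(prsm_b) &&
      prsm_a$accession == prsm_b$accession) {
    if (prsm_b$evalue < prsm_a$evalue) prsm_a <- NULL else prsm_b <- NULL
  }
  out <- bind_rows(prsm_a, prsm_b)
  if (!nrow(out)) return(empty_prsm_tibble())
  out$spectrum_id <- spectrum$spectrum_id
  out
}
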