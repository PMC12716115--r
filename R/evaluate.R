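# Scoring identifications against ground truth: correct / precursor
# selection error (PSE) / random matching error (RME), and the delta/gamma
# parameter-sweep harness.

#' Classify one identification against ground truth
#'
#' An identification for a precursor role is `correct` when it matches the
#' role's true protein, a `PSE` when it matches the *other* co-isolated
#' precursor's protein, and an `RME` (random matching error) otherwise.
#' Vectorized over its arguments.
#'
#' @param accession Identified protein accession(s).
#' @param base_accession,additive_accession True proteins of the two roles
#'   (`additive_accession` may be `NA` for single-proteoform spectra).
#' @param role `"base"` (highest-intensity precursor) or `"additive"`.
#' @return Character vector over `c("correct", "PSE", "RME")`.
#' @export
#' @examples
#' classify_error("P1", "P1", "P2", "base")
#' classify_error("P2", "P1", "P2", "base")
classify_error <- function(accession, base_accession, additive_accession,
                           role) {
  own <- ifelse(role == "base", base_accession, additive_accession)
  other <- ifelse(role == "base", additive_accession, base_accession)
  dplyr::case_when(
    !is.na(own) & accession == own ~ "correct",
    !is.na(other) & accession == other ~ "PSE",
    TRUE ~ "RME"
  )
}

#' Score pipeline output against ground truth
#'
#' Joins accepted PrSMs to the ground-truth table by spectrum id, assigns
#' each PrSM its precursor role from its precursor rank (rank 0 = base, the
#' highest-intensity precursor), classifies every identification with
#' [classify_error()], and tallies per-role counts. `n_missed` counts truth
#' entries of the role with no accepted identification, so counts per role
#' sum to the number of truth entries. Error rates are fractions of
#' identified spectra; `id_rate` is the identified fraction of truth
#' entries.
#'
#' @param prsms Accepted PrSM tibble (e.g. `run_pipeline(...)$prsms`).
#' @param truth Ground-truth tibble.
#' @return An `error_report` tibble with one row per role.
#' @export
evaluate_errors <- function(prsms, truth) {
  scored <- prsms
  scored$role <- ifelse(scored$precursor_rank == 0L, "base", "additive")
  ti <- match(scored$spectrum_id, truth$spectrum_id)
  if (anyNA(ti)) abort("PrSM spectrum id absent from ground truth")
  scored$outcome <- classify_error(
    scored$accession, truth$base_accession[ti],
    truth$additive_accession[ti], scored$role
  )
  per_role <- function(role) {
    n_truth <- if (role == "base") nrow(truth) else sum(!is.na(truth$additive_accession))
    sub <- scored[scored$role == role, , drop = FALSE]
    n_correct <- sum(sub$outcome == "correct")
    n_pse <- sum(sub$outcome == "PSE")
    n_rme <- sum(sub$outcome == "RME")
    n_id <- nrow(sub)
    tibble(
      role = role,
      n_truth = n_truth,
      n_correct = n_correct,
      n_pse = n_pse,
      n_rme = n_rme,
      n_missed = n_truth - n_id,
      correct_rate = if (n_id) n_correct / n_id else NA_real_,
      pse_rate = if (n_id) n_pse / n_id else NA_real_,
      rme_rate = if (n_id) n_rme / n_id else NA_real_,
      id_rate = if (n_truth) n_id / n_truth else NA_real_
    )
  }
  out <- bind_rows(per_role("base"), per_role("additive"))
  class(out) <- c("error_report", class(out))
  out
}

#' Sweep the NNMFM penalties over a grid
#'
#' Re-runs the full pipeline on a ground-truthed dataset for every
#' (delta, gamma) combination and reports per-role PSE/RME/identification
#' rates, mirroring the parameter-selection analysis used to fix the
#' default penalties.
#'
#' @param spectra Benchmark spectra tibble.
#' @param truth Its ground-truth tibble.
#' @param db Protein tibble (targets + decoys) or index.
#' @param delta_grid,gamma_grid Numeric grids; defaults 0..8.
#' @param cfg Base [demux_config()]; `delta`/`gamma` are overridden per
#'   grid point.
#' @param ... Passed to [run_pipeline()].
#' @return A `dg_sweep` tibble with one row per grid point.
#' @export
sweep_delta_gamma <- function(spectra, truth, db, delta_grid = 0:8,
                              gamma_grid = 0:8, cfg = demux_config(), ...) {
  index <- build_search_index(db)
  grid <- tidyr::expand_grid(delta = delta_grid, gamma = gamma_grid)
  rows <- map(seq_len(nrow(grid)), function(k) {
    cfg_k <- cfg
    cfg_k$delta <- grid$delta[k]
    cfg_k$gamma <- grid$gamma[k]
    res <- run_pipeline(spectra, index, cfg_k, ...)
    rep_k <- evaluate_errors(res$prsms, truth)
    base <- rep_k[rep_k$role == "base", ]
    add <- rep_k[rep_k$role == "additive", ]
    tibble(
      delta = grid$delta[k], gamma = grid$gamma[k],
      n_spectra = nrow(spectra),
      base_n_pse = base$n_pse, base_n_rme = base$n_rme,
      base_pse_rate = base$pse_rate, base_rme_rate = base$rme_rate,
      base_id_rate = base$id_rate,
      additive_pse_rate = add$pse_rate, additive_rme_rate = add$rme_rate,
      additive_id_rate = add$id_rate
    )
  })
  out <- bind_rows(rows)
  class(out) <- c("dg_sweep", class(out))
  out
}
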