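# Whole-dataset pipeline: classify -> select primary -> two-round search ->
# per-round spectrum-level FDR -> merge -> proteoform grouping ->
# proteoform-level FDR.

#' Target-decoy FDR filtering
#'
#' Sorts PrSMs (or any table carrying `evalue` and `is_decoy`) by ascending
#' E-value, estimates the FDR of each prefix as `#decoys / max(1, #targets)`,
#' monotonizes by a cumulative minimum from the largest prefix (the standard
#' q-value construction), and returns the target rows of the largest prefix
#' whose monotonized FDR is at or below `cutoff`.
#'
#' @param prsms A tibble with `evalue` and `is_decoy` columns.
#' @param cutoff FDR cutoff in \[0, 1\].
#' @return The accepted target rows (possibly empty).
#' @export
filter_fdr <- function(prsms, cutoff) {
  if (!nrow(prsms)) return(prsms)
  ord <- order(prsms$evalue)
  sorted <- prsms[ord, , drop = FALSE]
  n_decoy <- cumsum(sorted$is_decoy)
  n_target <- cumsum(!sorted$is_decoy)
  fdr <- n_decoy / pmax(1, n_target)
  qval <- rev(cummin(rev(fdr)))
  keep <- which(qval <= cutoff)
  if (!length(keep)) return(sorted[0, , drop = FALSE])
  kept <- sorted[seq_len(max(keep)), , drop = FALSE]
  kept[!kept$is_decoy, , drop = FALSE]
}

# Minimal union-find used for single-linkage proteoform grouping.
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}
uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i)
  rj <- uf_find(parent, j)
  if (ri != rj) parent[rj] <- ri
  parent
}

#' Group PrSMs into proteoform groups
#'
#' Single-linkage clustering of accepted PrSMs under the grouping predicate:
#' two PrSMs belong to the same proteoform when their precursors come from
#' the same proteoform feature, or when they match the same protein and
#' their precursor mass difference is below `group_mass_tol_da`
#' (raw precursor neutral masses; the bound is exclusive). Groups are
#' ranked by their best (lowest) member E-value.
#'
#' @param prsms A PrSM tibble (merged round-1 and round-2 survivors).
#' @param cfg A [demux_config()].
#' @return A proteoform-group tibble: `group_id`, `accession`, `is_decoy`,
#'   `representative_mass`, `best_evalue`, `n_members`, `spectrum_ids`,
#'   `members` (list of member row indices into `prsms`).
#' @export
group_proteoforms <- function(prsms, cfg = demux_config()) {
  n <- nrow(prsms)
  empty <- tibble(
    group_id = integer(), accession = character(), is_decoy = logical(),
    representative_mass = numeric(), best_evalue = numeric(),
    n_members = integer(), spectrum_ids = list(), members = list()
  )
  if (!n) return(empty)
  parent <- uf_new(n)
  # same proteoform feature
  by_feature <- split(seq_len(n), prsms$feature_id)
  for (idx in by_feature) {
    if (length(idx) > 1L) {
      for (j in idx[-1]) parent <- uf_union(parent, idx[1], j)
    }
  }
  # same protein and close precursor mass: adjacent linking after sorting by
  # mass is equivalent to single linkage for an interval predicate
  by_acc <- split(seq_len(n), prsms$accession)
  for (idx in by_acc) {
    if (length(idx) > 1L) {
      idx <- idx[order(prsms$proteoform_mass[idx])]
      masses <- prsms$proteoform_mass[idx]
      for (k in seq_len(length(idx) - 1L)) {
        if (masses[k + 1L] - masses[k] < cfg$group_mass_tol_da) {
          parent <- uf_union(parent, idx[k], idx[k + 1L])
        }
      }
    }
  }
  roots <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  groups <- split(seq_len(n), roots)
  rows <- map(groups, function(idx) {
    best <- idx[which.min(prsms$evalue[idx])]
    tibble(
      accession = prsms$accession[best],
      is_decoy = prsms$is_decoy[best],
      representative_mass = prsms$proteoform_mass[best],
      best_evalue = prsms$evalue[best],
      n_members = length(idx),
      spectrum_ids = list(prsms$spectrum_id[idx]),
      members = list(idx)
    )
  })
  out <- bind_rows(rows)
  out <- out[order(out$best_evalue, out$accession), , drop = FALSE]
  out$group_id <- seq_len(nrow(out))
  out[, names(empty)]
}

#' Run the full demultiplexing pipeline
#'
#' For every spectrum: classify as multiplexed or single, select the primary
#' precursor (when enabled), run the two-round search, pool round-1 and
#' round-2 PrSMs, filter each pool separately at the spectrum level, merge,
#' group into proteoforms and filter groups at the proteoform level.
#' Matching uses fragment masses only, so fragment intensities never change
#' the result.
#'
#' With `select_primary = FALSE` and `second_round = FALSE` this reduces to
#' the naive baseline that pairs only the highest-intensity precursor with
#' the fragment masses (at most one PrSM per spectrum).
#'
#' @param spectra A spectra tibble.
#' @param db Protein tibble (targets + decoys for FDR filtering) or a
#'   [build_search_index()] object.
#' @param cfg A [demux_config()].
#' @param select_primary Use NNMFM-based primary-precursor selection
#'   (otherwise the top-intensity precursor is always primary).
#' @param second_round Run the subtract-and-search second round on
#'   multiplexed spectra.
#' @param filter `"fdr"` for target-decoy FDR cutoffs (`fdr_spectrum`,
#'   `fdr_proteoform`) or `"evalue"` for the fixed `evalue_cutoff`.
#' @return A `demux_result` object: list with `prsms` (accepted target
#'   PrSMs), `groups` (accepted proteoform groups), `decisions` (per-spectrum
#'   log: classification, error-prone flag, primary rank), `config`, and
#'   pre-filter counts.
#' @export
run_pipeline <- function(spectra, db, cfg = demux_config(),
                         select_primary = TRUE, second_round = TRUE,
                         filter = c("fdr", "evalue")) {
  filter <- match.arg(filter)
  index <- build_search_index(db)
  n <- nrow(spectra)
  all_prsms <- vector("list", n)
  decisions <- vector("list", n)
  for (i in seq_len(n)) {
    row <- spectra[i, , drop = FALSE]
    cls <- classify_spectrum(row, cfg$alpha)
    multiplexed <- cls == "multiplexed"
    primary <- 0L
    error_prone <- NA
    round1 <- NULL
    if (multiplexed && select_primary) {
      sel <- select_primary(row, index, cfg)
      primary <- sel$primary_rank
      error_prone <- sel$error_prone
      round1 <- if (primary == 0L) sel$prsm1 else sel$prsm2
    }
    prsms <- two_round_search(
      row, index, cfg,
      primary_rank = primary,
      run_round2 = multiplexed && second_round,
      round1_prsm = round1
    )
    all_prsms[[i]] <- prsms
    decisions[[i]] <- tibble(
      spectrum_id = row$spectrum_id,
      classification = cls,
      primary_rank = primary,
      error_prone = error_prone,
      n_prsms = nrow(prsms)
    )
  }
  pooled <- bind_rows(all_prsms)
  decisions <- bind_rows(decisions)

  accept <- function(tbl, cutoff_fdr) {
    if (!nrow(tbl)) return(tbl)
    if (filter == "fdr") {
      filter_fdr(tbl, cutoff_fdr)
    } else {
      tbl[!tbl$is_decoy & tbl$evalue <= cfg$evalue_cutoff, , drop = FALSE]
    }
  }
  accepted <- bind_rows(
    accept(pooled[!is.na(pooled$round) & pooled$round == 1L, , drop = FALSE],
           cfg$fdr_spectrum),
    accept(pooled[!is.na(pooled$round) & pooled$round == 2L, , drop = FALSE],
           cfg$fdr_spectrum)
  )

  groups_all <- group_proteoforms(
    if (filter == "fdr") {
      bind_rows(
        filter_prefix_with_decoys(pooled, 1L, cfg$fdr_spectrum),
        filter_prefix_with_decoys(pooled, 2L, cfg$fdr_spectrum)
      )
    } else {
      pooled[pooled$evalue <= cfg$evalue_cutoff, , drop = FALSE]
    },
    cfg
  )
  groups_all$evalue <- groups_all$best_evalue
  groups <- accept(groups_all, cfg$fdr_proteoform)
  groups$evalue <- NULL

  structure(
    list(
      prsms = accepted,
      groups = groups,
      decisions = decisions,
      config = cfg,
      n_spectra = n,
      n_multiplexed = sum(decisions$classification == "multiplexed"),
      n_prsms_prefilter = nrow(pooled)
    ),
    class = "demux_result"
  )
}

# Spectrum-level filtering that retains decoy survivors so the proteoform
# level can still estimate an FDR over groups.
filter_prefix_with_decoys <- function(pooled, rnd, cutoff) {
  tbl <- pooled[!is.na(pooled$round) & pooled$round == rnd, , drop = FALSE]
  if (!nrow(tbl)) return(tbl)
  ord <- order(tbl$evalue)
  sorted <- tbl[ord, , drop = FALSE]
  fdr <- cumsum(sorted$is_decoy) / pmax(1, cumsum(!sorted$is_decoy))
  qval <- rev(cummin(rev(fdr)))
  keep <- which(qval <= cutoff)
  if (!length(keep)) return(sorted[0, , drop = FALSE])
  sorted[seq_len(max(keep)), , drop = FALSE]
}

#' @export
print.demux_result <- function(x, ...) {
  cat("<demux_result>\n")
  cat(sprintf("  spectra:          %d (%d multiplexed)\n", x$n_spectra, x$n_multiplexed))
  cat(sprintf("  PrSMs pre-filter: %d\n", x$n_prsms_prefilter))
  cat(sprintf("  accepted PrSMs:   %d (round 1: %d, round 2: %d)\n",
              nrow(x$prsms), sum(x$prsms$round == 1L), sum(x$prsms$round == 2L)))
  cat(sprintf("  proteoform groups: %d\n", nrow(x$groups)))
  invisible(x)
}
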