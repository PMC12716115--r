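# Construction of pseudo-multiplexed benchmark spectra (SPMS and RPMS) from
# identified non-multiplexed spectra, with ground truth for error scoring.

#' Is a spectrum non-multiplexed?
#'
#' A spectrum qualifies as non-multiplexed for benchmark construction when
#' its highest-intensity precursor carries at least `threshold` of the total
#' precursor intensity.
#'
#' @param spectrum One row of a spectra tibble.
#' @param threshold Fraction in \[0, 1\]; default 0.85.
#' @return `TRUE`/`FALSE` (zero total intensity gives `FALSE`).
#' @export
is_nonmultiplexed <- function(spectrum, threshold = 0.85) {
  ints <- spectrum$precursors[[1]]$intensity
  total <- sum(ints)
  if (total <= 0) return(FALSE)
  max(ints) / total >= threshold
}

#' Identify non-multiplexed spectra with the top precursor
#'
#' Convenience wrapper used before benchmark construction: keeps spectra
#' passing [is_nonmultiplexed()], searches each top-intensity PFPS, and
#' keeps identifications at the configured E-value cutoff.
#'
#' @param spectra A spectra tibble.
#' @param db Protein tibble or [build_search_index()] object.
#' @param cfg A [demux_config()].
#' @param threshold Non-multiplexed intensity threshold.
#' @return A list: `spectra` (the identified non-multiplexed spectra) and
#'   `prsms` (one PrSM row per kept spectrum).
#' @export
identify_nonmultiplexed <- function(spectra, db, cfg = demux_config(),
                                    threshold = 0.85) {
  index <- build_search_index(db)
  keep_nm <- map_lgl(seq_len(nrow(spectra)),
                     ~ is_nonmultiplexed(spectra[.x, ], threshold))
  spectra <- spectra[keep_nm, , drop = FALSE]
  prsms <- map(seq_len(nrow(spectra)), function(i) {
    row <- spectra[i, , drop = FALSE]
    prsm <- search_pfps(row$precursors[[1]][1, ], row$frag_masses[[1]],
                        index, cfg)
    if (is.null(prsm) || prsm$is_decoy || prsm$evalue > cfg$evalue_cutoff) {
      return(NULL)
    }
    prsm$spectrum_id <- row$spectrum_id
    prsm$round <- 1L
    prsm
  })
  found <- !map_lgl(prsms, is.null)
  list(spectra = spectra[found, , drop = FALSE], prsms = bind_rows(prsms[found]))
}

# One row of pairing metadata per identified spectrum.
spectrum_pair_info <- function(spectra, prsms) {
  stopifnot(all(prsms$spectrum_id %in% spectra$spectrum_id))
  idx <- match(prsms$spectrum_id, spectra$spectrum_id)
  tibble(
    spectrum_id = prsms$spectrum_id,
    charge = map_int(spectra$precursors[idx], ~ .x$charge[1]),
    avg_mz = map_dbl(spectra$precursors[idx], ~ .x$avg_mz[1]),
    n_frags = map_int(spectra$frag_masses[idx], length),
    accession = prsms$accession,
    matched_count = prsms$matched_count,
    shift_count = prsms$shift_count,
    shift_da = prsms$shift_da,
    proteoform_mass = prsms$proteoform_mass
  )
}

#' Pair spectra for the SPMS benchmark
#'
#' Returns every unordered pair of identified non-multiplexed spectra whose
#' precursors have different charge states, whose average precursor m/z
#' differ by at most 1.5, and whose identifications are from two different
#' proteins. The member with more matched fragment masses is the base
#' spectrum (ties: lexicographically smaller spectrum id).
#'
#' @param spectra Identified non-multiplexed spectra tibble.
#' @param prsms Their PrSM tibble (one row per spectrum).
#' @param max_dmz Maximum average-m/z difference; default 1.5.
#' @return A pair tibble: `base_id`, `additive_id`, `pair_kind`,
#'   `shift_class`.
#' @export
pair_spms <- function(spectra, prsms, max_dmz = 1.5) {
  info <- spectrum_pair_info(spectra, prsms)
  n <- nrow(info)
  pairs <- list()
  if (n >= 2L) {
    combos <- utils::combn(n, 2L)
    for (k in seq_len(ncol(combos))) {
      i <- combos[1, k]
      j <- combos[2, k]
      if (info$charge[i] == info$charge[j]) next
      if (abs(info$avg_mz[i] - info$avg_mz[j]) > max_dmz) next
      if (info$accession[i] == info$accession[j]) next
      base <- if (info$matched_count[i] > info$matched_count[j]) i
      else if (info$matched_count[j] > info$matched_count[i]) j
      else if (info$spectrum_id[i] <= info$spectrum_id[j]) i else j
      add <- if (base == i) j else i
      pairs[[length(pairs) + 1L]] <- tibble(
        base_id = info$spectrum_id[base],
        additive_id = info$spectrum_id[add],
        pair_kind = "SPMS",
        shift_class = sprintf("Base%d-Add%d", info$shift_count[base],
                              info$shift_count[add])
      )
    }
  }
  bind_rows(pairs) %||% tibble(base_id = character(), additive_id = character(),
                               pair_kind = character(), shift_class = character())
}

#' Validity of an RPMS additive spectrum for a base spectrum
#'
#' The candidate is a valid additive spectrum when the precursor charges
#' differ, the average precursor m/z differ by at most 20, the
#' identifications are from different proteins, and — after removing the
#' candidate fragment masses randomly matched to the b/y ions of the base
#' proteoform — the remaining additive fragment count is at least twice the
#' base spectrum's matched fragment count.
#'
#' @param base,cand Lists with elements `spectrum` (one spectra-tibble row)
#'   and `prsm` (its one-row PrSM tibble).
#' @param db Protein tibble or [build_search_index()] object (for the base
#'   proteoform's theoretical ions).
#' @param cfg A [demux_config()].
#' @return `TRUE`/`FALSE`.
#' @export
valid_rpms_additive <- function(base, cand, db, cfg = demux_config()) {
  bsp <- base$spectrum
  csp <- cand$spectrum
  if (bsp$precursors[[1]]$charge[1] == csp$precursors[[1]]$charge[1]) return(FALSE)
  if (abs(bsp$precursors[[1]]$avg_mz[1] - csp$precursors[[1]]$avg_mz[1]) > 20) return(FALSE)
  if (base$prsm$accession == cand$prsm$accession) return(FALSE)
  index <- build_search_index(db)
  k <- match(base$prsm$accession, index$accession)
  form <- list(prefix_masses = index$prefix[[k]], proteoform_mass = index$mass[k])
  cand_frags <- csp$frag_masses[[1]]
  n_random <- if (base$prsm$shift_count == 0L) {
    length(match_zero_shift(cand_frags, form, base$prsm$proteoform_mass,
                            cfg$frag_tol_ppm))
  } else {
    match_one_shift(cand_frags, form, base$prsm$shift_da, cfg$frag_tol_ppm)$count
  }
  (length(cand_frags) - n_random) >= 2L * base$prsm$matched_count
}

#' Pair spectra for the RPMS benchmark
#'
#' For every identified non-multiplexed spectrum taken as a base, scans the
#' others in spectrum-id order and keeps the first valid zero-shift additive
#' spectrum and the first valid one-shift additive spectrum (see
#' [valid_rpms_additive()]). Only bases with both are retained, yielding two
#' pairs per base.
#'
#' @inheritParams pair_spms
#' @param db Protein tibble or [build_search_index()] object.
#' @param cfg A [demux_config()].
#' @return A pair tibble (`pair_kind` = `"RPMS"`).
#' @export
pair_rpms <- function(spectra, prsms, db, cfg = demux_config()) {
  index <- build_search_index(db)
  info <- spectrum_pair_info(spectra, prsms)
  ord <- order(info$spectrum_id)
  pairs <- list()
  for (i in seq_len(nrow(info))) {
    base <- list(spectrum = spectra[i, , drop = FALSE], prsm = prsms[i, , drop = FALSE])
    add0 <- NULL
    add1 <- NULL
    for (j in ord) {
      if (j == i) next
      if (!is.null(add0) && !is.null(add1)) break
      slot <- if (prsms$shift_count[j] == 0L) "add0" else "add1"
      if (slot == "add0" && !is.null(add0)) next
      if (slot == "add1" && !is.null(add1)) next
      cand <- list(spectrum = spectra[j, , drop = FALSE], prsm = prsms[j, , drop = FALSE])
      if (valid_rpms_additive(base, cand, index, cfg)) {
        if (slot == "add0") add0 <- j else add1 <- j
      }
    }
    if (!is.null(add0) && !is.null(add1)) {
      for (j in c(add0, add1)) {
        pairs[[length(pairs) + 1L]] <- tibble(
          base_id = info$spectrum_id[i],
          additive_id = info$spectrum_id[j],
          pair_kind = "RPMS",
          shift_class = sprintf("Base%d-Add%d", info$shift_count[i],
                                info$shift_count[j])
        )
      }
    }
  }
  bind_rows(pairs) %||% tibble(base_id = character(), additive_id = character(),
                               pair_kind = character(), shift_class = character())
}

#' Merge a spectrum pair into a pseudo-multiplexed spectrum
#'
#' Combines all base fragment masses with additive fragment masses — all of
#' them for SPMS (`ab_ratio = NULL`), or a uniform random subset of size
#' `round(ab_ratio * n_base)` (clamped to availability, with a message) for
#' RPMS. Both precursors are attached with the base precursor's intensity
#' strictly higher; exact duplicate masses collapse to one entry keeping the
#' higher intensity.
#'
#' @param pair One row of a pair tibble.
#' @param spectra,prsms The source spectra and PrSMs.
#' @param ab_ratio `NULL`, or the additive-base fragment-count ratio in
#'   \[0, 2\].
#' @param spectrum_id Id for the merged spectrum.
#' @return A list with `spectrum` and `truth` one-row tibbles.
#' @export
merge_pair <- function(pair, spectra, prsms, ab_ratio = NULL,
                       spectrum_id = NULL) {
  if (!is.null(ab_ratio) && (ab_ratio < 0 || ab_ratio > 2)) {
    abort("ab_ratio must lie in [0, 2]")
  }
  bi <- match(pair$base_id, spectra$spectrum_id)
  ai <- match(pair$additive_id, spectra$spectrum_id)
  bp <- prsms[match(pair$base_id, prsms$spectrum_id), , drop = FALSE]
  ap <- prsms[match(pair$additive_id, prsms$spectrum_id), , drop = FALSE]
  if (is.null(spectrum_id)) {
    spectrum_id <- paste0("PMX_", pair$base_id, "_", pair$additive_id)
  }
  base_m <- spectra$frag_masses[[bi]]
  base_i <- spectra$frag_intensities[[bi]]
  add_m <- spectra$frag_masses[[ai]]
  add_i <- spectra$frag_intensities[[ai]]
  if (!is.null(ab_ratio)) {
    k <- round(ab_ratio * length(base_m))
    if (k > length(add_m)) {
      inform(paste0(spectrum_id, ": additive subset clamped from ", k,
                    " to ", length(add_m)))
      k <- length(add_m)
    }
    sel <- sort(sample.int(length(add_m), k))
    add_m <- add_m[sel]
    add_i <- add_i[sel]
  }
  masses <- c(base_m, add_m)
  ints <- c(base_i, add_i)
  origin <- c(rep("base", length(base_m)), rep("additive", length(add_m)))
  ord <- order(masses, origin != "base")  # base provenance wins a tie
  masses <- masses[ord]
  ints <- ints[ord]
  origin <- origin[ord]
  dup <- duplicated(masses)
  if (any(dup)) {
    for (d in which(dup)) ints[d - 1L] <- max(ints[d - 1L], ints[d])
    masses <- masses[!dup]
    ints <- ints[!dup]
    origin <- origin[!dup]
  }
  prb <- spectra$precursors[[bi]][1, ]
  pra <- spectra$precursors[[ai]][1, ]
  prec <- precursor_table(
    feature_id = c(prb$feature_id, pra$feature_id),
    neutral_mass = c(prb$neutral_mass, pra$neutral_mass),
    charge = c(prb$charge, pra$charge),
    avg_mz = c(prb$avg_mz, pra$avg_mz),
    intensity = c(1000, 500)
  )
  spectrum <- deconv_spectra(
    spectrum_id = spectrum_id,
    iso_lo = min(prb$avg_mz, pra$avg_mz) - 1.5,
    iso_hi = max(prb$avg_mz, pra$avg_mz) + 1.5,
    precursors = list(prec),
    frag_masses = list(masses),
    frag_intensities = list(ints)
  )
  truth <- tibble(
    spectrum_id = spectrum_id,
    base_accession = bp$accession,
    additive_accession = ap$accession,
    base_shift_da = bp$shift_da,
    additive_shift_da = ap$shift_da,
    base_frag_count = sum(origin == "base"),
    additive_frag_count = sum(origin == "additive"),
    base_frag_ids = list(which(origin == "base")),
    additive_frag_ids = list(which(origin == "additive")),
    base_feature_id = prb$feature_id,
    additive_feature_id = pra$feature_id,
    scenario = pair$pair_kind
  )
  list(spectrum = spectrum, truth = truth)
}

#' Build the SPMS dataset
#'
#' Merges every pair with all additive fragments.
#'
#' @param pairs A pair tibble from [pair_spms()].
#' @param spectra,prsms The source spectra and PrSMs.
#' @return A list with `spectra` and `truth` tibbles.
#' @export
make_spms_dataset <- function(pairs, spectra, prsms) {
  out <- map(seq_len(nrow(pairs)), function(k) {
    merge_pair(pairs[k, ], spectra, prsms,
               spectrum_id = sprintf("SPMS_%04d", k))
  })
  list(spectra = bind_rows(map(out, "spectrum")),
       truth = bind_rows(map(out, "truth")))
}

#' Build the RPMS dataset series
#'
#' One dataset per additive-base ratio; each dataset has exactly one merged
#' spectrum per pair, with `round(ratio * n_base)` additive fragments.
#' Deterministic in `seed`.
#'
#' @param pairs A pair tibble from [pair_rpms()].
#' @param spectra,prsms The source spectra and PrSMs.
#' @param ratios Additive-base ratios; default 0, 0.2, ..., 2.
#' @param seed Integer seed for additive-fragment subsampling.
#' @return A named list (one element per ratio) of `spectra`/`truth` lists.
#' @export
make_rpms_datasets <- function(pairs, spectra, prsms,
                               ratios = seq(0, 2, by = 0.2), seed = 1L) {
  withr::with_seed(as.integer(seed), {
    out <- map(ratios, function(r) {
      merged <- map(seq_len(nrow(pairs)), function(k) {
        merge_pair(pairs[k, ], spectra, prsms, ab_ratio = r,
                   spectrum_id = sprintf("RPMS_r%03d_%04d", round(100 * r), k))
      })
      list(spectra = bind_rows(map(merged, "spectrum")),
           truth = bind_rows(map(merged, "truth")))
    })
    names(out) <- format(ratios)
    out
  })
}
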