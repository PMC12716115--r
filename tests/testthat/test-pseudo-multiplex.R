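# Shared source material: identified single-proteoform spectra with a broad
# per-spectrum coverage spread, as benchmark construction requires.
source_singles <- local({
  p <- sim_params(seed = 42, coverage_range = c(0.25, 0.9))
  bm <- gen_benchmark(p, n_spectra = 80, scenario_mix = c(single = 1))
  db <- build_decoy_db(bm$proteome, seed = 42)
  idn <- identify_nonmultiplexed(bm$spectra, db)
  list(spectra = idn$spectra, prsms = idn$prsms, db = db, proteome = bm$proteome)
})

test_that("the non-multiplexed filter uses the 85% intensity rule", {
  two <- function(i1, i2) {
    fixture_spectrum("S", precursor_table(1:2, c(7000, 8000), c(8L, 9L),
                                          c(876, 890), c(i1, i2)),
                     frags = c(500, 600))
  }
  expect_true(is_nonmultiplexed(two(900, 100)))
  expect_false(is_nonmultiplexed(two(800, 200)))
  one <- fixture_spectrum("S", fixture_precursor(7000, 1000), c(500, 600))
  expect_true(is_nonmultiplexed(one))
  expect_false(is_nonmultiplexed(two(0, 0)))
})

test_that("SPMS pairing enforces charge, m/z-distance and protein criteria", {
  mk <- function(id, charge, mz, acc, matched) {
    sp <- fixture_spectrum(id, precursor_table(1L, 7000, charge, mz, 1000),
                           c(500, 600, 700))
    pr <- tibble::tibble(
      spectrum_id = id, precursor_rank = 0L, feature_id = 1L, accession = acc,
      is_decoy = FALSE, proteoform_mass = 7000, shift_count = 0L,
      shift_da = 0, matched_count = matched, nnmfm = matched, evalue = 1e-6,
      matched_masses = list(c(500, 600)), round = 1L
    )
    list(sp = sp, pr = pr)
  }
  s1 <- mk("s1", 8L, 900.0, "P1", 12L)
  s2 <- mk("s2", 9L, 900.8, "P2", 9L)
  s3 <- mk("s3", 8L, 900.5, "P3", 7L)   # same charge as s1
  s4 <- mk("s4", 7L, 901.0, "P1", 7L)   # same protein as s1
  s5 <- mk("s5", 10L, 950.0, "P4", 7L)  # too far in m/z
  spectra <- dplyr::bind_rows(s1$sp, s2$sp, s3$sp, s4$sp, s5$sp)
  prsms <- dplyr::bind_rows(s1$pr, s2$pr, s3$pr, s4$pr, s5$pr)
  pairs <- pair_spms(spectra, prsms)
  expect_true(all(pairs$pair_kind == "SPMS"))
  # s1-s2 valid with s1 (more matches) as base
  expect_true(any(pairs$base_id == "s1" & pairs$additive_id == "s2"))
  # rejected pairs are absent in either order
  key <- paste(pairs$base_id, pairs$additive_id)
  expect_false(any(key %in% c("s1 s3", "s3 s1")))  # same charge
  expect_false(any(key %in% c("s1 s4", "s4 s1")))  # same protein
  expect_false(any(grepl("s5", key)))              # m/z distance
  # a matched-count tie makes the lexicographically smaller id the base
  s6 <- mk("s6", 11L, 900.2, "P5", 9L)
  pairs2 <- pair_spms(dplyr::bind_rows(s2$sp, s6$sp),
                      dplyr::bind_rows(s2$pr, s6$pr))
  expect_equal(pairs2$base_id, "s2")
})

test_that("generated SPMS pairs always satisfy the three pairing criteria", {
  src <- source_singles
  pairs <- pair_spms(src$spectra, src$prsms)
  expect_gt(nrow(pairs), 0L)
  info_of <- function(ids) {
    idx <- match(ids, src$spectra$spectrum_id)
    list(
      charge = vapply(src$spectra$precursors[idx], function(x) x$charge[1], integer(1)),
      mz = vapply(src$spectra$precursors[idx], function(x) x$avg_mz[1], numeric(1)),
      acc = src$prsms$accession[match(ids, src$prsms$spectrum_id)],
      matched = src$prsms$matched_count[match(ids, src$prsms$spectrum_id)]
    )
  }
  b <- info_of(pairs$base_id)
  a <- info_of(pairs$additive_id)
  expect_true(all(b$charge != a$charge))
  expect_true(all(abs(b$mz - a$mz) <= 1.5))
  expect_true(all(b$acc != a$acc))
  expect_true(all(b$matched >= a$matched))
})

test_that("pair merging controls the additive fragment count", {
  src <- source_singles
  pairs <- pair_spms(src$spectra, src$prsms)
  pair <- pairs[1, ]
  n_base <- length(src$spectra$frag_masses[[
    match(pair$base_id, src$spectra$spectrum_id)]])
  n_add <- length(src$spectra$frag_masses[[
    match(pair$additive_id, src$spectra$spectrum_id)]])

  # SPMS merge: full union minus exact duplicates, both precursors attached
  m <- merge_pair(pair, src$spectra, src$prsms)
  expect_equal(length(m$spectrum$frag_masses[[1]]),
               m$truth$base_frag_count + m$truth$additive_frag_count)
  expect_lte(length(m$spectrum$frag_masses[[1]]), n_base + n_add)
  expect_equal(nrow(m$spectrum$precursors[[1]]), 2L)
  # the base precursor carries the higher intensity
  expect_gt(m$spectrum$precursors[[1]]$intensity[1],
            m$spectrum$precursors[[1]]$intensity[2])

  # RPMS merges: round(ratio * n_base) additive fragments
  withr::with_seed(1, {
    m2 <- merge_pair(pair, src$spectra, src$prsms, ab_ratio = 0.2)
    expect_equal(m2$truth$additive_frag_count, round(0.2 * n_base))
    m0 <- merge_pair(pair, src$spectra, src$prsms, ab_ratio = 0)
    expect_equal(m0$truth$additive_frag_count, 0L)
    expect_equal(m0$spectrum$frag_masses[[1]],
                 src$spectra$frag_masses[[match(pair$base_id, src$spectra$spectrum_id)]])
    expect_equal(nrow(m0$spectrum$precursors[[1]]), 2L)
  })
  expect_error(merge_pair(pair, src$spectra, src$prsms, ab_ratio = 2.5),
               "ab_ratio")
})

test_that("RPMS additive validity applies the charge, m/z, protein and 2x rules", {
  db <- fixture_db()
  cfg <- demux_config()
  seq_a <- db$sequence[1]
  form_a <- theoretical_prefix_masses(seq_a)
  base_prsm <- tibble::tibble(
    spectrum_id = "base", precursor_rank = 0L, feature_id = 1L,
    accession = "P_A", is_decoy = FALSE,
    proteoform_mass = form_a$proteoform_mass, shift_count = 0L, shift_da = 0,
    matched_count = 10L, nnmfm = 10, evalue = 1e-8,
    matched_masses = list(numeric(0)), round = 1L
  )
  base <- list(
    spectrum = fixture_spectrum("base", fixture_precursor(form_a$proteoform_mass,
                                                          1000, 1L, 8L),
                                sort(fixture_ions(seq_a))),
    prsm = base_prsm
  )
  cand_of <- function(frags, charge = 9L, mz_offset = 0) {
    prec <- precursor_table(2L, 8000, charge,
                            base$spectrum$precursors[[1]]$avg_mz[1] + mz_offset,
                            900)
    prsm <- base_prsm
    prsm$spectrum_id <- "cand"
    prsm$accession <- "P_B"
    list(spectrum = fixture_spectrum("cand", prec, frags), prsm = prsm)
  }
  far <- seq(2000, 2300, length.out = 22)  # matches nothing of P_A
  ions3 <- fixture_ions(seq_a)[1:3]
  # 25 candidate fragments, 3 randomly matching the base proteoform:
  # 22 remaining >= 2 * 10 -> valid
  expect_true(valid_rpms_additive(base, cand_of(c(far, ions3)), db, cfg))
  # 6 matching -> 19 remaining < 20 -> invalid
  ions6 <- fixture_ions(seq_a)[1:6]
  expect_false(valid_rpms_additive(base, cand_of(c(far[1:19], ions6)), db, cfg))
  # same charge or distant m/z fail regardless of counts
  expect_false(valid_rpms_additive(base, cand_of(c(far, ions3), charge = 8L), db, cfg))
  expect_false(valid_rpms_additive(base, cand_of(c(far, ions3), mz_offset = 21), db, cfg))
})

test_that("RPMS dataset series has exact per-ratio additive counts and is reproducible", {
  src <- source_singles
  pairs <- pair_rpms(src$spectra, src$prsms, src$db)
  expect_gt(nrow(pairs), 4L)
  pairs <- pairs[seq_len(min(10, nrow(pairs))), ]
  ratios <- seq(0, 2, by = 0.2)
  ds1 <- make_rpms_datasets(pairs, src$spectra, src$prsms, ratios, seed = 9)
  expect_length(ds1, 11L)
  n_base <- vapply(match(pairs$base_id, src$spectra$spectrum_id),
                   function(i) length(src$spectra$frag_masses[[i]]), integer(1))
  n_avail <- vapply(match(pairs$additive_id, src$spectra$spectrum_id),
                    function(i) length(src$spectra$frag_masses[[i]]), integer(1))
  for (k in seq_along(ratios)) {
    d <- ds1[[k]]
    expect_equal(nrow(d$spectra), nrow(pairs))
    expect_equal(d$truth$additive_frag_count,
                 pmin(round(ratios[k] * n_base), n_avail))
    # base fragments are identical across the ratio series
    expect_equal(d$truth$base_frag_count, n_base)
  }
  ds2 <- make_rpms_datasets(pairs, src$spectra, src$prsms, ratios, seed = 9)
  expect_identical(ds1, ds2)
})

test_that("error classification partitions identifications by role", {
  expect_equal(classify_error("P1", "P1", "P2", "base"), "correct")
  expect_equal(classify_error("P2", "P1", "P2", "base"), "PSE")
  expect_equal(classify_error("P9", "P1", "P2", "base"), "RME")
  expect_equal(classify_error("P2", "P1", "P2", "additive"), "correct")
  expect_equal(classify_error("P1", "P1", "P2", "additive"), "PSE")
  # a single-proteoform spectrum has no additive protein to confuse with
  expect_equal(classify_error("P9", "P1", NA_character_, "base"), "RME")

  # counts conserve: correct + PSE + RME + missed = truth entries per role
  p <- sim_params(seed = 57)
  bm <- gen_benchmark(p, n_spectra = 25, scenario_mix = c(normal = 1))
  db <- build_decoy_db(bm$proteome, seed = 57)
  res <- run_pipeline(bm$spectra, db)
  rep <- evaluate_errors(res$prsms, bm$truth)
  expect_equal(rep$n_correct + rep$n_pse + rep$n_rme + rep$n_missed,
               rep$n_truth)
  expect_true(all(rep$n_truth == 25L))
})

test_that("the penalty sweep returns one row per grid point with sane rates", {
  p <- sim_params(seed = 61)
  bm <- gen_benchmark(p, n_spectra = 12, scenario_mix = c(`swapped-intensity` = 1))
  db <- build_decoy_db(bm$proteome, seed = 61)
  sw <- sweep_delta_gamma(bm$spectra, bm$truth, db,
                          delta_grid = c(4, 5), gamma_grid = c(3, 4))
  expect_equal(nrow(sw), 4L)
  expect_equal(nrow(dplyr::distinct(sw[, c("delta", "gamma")])), 4L)
  rates <- unlist(sw[, c("base_pse_rate", "base_rme_rate", "base_id_rate",
                         "additive_pse_rate", "additive_rme_rate",
                         "additive_id_rate")])
  expect_true(all(rates >= 0 & rates <= 1, na.rm = TRUE))
})
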