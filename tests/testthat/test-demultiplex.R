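test_that("precursor intensity sums feature peaks inside the isolation window", {
  peaks <- data.frame(mz = c(900.1, 900.9, 1101.2), intensity = c(500, 300, 200))
  expect_equal(precursor_intensity(peaks, 899.5, 902.5), 800)
  expect_equal(precursor_intensity(peaks, 100, 200), 0)
  expect_equal(precursor_intensity(peaks, 0, 2000), 1000)
})

test_that("multiplexed classification uses an inclusive intensity-ratio boundary", {
  two <- function(i1, i2) {
    fixture_spectrum("S", precursor_table(1:2, c(7000, 8000), c(8L, 9L),
                                          c(876, 890), c(i1, i2)),
                     frags = c(500, 600))
  }
  expect_equal(classify_spectrum(two(1000, 250), 0.2), "multiplexed")
  expect_equal(classify_spectrum(two(1000, 200), 0.2), "multiplexed")  # exactly alpha
  expect_equal(classify_spectrum(two(1000, 199), 0.2), "single")
  one <- fixture_spectrum("S", fixture_precursor(7000, 1000), c(500, 600))
  expect_equal(classify_spectrum(one, 0.2), "single")
  expect_message(cls <- classify_spectrum(two(0, 0), 0.2), "zero")
  expect_equal(cls, "single")
})

test_that("shared-match ratio and error-prone detection follow the inclusive rules", {
  expect_equal(shared_match_ratio(1:12, c(1:7, 20:22)), 0.7)
  expect_equal(shared_match_ratio(1:5, 1:5), 1.0)
  expect_equal(shared_match_ratio(1:5, 6:10), 0.0)
  expect_message(r0 <- shared_match_ratio(numeric(0), 1:3), "empty")
  expect_equal(r0, 0)

  prsm <- function(acc, matched) {
    tibble::tibble(accession = acc, matched_masses = list(matched))
  }
  # same protein: flagged regardless of overlap
  expect_true(detect_error_prone(prsm("P1", 1:10), prsm("P1", 50:60), 0.7))
  # ratio exactly at beta is error-prone (inclusive)
  expect_true(detect_error_prone(prsm("P1", 1:10), prsm("P2", c(1:7, 20:22)), 0.7))
  # just below beta is not
  expect_false(detect_error_prone(prsm("P1", 1:100), prsm("P2", c(1:69, 200:230)), 0.7))
})

test_that("NNMFM applies the shift and rank penalties", {
  expect_equal(nnmfm(20, 1, 1, 5, 4), 11)
  expect_equal(nnmfm(20, 0, 0, 5, 4), 20)
  expect_equal(nnmfm(3, 1, 1, 5, 4), -6)  # negative scores allowed
})

test_that("primary selection follows the one-hit, error-prone-NNMFM and tie rules", {
  db <- fixture_db()
  cfg <- demux_config()
  seq_a <- db$sequence[1]
  seq_b <- db$sequence[2]
  form_a <- theoretical_prefix_masses(seq_a)
  form_b <- theoretical_prefix_masses(seq_b)

  # (a) only the top-intensity PFPS identifies: its precursor is primary
  frags_a <- sort(fixture_ions(seq_a))
  sp <- fixture_spectrum("S", dplyr::bind_rows(
    fixture_precursor(form_a$proteoform_mass, 1000, 1L, 8L),
    fixture_precursor(form_a$proteoform_mass + 5000, 400, 2L, 9L)  # matches nothing
  ), frags_a)
  sel <- select_primary(sp, db, cfg)
  expect_equal(sel$primary_rank, 0L)
  expect_null(sel$prsm2)
  expect_false(sel$error_prone)

  # (c) error-prone (same protein): the higher-NNMFM precursor wins.
  # All of B's ions; F1 carries B's mass + 100 (one-shift), F2 carries B's
  # exact mass (zero-shift with more matches) -> F2 primary.
  frags_b <- sort(fixture_ions(seq_b))
  sp2 <- fixture_spectrum("S2", dplyr::bind_rows(
    fixture_precursor(form_b$proteoform_mass + 100, 1000, 1L, 8L),
    fixture_precursor(form_b$proteoform_mass, 400, 2L, 9L)
  ), frags_b)
  sel2 <- select_primary(sp2, db, cfg)
  expect_true(sel2$error_prone)
  expect_equal(sel2$prsm1$accession, "P_B")
  expect_equal(sel2$prsm2$accession, "P_B")
  expect_gt(sel2$prsm2$nnmfm, sel2$prsm1$nnmfm)
  expect_equal(sel2$primary_rank, 1L)

  # NNMFM tie -> top-intensity precursor stays primary. Fragments are B's
  # prefix masses plus one shifted suffix of the F1 model, making
  # x1 = x2 + 1 and the NNMFMs equal (delta - gamma = 1).
  np <- length(form_b$prefix_masses)
  frags_tie <- sort(c(form_b$prefix_masses,
                      form_b$proteoform_mass + 100 - form_b$prefix_masses[1]))
  sp3 <- fixture_spectrum("S3", dplyr::bind_rows(
    fixture_precursor(form_b$proteoform_mass + 100, 1000, 1L, 8L),
    fixture_precursor(form_b$proteoform_mass, 400, 2L, 9L)
  ), frags_tie)
  sel3 <- select_primary(sp3, db, cfg)
  expect_true(sel3$error_prone)
  expect_equal(sel3$prsm1$nnmfm, sel3$prsm2$nnmfm)
  expect_equal(sel3$primary_rank, 0L)
})

test_that("two-round search subtracts matched masses and resolves same-protein hits", {
  db <- fixture_db()
  cfg <- demux_config()
  seq_a <- db$sequence[1]
  seq_b <- db$sequence[2]
  form_a <- theoretical_prefix_masses(seq_a)
  form_b <- theoretical_prefix_masses(seq_b)
  ions_a <- withr::with_seed(2, sample(fixture_ions(seq_a), 15))
  ions_b <- withr::with_seed(3, sample(fixture_ions(seq_b), 10))
  sp <- fixture_spectrum("S", dplyr::bind_rows(
    fixture_precursor(form_a$proteoform_mass, 1000, 1L, 8L),
    fixture_precursor(form_b$proteoform_mass, 400, 2L, 9L)
  ), c(ions_a, ions_b))

  out <- two_round_search(sp, db, cfg, primary_rank = 0L)
  expect_equal(nrow(out), 2L)
  expect_equal(out$accession, c("P_A", "P_B"))
  expect_equal(out$round, c(1L, 2L))
  expect_equal(out$matched_count, c(15L, 10L))
  # subtraction soundness: round-2 matches are disjoint from round-1 matches
  expect_length(intersect(out$matched_masses[[1]], out$matched_masses[[2]]), 0L)

  # when round 1 finds nothing, round 2 still searches the full fragment list
  sp_none <- fixture_spectrum("S", dplyr::bind_rows(
    fixture_precursor(form_a$proteoform_mass + 5000, 1000, 1L, 8L),
    fixture_precursor(form_b$proteoform_mass, 400, 2L, 9L)
  ), c(ions_a, ions_b))
  out2 <- two_round_search(sp_none, db, cfg, primary_rank = 0L)
  expect_equal(nrow(out2), 1L)
  expect_equal(out2$round, 2L)
  expect_equal(out2$matched_count, 10L)

  # both rounds hitting the same protein keep only the lower E-value
  frags_dup <- sort(fixture_ions(seq_a))
  sp_dup <- fixture_spectrum("S", dplyr::bind_rows(
    fixture_precursor(form_a$proteoform_mass + 100, 1000, 1L, 8L),
    fixture_precursor(form_a$proteoform_mass, 400, 2L, 9L)
  ), frags_dup)
  out3 <- two_round_search(sp_dup, db, cfg, primary_rank = 0L)
  expect_equal(nrow(out3), 1L)
  expect_equal(out3$accession, "P_A")
})

test_that("FDR filtering keeps the largest prefix under the monotonized estimate", {
  tbl <- function(ev, decoy) tibble::tibble(evalue = ev, is_decoy = decoy)
  # decoy-free top prefix: all targets kept
  out <- filter_fdr(tbl(c(1e-9, 1e-8, 1e-7, 1e-2), c(F, F, F, T)), 0.01)
  expect_equal(nrow(out), 3L)
  expect_false(any(out$is_decoy))
  # alternating decoys and targets from the top: nothing survives at 1%
  # (every prefix FDR is >= 0.5)
  out2 <- filter_fdr(tbl(10^-(8:1), rep(c(TRUE, FALSE), 4)), 0.01)
  expect_equal(nrow(out2), 0L)
  # vacuous cutoff keeps every target
  out3 <- filter_fdr(tbl(10^-(8:1), rep(c(TRUE, FALSE), 4)), 1.0)
  expect_equal(nrow(out3), 4L)
  expect_equal(nrow(filter_fdr(tbl(numeric(0), logical(0)), 0.01)), 0L)
})

test_that("proteoform grouping applies the feature and mass-difference predicates", {
  prsm_row <- function(id, acc, mass, feat, ev = 1e-6) {
    tibble::tibble(
      spectrum_id = id, precursor_rank = 0L, feature_id = feat,
      accession = acc, is_decoy = FALSE, proteoform_mass = mass,
      shift_count = 0L, shift_da = 0, matched_count = 10L, nnmfm = 10,
      evalue = ev, matched_masses = list(numeric(0)), round = 1L
    )
  }
  cfg <- demux_config()
  # same protein, 1.1 Da apart -> one group
  g1 <- group_proteoforms(dplyr::bind_rows(
    prsm_row("S1", "P1", 10000.0, 1L), prsm_row("S2", "P1", 10001.1, 2L)
  ), cfg)
  expect_equal(nrow(g1), 1L)
  expect_equal(g1$n_members, 2L)
  # same protein, 1.3 Da apart, different features -> two groups
  g2 <- group_proteoforms(dplyr::bind_rows(
    prsm_row("S1", "P1", 10000.0, 1L), prsm_row("S2", "P1", 10001.3, 2L)
  ), cfg)
  expect_equal(nrow(g2), 2L)
  # different proteins but the same feature -> one group
  g3 <- group_proteoforms(dplyr::bind_rows(
    prsm_row("S1", "P1", 10000.0, 7L), prsm_row("S2", "P2", 12000.0, 7L)
  ), cfg)
  expect_equal(nrow(g3), 1L)
  # best E-value is the group representative's
  g4 <- group_proteoforms(dplyr::bind_rows(
    prsm_row("S1", "P1", 10000.0, 1L, 1e-3),
    prsm_row("S2", "P1", 10000.5, 2L, 1e-9)
  ), cfg)
  expect_equal(g4$best_evalue, 1e-9)
})

test_that("the pipeline reduces to a single-precursor search on single spectra", {
  p <- sim_params(seed = 23)
  bm <- gen_benchmark(p, n_spectra = 15, scenario_mix = c(single = 1))
  db <- build_decoy_db(bm$proteome, seed = 23)
  res <- run_pipeline(bm$spectra, db)
  expect_true(all(res$decisions$classification == "single"))
  expect_lte(max(table(res$prsms$spectrum_id)), 1L)
  index <- build_search_index(db)
  direct <- dplyr::bind_rows(lapply(seq_len(15), function(i) {
    r <- bm$spectra[i, ]
    hit <- search_pfps(r$precursors[[1]][1, ], r$frag_masses[[1]], index)
    if (!is.null(hit)) hit$spectrum_id <- r$spectrum_id
    hit
  }))
  expect_equal(sort(res$prsms$accession), sort(direct$accession))
})

test_that("fragment intensities never change pipeline output", {
  p <- sim_params(seed = 31)
  bm <- gen_benchmark(p, n_spectra = 10, scenario_mix = c(normal = 1))
  db <- build_decoy_db(bm$proteome, seed = 31)
  doubled <- bm$spectra
  doubled$frag_intensities <- lapply(doubled$frag_intensities, function(x) 2 * x)
  r1 <- run_pipeline(bm$spectra, db)
  r2 <- run_pipeline(doubled, db)
  expect_equal(r1$prsms, r2$prsms)
  expect_equal(r1$groups, r2$groups)
})

test_that("an empty database yields empty result tables", {
  p <- sim_params(seed = 3)
  bm <- gen_benchmark(p, n_spectra = 3, scenario_mix = c(normal = 1))
  empty_db <- fixture_db()[0, ]
  res <- run_pipeline(bm$spectra, empty_db)
  expect_equal(nrow(res$prsms), 0L)
  expect_equal(nrow(res$groups), 0L)
})

test_that("pipeline output satisfies the PrSM structural invariants", {
  p <- sim_params(seed = 47)
  bm <- gen_benchmark(p, n_spectra = 30,
                      scenario_mix = c(normal = 0.6, `swapped-intensity` = 0.4))
  db <- build_decoy_db(bm$proteome, seed = 47)
  cfg <- demux_config()
  res <- run_pipeline(bm$spectra, db, cfg)
  # at most 2 PrSMs per spectrum; matched sets are subsets of the spectrum
  counts <- table(res$prsms$spectrum_id)
  expect_lte(max(counts), 2L)
  for (i in seq_len(nrow(res$prsms))) {
    sp <- bm$spectra[bm$spectra$spectrum_id == res$prsms$spectrum_id[i], ]
    expect_true(all(res$prsms$matched_masses[[i]] %in% sp$frag_masses[[1]]))
    expect_equal(res$prsms$matched_count[i],
                 length(res$prsms$matched_masses[[i]]))
  }
  # stored NNMFM is reproducible from stored fields
  expect_equal(
    res$prsms$nnmfm,
    res$prsms$matched_count - res$prsms$shift_count * cfg$delta -
      res$prsms$precursor_rank * cfg$gamma
  )
})
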