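# Ground-truthed simulator of random proteomes and deconvoluted multiplexed
# MS/MS spectra. The generator emulates the statistical structure the
# pipeline's decisions depend on — partial b/y fragment coverage, ppm-scale
# mass error, uniform noise masses, optional single unknown mass shifts, and
# two co-isolated precursors with controlled intensity order — not raw
# spectra (no isotopic envelopes, charge distributions or elution profiles).

#' Simulation parameters
#'
#' @param n_proteins Number of proteins in the synthetic proteome.
#' @param len_range Integer (min, max) sequence length in residues; min
#'   must be >= 10.
#' @param coverage Probability each theoretical b/y ion is observed.
#' @param coverage_range Optional (lo, hi): when set, each simulated
#'   proteoform draws its own observation probability uniformly from this
#'   interval instead of using `coverage`, emulating the broad
#'   fragment-coverage spread of real identified spectra (needed for the
#'   ratio-paired benchmark, whose validity rule compares base and additive
#'   fragment counts).
#' @param mass_error_ppm Standard deviation of the Gaussian relative mass
#'   error applied to observed fragments, in ppm.
#' @param n_noise Number of uniform noise masses added per spectrum.
#' @param shift_prob Probability a simulated proteoform carries one unknown
#'   mass shift. The default mirrors the one-shift share typically seen
#'   among identified non-multiplexed top-down spectra (roughly 45%).
#' @param shift_range_da (min, max) of the uniform shift value, Da.
#' @param intensity_ratio_range (lo, hi) of the secondary/primary precursor
#'   intensity ratio, within (0, 1].
#' @param seed Integer seed; all generator outputs are deterministic in it.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_proteins = 50L,
                       len_range = c(30L, 60L),
                       coverage = 0.8,
                       coverage_range = NULL,
                       mass_error_ppm = 5,
                       n_noise = 5L,
                       shift_prob = 0.4,
                       shift_range_da = c(-50, 200),
                       intensity_ratio_range = c(0.25, 0.8),
                       seed = 42L) {
  p <- list(
    n_proteins = as.integer(n_proteins), len_range = as.integer(len_range),
    coverage = coverage, coverage_range = coverage_range,
    mass_error_ppm = mass_error_ppm,
    n_noise = as.integer(n_noise), shift_prob = shift_prob,
    shift_range_da = shift_range_da,
    intensity_ratio_range = intensity_ratio_range, seed = as.integer(seed)
  )
  stopifnot(
    p$coverage >= 0, p$coverage <= 1, p$shift_prob >= 0, p$shift_prob <= 1,
    length(p$len_range) == 2L, p$len_range[1] >= 10L,
    p$len_range[1] <= p$len_range[2],
    p$mass_error_ppm >= 0, p$n_noise >= 0,
    is.null(p$coverage_range) ||
      (length(p$coverage_range) == 2L && p$coverage_range[1] >= 0 &&
         p$coverage_range[2] <= 1 && p$coverage_range[1] <= p$coverage_range[2]),
    length(p$shift_range_da) == 2L,
    p$shift_range_da[1] < p$shift_range_da[2],
    length(p$intensity_ratio_range) == 2L,
    p$intensity_ratio_range[1] > 0, p$intensity_ratio_range[2] <= 1,
    p$intensity_ratio_range[1] <= p$intensity_ratio_range[2]
  )
  structure(p, class = "sim_params")
}

gen_proteome_impl <- function(params) {
  lens <- sample(seq(params$len_range[1], params$len_range[2]),
                 params$n_proteins, replace = TRUE)
  seqs <- vapply(lens, function(L) {
    paste(sample(names(AA_MONO), L, replace = TRUE), collapse = "")
  }, character(1))
  tibble(
    accession = sprintf("SYN_%04d", seq_len(params$n_proteins)),
    sequence = seqs,
    is_decoy = FALSE
  )
}

#' Generate a random proteome
#'
#' Sequences have i.i.d. uniform residues and uniform lengths in
#' `len_range`; accessions are `SYN_0001` onwards. Deterministic in
#' `params$seed`.
#'
#' @param params A [sim_params()] object.
#' @return A protein tibble.
#' @export
gen_proteome <- function(params = sim_params()) {
  withr::with_seed(params$seed, gen_proteome_impl(params))
}

# True neutral ion masses of a proteoform whose single mass shift sits after
# split site s (matcher convention: prefixes with index <= s are unshifted,
# suffixes over cleavage j <= s carry the shift).
proteoform_ion_masses <- function(form, shift_da = 0, split = 0L) {
  p <- form$prefix_masses
  np <- length(p)
  j <- seq_len(np)
  b <- p + shift_da * (j > split)
  y <- (form$proteoform_mass - p) + shift_da * (j <= split)
  list(b = b, y = y)
}

# Draw one proteoform state (shift indicator, value, split site).
draw_proteoform_state <- function(form, params) {
  np <- length(form$prefix_masses)
  if (runif(1) < params$shift_prob) {
    list(shift = runif(1, params$shift_range_da[1], params$shift_range_da[2]),
         split = sample.int(np + 1L, 1L) - 1L, shifted = TRUE)
  } else {
    list(shift = 0, split = 0L, shifted = FALSE)
  }
}

# Observe a proteoform's ions with per-ion probability `prob`, returning the
# observed true masses (before mass error).
observe_ions <- function(ions, prob) {
  all_masses <- c(ions$b, ions$y)
  all_masses[runif(length(all_masses)) < prob]
}

#' Generate one synthetic deconvoluted spectrum
#'
#' Simulates a single- or two-proteoform (HetM) spectrum with ground truth.
#' In the `"normal"` scenario the higher-intensity precursor (`protein_a`)
#' contributes at least as many fragments as the second; in the
#' `"swapped-intensity"` scenario the high-intensity precursor's proteoform
#' is observed at a third of `coverage` while the low-intensity proteoform
#' keeps full coverage (and at least twice the fragments), the setting in
#' which naive top-intensity-first search produces precursor selection
#' errors. Uses the current RNG state; seed externally (see
#' [gen_benchmark()]) for reproducibility.
#'
#' @param protein_a One-row protein tibble for the higher-intensity
#'   precursor.
#' @param protein_b One-row protein tibble for the second precursor, or
#'   `NULL` for a single-proteoform spectrum.
#' @param params A [sim_params()] object.
#' @param scenario `"normal"` or `"swapped-intensity"`.
#' @param spectrum_id Id for the generated spectrum.
#' @param feature_start First feature id to assign (precursors get
#'   consecutive ids).
#' @return A list with `spectrum` (one-row spectra tibble) and `truth`
#'   (one-row ground-truth tibble with fragment index sets).
#' @export
gen_spectrum <- function(protein_a, protein_b = NULL, params = sim_params(),
                         scenario = c("normal", "swapped-intensity"),
                         spectrum_id = "SYN_SPEC_0001",
                         feature_start = 1L) {
  scenario <- match.arg(scenario)
  form_a <- theoretical_prefix_masses(protein_a$sequence)
  state_a <- draw_proteoform_state(form_a, params)
  ions_a <- proteoform_ion_masses(form_a, state_a$shift, state_a$split)
  has_b <- !is.null(protein_b)

  draw_cov <- function() {
    if (is.null(params$coverage_range)) params$coverage
    else runif(1, params$coverage_range[1], params$coverage_range[2])
  }
  cov_a <- draw_cov()
  if (has_b && scenario == "swapped-intensity") cov_a <- cov_a / 3
  obs_a <- observe_ions(ions_a, cov_a)

  obs_b <- numeric(0)
  state_b <- list(shift = NA_real_, split = NA_integer_, shifted = NA)
  mass_b <- NA_real_
  if (has_b) {
    form_b <- theoretical_prefix_masses(protein_b$sequence)
    state_b <- draw_proteoform_state(form_b, params)
    ions_b <- proteoform_ion_masses(form_b, state_b$shift, state_b$split)
    obs_b <- observe_ions(ions_b, draw_cov())
    if (scenario == "swapped-intensity") {
      cap <- floor(length(obs_b) / 2)
      if (length(obs_a) > cap) obs_a <- sample(obs_a, cap)
    } else {
      if (length(obs_b) > length(obs_a)) obs_b <- sample(obs_b, length(obs_a))
    }
    mass_b <- form_b$proteoform_mass + state_b$shift
  }
  mass_a <- form_a$proteoform_mass + state_a$shift

  perturb <- function(m) {
    if (!length(m)) return(m)
    m * (1 + rnorm(length(m), 0, params$mass_error_ppm * 1e-6))
  }
  noise_hi <- 0.95 * max(mass_a, mass_b, na.rm = TRUE)
  noise <- runif(params$n_noise, 200, max(noise_hi, 201))
  masses <- c(perturb(obs_a), perturb(obs_b), noise)
  origin <- c(rep("base", length(obs_a)), rep("additive", length(obs_b)),
              rep("noise", length(noise)))
  ord <- order(masses)
  masses <- masses[ord]
  origin <- origin[ord]
  keep <- !duplicated(masses)
  masses <- masses[keep]
  origin <- origin[keep]

  intensity_a <- runif(1, 1e5, 1e6)
  mz_of <- function(mass) {
    charge <- max(1L, as.integer(round(mass / runif(1, 800, 1000))))
    list(charge = charge, mz = mass / charge + PROTON_MASS)
  }
  mza <- mz_of(mass_a)
  if (has_b) {
    mzb <- mz_of(mass_b)
    ratio <- runif(1, params$intensity_ratio_range[1], params$intensity_ratio_range[2])
    prec <- precursor_table(
      feature_id = c(feature_start, feature_start + 1L),
      neutral_mass = c(mass_a, mass_b),
      charge = c(mza$charge, mzb$charge),
      avg_mz = c(mza$mz, mzb$mz),
      intensity = c(intensity_a, intensity_a * ratio)
    )
  } else {
    prec <- precursor_table(
      feature_id = feature_start, neutral_mass = mass_a,
      charge = mza$charge, avg_mz = mza$mz, intensity = intensity_a
    )
  }
  spectrum <- deconv_spectra(
    spectrum_id = spectrum_id,
    iso_lo = mza$mz - 1.5, iso_hi = mza$mz + 1.5,
    precursors = list(prec),
    frag_masses = list(masses),
    frag_intensities = list(round(runif(length(masses), 10, 1000), 2))
  )
  truth <- tibble(
    spectrum_id = spectrum_id,
    base_accession = protein_a$accession,
    additive_accession = if (has_b) protein_b$accession else NA_character_,
    base_shift_da = state_a$shift,
    additive_shift_da = state_b$shift,
    base_frag_count = sum(origin == "base"),
    additive_frag_count = sum(origin == "additive"),
    base_frag_ids = list(which(origin == "base")),
    additive_frag_ids = list(which(origin == "additive")),
    base_feature_id = feature_start,
    additive_feature_id = if (has_b) feature_start + 1L else NA_integer_,
    scenario = if (has_b) scenario else "single"
  )
  list(spectrum = spectrum, truth = truth)
}

#' Generate a ground-truthed benchmark dataset
#'
#' Draws a proteome (unless one is supplied), pairs proteins by adjacent
#' proteoform mass (the heavier member gets the higher-intensity precursor,
#' so the cross-precursor mass difference usually falls inside the allowed
#' shift range, as co-isolation implies for real data), and generates
#' `n_spectra` spectra with scenarios sampled from `scenario_mix`. Fully
#' deterministic in `params$seed`.
#'
#' @param params A [sim_params()] object.
#' @param n_spectra Number of spectra to generate.
#' @param scenario_mix Named probabilities over `"normal"`,
#'   `"swapped-intensity"` and `"single"`.
#' @param proteome Optional protein tibble to reuse.
#' @return A list with `proteome`, `spectra` and `truth` tibbles.
#' @export
gen_benchmark <- function(params = sim_params(), n_spectra = 200L,
                          scenario_mix = c(normal = 1), proteome = NULL) {
  stopifnot(all(names(scenario_mix) %in% c("normal", "swapped-intensity", "single")),
            all(scenario_mix >= 0), sum(scenario_mix) > 0)
  withr::with_seed(params$seed, {
    if (is.null(proteome)) proteome <- gen_proteome_impl(params)
    masses <- map_dbl(proteome$sequence,
                      ~ theoretical_prefix_masses(.x)$proteoform_mass)
    ord <- order(masses)
    n_pairs <- floor(length(ord) / 2)
    pair_idx <- map(seq_len(n_pairs), function(k) {
      duo <- ord[c(2L * k - 1L, 2L * k)]
      duo[order(-masses[duo])]  # heavier first -> higher-intensity precursor
    })
    scen <- sample(names(scenario_mix), n_spectra, replace = TRUE,
                   prob = scenario_mix)
    out <- vector("list", n_spectra)
    for (i in seq_len(n_spectra)) {
      if (scen[i] == "single") {
        a <- proteome[sample.int(nrow(proteome), 1L), , drop = FALSE]
        b <- NULL
        s <- "normal"
      } else {
        duo <- pair_idx[[sample.int(n_pairs, 1L)]]
        a <- proteome[duo[1], , drop = FALSE]
        b <- proteome[duo[2], , drop = FALSE]
        s <- scen[i]
      }
      out[[i]] <- gen_spectrum(
        a, b, params, scenario = s,
        spectrum_id = sprintf("SYN_SPEC_%04d", i),
        feature_start = 2L * i - 1L
      )
    }
    list(
      proteome = proteome,
      spectra = bind_rows(map(out, "spectrum")),
      truth = bind_rows(map(out, "truth"))
    )
  })
}
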