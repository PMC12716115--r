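# Shared fixture builders. Everything is generated in code at test time.

# A tiny deterministic protein database.
fixture_db <- function() {
  tibble::tibble(
    accession = c("P_A", "P_B", "P_C"),
    sequence = c(
      "MKVLAHTGERSWQDN",      # 15 residues
      "ACDEFGHIKLMNPQRSTVWY", # 20 residues, all distinct
      "GGSSAAPPTTVVLLKKRRDD"  # 20 residues
    ),
    is_decoy = FALSE
  )
}

# One-row spectra tibble from explicit parts.
fixture_spectrum <- function(id, prec, frags, iso = NULL) {
  if (is.null(iso)) iso <- c(min(prec$avg_mz) - 1.5, max(prec$avg_mz) + 1.5)
  deconv_spectra(
    spectrum_id = id, iso_lo = iso[1], iso_hi = iso[2],
    precursors = list(prec), frag_masses = list(sort(frags))
  )
}

# A precursor row for a proteoform of neutral mass `mass`.
fixture_precursor <- function(mass, intensity, feature_id = 1L, charge = 8L) {
  precursor_table(
    feature_id = feature_id, neutral_mass = mass, charge = charge,
    avg_mz = mass / charge + 1.00727646688, intensity = intensity
  )
}

# All theoretical b/y masses of a sequence (optionally shifted after `split`).
fixture_ions <- function(sequence, shift = 0, split = 0L) {
  form <- theoretical_prefix_masses(sequence)
  p <- form$prefix_masses
  j <- seq_along(p)
  c(p + shift * (j > split), (form$proteoform_mass - p) + shift * (j <= split))
}

# Independent brute-force oracle for the one-shift matcher: enumerate every
# split, build the full theoretical set, and count matches directly.
brute_force_one_shift <- function(frag_masses, form, shift_da, tol_ppm) {
  p <- form$prefix_masses
  np <- length(p)
  m0 <- form$proteoform_mass
  msh <- m0 + shift_da
  best <- list(matched = numeric(0), count = -1L, split = 0L)
  for (i in 0:np) {
    j <- seq_len(np)
    theo <- c(p[j <= i], p[j > i] + shift_da, msh - p[j <= i], m0 - p[j > i])
    theo <- theo[theo > 0]
    hit <- vapply(frag_masses, function(m) {
      any(abs(m - theo) <= tol_ppm * 1e-6 * theo)
    }, logical(1))
    if (sum(hit) > best$count) {
      best <- list(matched = frag_masses[hit], count = sum(hit), split = i)
    }
  }
  best
}

# A random amino-acid sequence of length n (uses the current RNG stream).
random_sequence <- function(n) {
  paste(sample(names(residue_masses()), n, replace = TRUE), collapse = "")
}
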