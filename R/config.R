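#' Pipeline configuration
#'
#' Builds the validated parameter set shared by all stages of the
#' demultiplexing pipeline. Defaults are the method's published operating
#' point on top-down DDA data.
#'
#' @param alpha Intensity-ratio threshold (I2/I1, inclusive) above which a
#'   spectrum with two precursors is classified as multiplexed. Fraction in
#'   \[0, 1\]; default 0.2.
#' @param beta Shared-matched-fragment ratio (inclusive) at or above which a
#'   pair of precursor-fragment paired spectrum (PFPS) identifications is
#'   flagged error-prone. Fraction in \[0, 1\]; default 0.7.
#' @param delta Penalty, in matched-fragment-count units, per unknown mass
#'   shift in the NNMFM score. Default 5.
#' @param gamma Penalty, in matched-fragment-count units, applied to the
#'   PrSM of the second-highest-intensity precursor in the NNMFM score.
#'   Default 4.
#' @param frag_tol_ppm Fragment mass tolerance in parts per million.
#'   Default 15.
#' @param shift_min_da,shift_max_da Allowed range for a single unknown mass
#'   shift, in Daltons. Defaults -50 and 200.
#' @param zero_shift_tol_da Maximum |precursor mass - proteoform mass| for a
#'   zero-shift search, in Daltons; absorbs +/-1 Da isotope errors.
#'   Default 1.2.
#' @param evalue_cutoff E-value threshold used when filtering by E-value
#'   instead of FDR. Default 0.01.
#' @param fdr_spectrum Spectrum-level target-decoy FDR cutoff. Default 0.01.
#' @param fdr_proteoform Proteoform-level target-decoy FDR cutoff.
#'   Default 0.01.
#' @param group_mass_tol_da Precursor mass difference (exclusive upper bound,
#'   Da) under which two same-protein PrSMs are grouped into one proteoform.
#'   Default 1.2.
#' @param min_match Minimum matched fragment masses for a PrSM to be
#'   reported at all. Default 4.
#' @param seed Integer seed governing any randomized stage run under this
#'   configuration. Default 1.
#' @return A list of class `demux_config`.
#' @export
#' @examples
#' cfg <- demux_config()
#' cfg$alpha
demux_config <- function(alpha = 0.2,
                         beta = 0.7,
                         delta = 5,
                         gamma = 4,
                         frag_tol_ppm = 15,
                         shift_min_da = -50,
                         shift_max_da = 200,
                         zero_shift_tol_da = 1.2,
                         evalue_cutoff = 0.01,
                         fdr_spectrum = 0.01,
                         fdr_proteoform = 0.01,
                         group_mass_tol_da = 1.2,
                         min_match = 4,
                         seed = 1L) {
  cfg <- list(
    alpha = alpha, beta = beta, delta = delta, gamma = gamma,
    frag_tol_ppm = frag_tol_ppm, shift_min_da = shift_min_da,
    shift_max_da = shift_max_da, zero_shift_tol_da = zero_shift_tol_da,
    evalue_cutoff = evalue_cutoff, fdr_spectrum = fdr_spectrum,
    fdr_proteoform = fdr_proteoform, group_mass_tol_da = group_mass_tol_da,
    min_match = min_match, seed = as.integer(seed)
  )
  validate_config(cfg)
  structure(cfg, class = "demux_config")
}

validate_config <- function(cfg) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (key in c("alpha", "beta", "delta", "gamma", "frag_tol_ppm",
                "shift_min_da", "shift_max_da", "zero_shift_tol_da",
                "evalue_cutoff", "fdr_spectrum", "fdr_proteoform",
                "group_mass_tol_da", "min_match")) {
    if (!num1(cfg[[key]])) abort(paste0("config key `", key, "` must be a finite number"))
  }
  if (cfg$alpha < 0 || cfg$alpha > 1) abort("alpha must lie in [0, 1]")
  if (cfg$beta < 0 || cfg$beta > 1) abort("beta must lie in [0, 1]")
  if (cfg$delta < 0 || cfg$gamma < 0) abort("delta and gamma must be >= 0")
  if (cfg$shift_min_da >= cfg$shift_max_da) abort("shift_min_da must be < shift_max_da")
  for (key in c("frag_tol_ppm", "zero_shift_tol_da", "group_mass_tol_da")) {
    if (cfg[[key]] <= 0) abort(paste0("config key `", key, "` must be > 0"))
  }
  if (cfg$fdr_spectrum < 0 || cfg$fdr_spectrum > 1 ||
      cfg$fdr_proteoform < 0 || cfg$fdr_proteoform > 1) {
    abort("FDR cutoffs must lie in [0, 1]")
  }
  invisible(cfg)
}

#' @export
print.demux_config <- function(x, ...) {
  cat("<demux_config>\n")
  for (key in names(x)) cat(sprintf("  %-18s %s\n", key, format(x[[key]])))
  invisible(x)
}

#' Read a configuration file
#'
#' Reads a YAML key-value file whose keys are the [demux_config()] argument
#' names and returns a validated configuration. Unknown keys are an error.
#'
#' @param path Path to a YAML file.
#' @return A `demux_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.list(vals)) abort("config file must contain key: value pairs")
  known <- names(formals(demux_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    abort(paste0("unknown config key(s): ", paste(bad, collapse = ", ")))
  }
  do.call(demux_config, vals)
}
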