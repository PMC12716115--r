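# broom-style accessors and quick-look plots for result objects.

#' Tidy a demultiplexing result
#'
#' @param x A `demux_result` from [run_pipeline()].
#' @param ... Unused.
#' @return The accepted PrSM tibble (one row per identification), without
#'   the matched-mass list column.
#' @method tidy demux_result
#' @export
tidy.demux_result <- function(x, ...) {
  out <- as_tibble(x$prsms)
  out$matched_masses <- NULL
  out
}

#' One-row summary of a demultiplexing result
#'
#' @param x A `demux_result`.
#' @param ... Unused.
#' @return A one-row tibble: spectrum counts, accepted PrSMs per round,
#'   proteoform groups, and error-prone spectra flagged during selection.
#' @method glance demux_result
#' @export
glance.demux_result <- function(x, ...) {
  tibble(
    n_spectra = x$n_spectra,
    n_multiplexed = x$n_multiplexed,
    n_prsms = nrow(x$prsms),
    n_prsms_round1 = sum(x$prsms$round == 1L),
    n_prsms_round2 = sum(x$prsms$round == 2L),
    n_groups = nrow(x$groups),
    n_error_prone = sum(x$decisions$error_prone %in% TRUE)
  )
}

#' Plot identifications per search round
#'
#' @param object A `demux_result`.
#' @param ... Unused.
#' @return A ggplot: accepted PrSM counts by round and shift count.
#' @method autoplot demux_result
#' @export
autoplot.demux_result <- function(object, ...) {
  df <- tidy(object)
  df$round <- factor(df$round, levels = c(1L, 2L),
                     labels = c("round 1 (primary)", "round 2 (secondary)"))
  df$shifts <- factor(df$shift_count)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$round, fill = .data$shifts)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = NULL, y = "accepted PrSMs", fill = "mass shifts") +
    ggplot2::theme_minimal()
}

#' Plot an error report
#'
#' @param object An `error_report` from [evaluate_errors()].
#' @param ... Unused.
#' @return A ggplot: stacked outcome counts per precursor role.
#' @method autoplot error_report
#' @export
autoplot.error_report <- function(object, ...) {
  df <- tidyr::pivot_longer(
    as_tibble(object)[, c("role", "n_correct", "n_pse", "n_rme", "n_missed")],
    -"role", names_to = "outcome", values_to = "n"
  )
  df$outcome <- factor(df$outcome,
                       levels = c("n_correct", "n_pse", "n_rme", "n_missed"),
                       labels = c("correct", "PSE", "RME", "missed"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$role, y = .data$n,
                                   fill = .data$outcome)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "precursor role", y = "spectra", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a penalty sweep
#'
#' @param object A `dg_sweep` from [sweep_delta_gamma()].
#' @param ... Unused.
#' @return A ggplot: base-precursor PSE rate over the (delta, gamma) grid.
#' @method autoplot dg_sweep
#' @export
autoplot.dg_sweep <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = factor(.data$delta), y = factor(.data$gamma),
                               fill = .data$base_pse_rate)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = expression(delta), y = expression(gamma),
                  fill = "base PSE rate") +
    ggplot2::theme_minimal()
}
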