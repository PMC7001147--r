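# ggplot2 displays for the main result types

#' @method autoplot staircase_trace
#' @export
autoplot.staircase_trace <- function(object, ...) {
  df <- tidy(object)
  srt_val <- attr(object, "srt_db")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trial, y = .data$snr_db)) +
    ggplot2::geom_step(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$passed, colour = .data$is_reversal), size = 2) +
    ggplot2::geom_hline(yintercept = srt_val, linetype = 2, colour = "red") +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 4)) +
    ggplot2::labs(
      x = "sentence presentation", y = "SNR (dB)",
      title = sprintf("Adaptive staircase (SRT = %.2f dB)", srt_val),
      shape = "passed", colour = "reversal"
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot envt_spectrum
#' @export
autoplot.envt_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$freq_hz, y = .data$amplitude)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (Hz)", y = "amplitude", title = "Envelope amplitude spectrum") +
    ggplot2::theme_minimal()
}

#' @method autoplot envt_acf
#' @export
autoplot.envt_acf <- function(object, ...) {
  thr <- attr(object, "sig_threshold")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lag_ms, y = .data$r)) +
    ggplot2::geom_hline(yintercept = c(-thr, thr), linetype = 3, colour = "red") +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "lag (ms)", y = "autocorrelation",
      title = "Envelope autocorrelation with localization band"
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot envt_corr_map
#' @export
autoplot.envt_corr_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lag_ms, y = .data$phase_deg, fill = .data$r)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(
      x = "lag (ms)", y = "phase shift (deg)", fill = "r",
      title = "Phase shift versus time lag correlation"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an SRT-versus-phase profile with its multiperiodic fit
#'
#' Shows the mean sham-normalized SRT per phase (with standard-error
#' bars over subjects) and the reconstruction of a fit.
#'
#' @param profiles Data frame `subject`, `phase_deg`, `srt_db`.
#' @param fit Optional `multiperiodic_fit` drawn as a curve.
#' @return A ggplot.
#' @export
plot_phase_profile <- function(profiles, fit = NULL) {
  profiles <- tibble::as_tibble(profiles)
  summ <- profiles |>
    dplyr::group_by(.data$phase_deg) |>
    dplyr::summarise(
      mean_db = mean(.data$srt_db),
      se_db = stats::sd(.data$srt_db) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  p <- ggplot2::ggplot(summ, ggplot2::aes(x = .data$phase_deg, y = .data$mean_db)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$mean_db - .data$se_db,
        ymax = .data$mean_db + .data$se_db
      ),
      width = 8
    ) +
    ggplot2::scale_x_continuous(breaks = seq(0, 300, by = 60)) +
    ggplot2::labs(x = "stimulation phase (deg)", y = "SRT re sham (dB)") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    grid <- tibble::tibble(phase_deg = seq(0, 360, by = 1))
    grid$fit_db <- reconstruct(fit, grid$phase_deg)
    p <- p + ggplot2::geom_line(
      data = grid, ggplot2::aes(x = .data$phase_deg, y = .data$fit_db),
      colour = "red"
    )
  }
  p
}
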