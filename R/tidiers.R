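#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a multiperiodic fit
#'
#' One row per component (including the mean level as `k = 0`).
#'
#' @param x A `multiperiodic_fit`.
#' @param ... Unused.
#' @return A tibble with `k`, `period_deg`, `amplitude_db`, `psi_deg`.
#' @method tidy multiperiodic_fit
#' @export
tidy.multiperiodic_fit <- function(x, ...) {
  tibble::tibble(
    k = 0:3,
    period_deg = c(NA, 360, 180, 120),
    amplitude_db = c(x$A0, x$A),
    psi_deg = c(NA, x$psi_deg)
  )
}

#' @rdname tidy.multiperiodic_fit
#' @method glance multiperiodic_fit
#' @export
glance.multiperiodic_fit <- function(x, ...) {
  tibble::tibble(
    A0 = x$A0,
    modulation_depth_db = {
      e <- extrema(x)
      e$srt_max - e$srt_min
    },
    dominant_period_deg = c(360, 180, 120)[which.max(x$A)]
  )
}

#' Tidy a LASSO/LARS selection result
#'
#' @param x An `envt_selection`.
#' @param ... Unused.
#' @return The per-amplitude tibble (`k`, `period_deg`, `amplitude_cv`,
#'   `selected_cv`, `p_value`, `significant`).
#' @method tidy envt_selection
#' @export
tidy.envt_selection <- function(x, ...) {
  x$amplitudes
}

#' @rdname tidy.envt_selection
#' @method glance envt_selection
#' @export
glance.envt_selection <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_subjects = x$n_subjects, lambda_cv = x$lambda_cv,
    frac_cv = x$frac_cv, sigma2 = x$sigma2,
    n_selected = sum(x$amplitudes$selected_cv),
    n_significant = sum(x$amplitudes$significant)
  )
}

#' Tidy a staircase trace
#'
#' @param x A `staircase_trace`.
#' @param ... Unused.
#' @return The per-trial tibble.
#' @method tidy staircase_trace
#' @export
tidy.staircase_trace <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("trial", "snr_db", "n_correct", "passed", "is_reversal")])
}

#' @rdname tidy.staircase_trace
#' @method glance staircase_trace
#' @export
glance.staircase_trace <- function(x, ...) {
  tibble::tibble(
    srt_db = attr(x, "srt_db"),
    n_trials = nrow(x),
    n_reversals = sum(x$is_reversal)
  )
}
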