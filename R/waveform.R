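#' Sampled waveform and envelope objects
#'
#' `waveform()` wraps a real amplitude series sampled at a fixed rate
#' (e.g. a speech recording); `envelope()` wraps a slow amplitude
#' envelope. A raw envelope (`is_raw = TRUE`) is nonnegative, as produced
#' by magnitude extraction; phase-shifted or conditioned envelopes are
#' zero-mean and carry `is_raw = FALSE`.
#'
#' @param samples Numeric vector of amplitudes (arbitrary units).
#' @param rate Sampling rate in Hz.
#' @param is_raw Logical; `TRUE` for a nonnegative pre-conditioning envelope.
#' @return An object of class `envt_waveform` (resp. `envt_envelope`), a
#'   list with elements `samples` and `rate`.
#' @examples
#' t <- seq(0, 1, by = 1 / 100)
#' env <- envelope(1 + cos(2 * pi * 2 * t), rate = 100)
#' duration(env)
#' @export
waveform <- function(samples, rate) {
  samples <- as.numeric(samples)
  assert_scalar_num(rate, "rate", positive = TRUE)
  if (length(samples) < 2L) {
    stop_envtacs("a waveform needs at least 2 samples")
  }
  if (!all(is.finite(samples))) {
    stop_envtacs("all waveform samples must be finite")
  }
  structure(list(samples = samples, rate = rate), class = "envt_waveform")
}

#' @rdname waveform
#' @export
envelope <- function(samples, rate, is_raw = TRUE) {
  w <- waveform(samples, rate)
  if (isTRUE(is_raw) && any(w$samples < 0)) {
    stop_envtacs("a raw envelope must be nonnegative; use is_raw = FALSE for conditioned signals")
  }
  structure(
    list(samples = w$samples, rate = w$rate, is_raw = isTRUE(is_raw)),
    class = c("envt_envelope", "envt_waveform")
  )
}

#' @rdname waveform
#' @param x A waveform-like object.
#' @export
duration <- function(x) {
  UseMethod("duration")
}

#' @export
duration.envt_waveform <- function(x) length(x$samples) / x$rate

#' @export
print.envt_waveform <- function(x, ...) {
  cls <- class(x)[1]
  label <- switch(cls,
    envt_envelope = if (isTRUE(x$is_raw)) "raw envelope" else "envelope",
    envt_stimwave = "stimulation waveform",
    "waveform"
  )
  cat(sprintf(
    "<%s: %d samples @ %g Hz (%.3f s), range [%.4g, %.4g]>\n",
    label, length(x$samples), x$rate, duration(x),
    min(x$samples), max(x$samples)
  ))
  invisible(x)
}

#' @method as_tibble envt_waveform
#' @export
as_tibble.envt_waveform <- function(x, ...) {
  tibble::tibble(
    time_s = (seq_along(x$samples) - 1) / x$rate,
    value = x$samples
  )
}

#' Discrete analytic signal
#'
#' FFT-based complexification `z = x + i H[x]` with `H` the Hilbert
#' transform: the negative-frequency half of the spectrum is zeroed and
#' the positive half doubled. The real part of the result equals the
#' input exactly; the operator is circular (periodic boundary), so the
#' first and last few samples of broadband inputs carry wrap-around
#' leakage and edge-sensitive callers should pad or evaluate interior
#' samples.
#'
#' @param x Numeric vector.
#' @return Complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2L) stop_envtacs("analytic_signal needs at least 2 samples")
  if (!all(is.finite(x))) stop_envtacs("analytic_signal: input must be finite")
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

# reflect-pad a series by `pad` samples at each end (mirror without
# repeating the end point), used to suppress Hilbert edge ringing
reflect_pad <- function(x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  if (pad <= 0) {
    return(list(x = x, pad = 0L))
  }
  list(x = c(x[(pad + 1):2], x, x[(n - 1):(n - pad)]), pad = pad)
}

#' Extract the slow amplitude envelope of an audio waveform
#'
#' Computes the magnitude of the analytic signal (reflect-padded to tame
#' edge effects) and low-pass filters it with a linear-phase FIR filter
#' (Hamming-windowed sinc) whose group delay is compensated, so the
#' envelope stays time-aligned with the audio. Residual filter ringing
#' below zero is clipped so the result is a valid raw envelope.
#'
#' @param audio A [waveform()].
#' @param cutoff_hz Low-pass cut-off frequency in Hz (default 12, the
#'   upper edge of the slow modulations that carry syllabic rhythm).
#' @return An [envelope()] with `is_raw = TRUE`, same length and rate as
#'   the input.
#' @export
extract_envelope <- function(audio, cutoff_hz = 12) {
  stopifnot(inherits(audio, "envt_waveform"))
  assert_scalar_num(cutoff_hz, "cutoff_hz", positive = TRUE)
  rate <- audio$rate
  if (cutoff_hz >= rate / 2) {
    stop_envtacs(sprintf(
      "cutoff_hz (%g) must be below the Nyquist frequency (%g Hz)",
      cutoff_hz, rate / 2
    ))
  }
  # even order -> odd tap count -> integer group delay
  ord <- round(6 * rate / cutoff_hz / 2) * 2
  ntaps <- ord + 1L
  n <- length(audio$samples)
  if (n <= ntaps) {
    stop_envtacs(sprintf(
      "signal too short for the low-pass filter: need more than %d samples, got %d",
      ntaps, n
    ))
  }
  padded <- reflect_pad(audio$samples, ntaps)
  mag <- Mod(analytic_signal(padded$x))
  if (padded$pad > 0) {
    mag <- mag[(padded$pad + 1):(padded$pad + n)]
  }
  h <- signal::fir1(ord, cutoff_hz / (rate / 2))
  # reflect-pad again so the FIR convolution has full support everywhere
  padded <- reflect_pad(mag, ord)
  y <- fft_convolve(padded$x, h)
  # compensate group delay ord/2, then trim padding
  start <- ord / 2 + padded$pad + 1
  y <- y[start:(start + n - 1)]
  envelope(pmax(y, 0), rate, is_raw = TRUE)
}

# linear FFT convolution returning the "full" convolution
fft_convolve <- function(x, h) {
  n <- length(x) + length(h) - 1L
  nfft <- stats::nextn(n, 2)
  X <- stats::fft(c(x, numeric(nfft - length(x))))
  H <- stats::fft(c(h, numeric(nfft - length(h))))
  Re(stats::fft(X * H, inverse = TRUE) / nfft)[seq_len(n)]
}

#' Phase-shift an envelope through its analytic signal
#'
#' Removes the mean, forms the analytic signal `z(t)`, multiplies by
#' `exp(i * phi)` and returns the real part: every spectral component is
#' rotated by the same angle `phi` while its magnitude is preserved.
#' Positive `phi` advances a cosine: `cos(w t) -> cos(w t + phi)`.
#' A shift of 180 degrees is exact negation of the zero-mean envelope.
#'
#' @param env An [envelope()].
#' @param phi_deg Phase shift in degrees; values outside `[0, 360)` wrap.
#' @return A zero-mean [envelope()] with `is_raw = FALSE`.
#' @export
phase_shift_envelope <- function(env, phi_deg) {
  stopifnot(inherits(env, "envt_envelope"))
  assert_scalar_num(phi_deg, "phi_deg")
  phi <- deg2rad(wrap_deg(phi_deg))
  y0 <- env$samples - mean(env$samples)
  if (phi == 0) {
    return(envelope(y0, env$rate, is_raw = FALSE))
  }
  z <- analytic_signal(y0)
  out <- Re(exp(1i * phi) * z)
  envelope(out, env$rate, is_raw = FALSE)
}

#' Delay an envelope by a whole number of samples
#'
#' Shifts the series later in time by `tau_ms`, quantized to the nearest
#' sample (at typical rates the quantization error is negligible against
#' the 100/250 ms stimulation latencies). The leading gap is zero-filled
#' and the length preserved.
#'
#' @param env An [envelope()].
#' @param tau_ms Delay in milliseconds, `>= 0` and shorter than the signal.
#' @return An [envelope()] of the same length and rate.
#' @export
delay_envelope <- function(env, tau_ms) {
  stopifnot(inherits(env, "envt_envelope"))
  assert_scalar_num(tau_ms, "tau_ms")
  if (tau_ms < 0) stop_envtacs("tau_ms must be >= 0")
  k <- as.integer(round(tau_ms / 1000 * env$rate))
  n <- length(env$samples)
  if (k >= n) {
    stop_envtacs(sprintf(
      "delay of %g ms (%d samples) exceeds the signal duration (%g ms)",
      tau_ms, k, 1000 * duration(env)
    ))
  }
  if (k == 0L) {
    return(env)
  }
  out <- c(numeric(k), env$samples[seq_len(n - k)])
  envelope(out, env$rate, is_raw = isTRUE(env$is_raw) && all(out >= 0))
}
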