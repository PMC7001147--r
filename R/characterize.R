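#' Welch-style amplitude spectrum of an envelope
#'
#' Splits the signal into Hann-tapered segments of `1 / resolution_hz`
#' seconds with 50% overlap and averages the single-sided amplitude
#' spectra. Amplitudes are normalized so a unit-amplitude sinusoid has
#' peak amplitude ~1. The DC component is reported separately in the
#' `dc` attribute, not as a spectral bin.
#'
#' @param env An [envelope()].
#' @param resolution_hz Frequency resolution in Hz (segment length is
#'   `1 / resolution_hz` seconds; default 0.25 Hz, i.e. 4 s segments).
#' @return A tibble of class `envt_spectrum` with columns `freq_hz` and
#'   `amplitude`, and attributes `dc`, `resolution_hz`, `n_segments`.
#' @export
amplitude_spectrum <- function(env, resolution_hz = 0.25) {
  stopifnot(inherits(env, "envt_envelope"))
  assert_scalar_num(resolution_hz, "resolution_hz", positive = TRUE)
  x <- env$samples
  nseg <- as.integer(round(env$rate / resolution_hz))
  if (nseg < 8) stop_envtacs("resolution_hz too coarse for this sampling rate")
  if (length(x) < nseg) {
    stop_envtacs(sprintf(
      "signal too short: need at least %g s for a resolution of %g Hz",
      nseg / env$rate, resolution_hz
    ))
  }
  w <- hann_window(nseg)
  hop <- max(1L, nseg %/% 2L)
  starts <- seq(1L, length(x) - nseg + 1L, by = hop)
  nbin <- nseg %/% 2L
  acc <- numeric(nbin)
  dc <- 0
  scale <- 2 / sum(w)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    dc <- dc + abs(sum(seg * w)) / sum(w)
    seg <- seg - mean(seg) # per-segment detrend; DC is reported separately
    X <- stats::fft(seg * w)
    acc <- acc + Mod(X[2:(nbin + 1L)]) * scale
  }
  m <- length(starts)
  out <- tibble::tibble(
    freq_hz = (1:nbin) * env$rate / nseg,
    amplitude = acc / m
  )
  attr(out, "dc") <- dc / m
  attr(out, "resolution_hz") <- resolution_hz
  attr(out, "n_segments") <- m
  class(out) <- c("envt_spectrum", class(out))
  out
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)

# circular normalized autocorrelation via FFT; returns r at lags 0..L
circ_acf <- function(x, max_lag) {
  x <- x - mean(x)
  n <- length(x)
  S <- Mod(stats::fft(x))^2
  r <- Re(stats::fft(S, inverse = TRUE)) / n
  r[seq_len(max_lag + 1L)] / r[1]
}

#' Autocorrelation of an envelope with a localization band
#'
#' Computes the normalized (circular) autocorrelation on a symmetric lag
#' grid and a two-sided significance band for the null hypothesis that
#' the envelope carries no correlation beyond a short range. Surrogates
#' are drawn from a Gaussian process whose autocovariance equals the
#' sample autocovariance tapered to zero beyond `null_span_ms`; the band
#' is the `(1 - alpha)` quantile of max |r| over lags beyond that span.
#' An envelope is "localized" when its own |r| stays below the band
#' outside the short range.
#'
#' @param env An [envelope()].
#' @param max_lag_ms Largest lag (ms); must be below half the duration.
#' @param n_surrogates Number of surrogate series (default 1000; fewer
#'   than 100 triggers a warning since the max-quantile is unstable).
#' @param alpha Band level (default 0.05).
#' @param seed Integer seed for the surrogate draws.
#' @param null_span_ms Range (ms) within which correlation is allowed
#'   under the null (default 100).
#' @return A tibble of class `envt_acf` with columns `lag_ms` and `r`,
#'   and attributes `sig_threshold`, `alpha`, `null_span_ms`.
#' @export
autocorrelation <- function(env, max_lag_ms, n_surrogates = 1000,
                            alpha = 0.05, seed = 1, null_span_ms = 100) {
  stopifnot(inherits(env, "envt_envelope"))
  assert_scalar_num(max_lag_ms, "max_lag_ms", positive = TRUE)
  if (max_lag_ms >= 1000 * duration(env) / 2) {
    stop_envtacs("max_lag_ms must be below half the signal duration")
  }
  if (n_surrogates < 100) {
    warning("fewer than 100 surrogates: significance band is unstable", call. = FALSE)
  }
  rate <- env$rate
  L <- as.integer(round(max_lag_ms / 1000 * rate))
  k_null <- as.integer(round(null_span_ms / 1000 * rate))
  x <- env$samples - mean(env$samples)
  n <- length(x)

  r_pos <- circ_acf(x, L)

  # null autocovariance: sample autocovariance tapered (half-cosine) to
  # zero between null_span and 2 * null_span, symmetrized circularly
  cov_full <- r_pos * stats::var(x) * (n - 1) / n
  cov_all <- Re(stats::fft(Mod(stats::fft(x))^2, inverse = TRUE)) / n^2
  taper <- numeric(n)
  idx <- 0:(n - 1)
  lag_circ <- pmin(idx, n - idx)
  taper[lag_circ <= k_null] <- 1
  fade <- lag_circ > k_null & lag_circ <= 2L * k_null
  taper[fade] <- 0.5 * (1 + cos(pi * (lag_circ[fade] - k_null) / k_null))
  cov_null <- cov_all * taper
  spec <- Re(stats::fft(cov_null))
  spec[spec < 0] <- 0

  test_lags <- which(seq_len(L) > k_null) # lags (in samples) beyond the span
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  amp <- sqrt(spec)
  max_abs <- vapply(seq_len(n_surrogates), function(i) {
    # complex-Gaussian spectrum: a true Gaussian-process draw from the
    # truncated-covariance null, with proper sampling fluctuation
    z <- amp * (stats::rnorm(n) + 1i * stats::rnorm(n)) / sqrt(2)
    surr <- Re(stats::fft(z, inverse = TRUE)) / sqrt(n)
    rs <- circ_acf(surr, L)
    max(abs(rs[test_lags + 1L]))
  }, numeric(1))
  thr <- stats::quantile(max_abs, 1 - alpha, names = FALSE)

  lags <- -L:L
  out <- tibble::tibble(
    lag_ms = lags / rate * 1000,
    r = r_pos[abs(lags) + 1L]
  )
  attr(out, "sig_threshold") <- thr
  attr(out, "alpha") <- alpha
  attr(out, "null_span_ms") <- null_span_ms
  class(out) <- c("envt_acf", class(out))
  out
}

#' Correlation between phase-shifted and time-lagged envelope copies
#'
#' For each phase `phi` and lag `tau`, the Pearson correlation between
#' the envelope phase-shifted by `phi` and the envelope delayed by `tau`.
#' Lags are applied circularly (wrap-around), which makes the map exact
#' for periodic signals and introduces only O(lag/duration) bias for
#' long aperiodic envelopes. For a pure sinusoid at frequency `f` the map
#' equals `cos(2 pi f tau + phi)`: a lag can be traded against a phase
#' shift. For broadband envelopes no such trade-off exists and the map
#' decays with |lag|.
#'
#' @param env An [envelope()]; must not be constant.
#' @param phases_deg Vector of phase shifts (degrees).
#' @param lags_ms Vector of lags (ms); may be negative. Quantized to
#'   whole samples.
#' @return A tibble of class `envt_corr_map` in long format with columns
#'   `phase_deg`, `lag_ms`, `r`.
#' @export
phase_time_correlation_map <- function(env, phases_deg, lags_ms) {
  stopifnot(inherits(env, "envt_envelope"))
  if (length(phases_deg) == 0 || length(lags_ms) == 0) {
    stop_envtacs("phase and lag grids must be nonempty")
  }
  if (any(abs(lags_ms) > 1000 * duration(env) / 4)) {
    stop_envtacs("lags must be within a quarter of the signal duration")
  }
  x0 <- env$samples - mean(env$samples)
  n <- length(x0)
  if (stats::sd(x0) < 1e-12) stop_envtacs("degenerate (constant) envelope")
  z <- analytic_signal(x0)
  F0 <- stats::fft(x0)
  ks <- as.integer(round(lags_ms / 1000 * env$rate)) %% n
  ss0 <- sum(x0^2)

  rows <- lapply(phases_deg, function(phi) {
    yphi <- Re(exp(1i * deg2rad(wrap_deg(phi))) * z)
    # c_k = sum_t yphi_t * x0_{(t-k) mod n}  (x0 delayed by k samples)
    cc <- Re(stats::fft(Conj(stats::fft(yphi)) * F0)) / n
    r <- cc[ks + 1L] / sqrt(ss0 * sum(yphi^2))
    tibble::tibble(phase_deg = phi, lag_ms = lags_ms, r = pmin(1, pmax(-1, r)))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("envt_corr_map", class(out))
  out
}
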