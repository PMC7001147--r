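#' Ground truth for the synthetic SRT generator
#'
#' Collects every parameter of the data-generating model: per-latency
#' multiperiodic phase effects (offset `a0`, amplitudes `a1..a3` in dB
#' and phase offsets `psi1..psi3`), constant offsets for the control
#' conditions, between-subject and residual noise, the virtual
#' listener's psychometric slope, and the cohort size. The default
#' amplitudes and offsets are generator choices on the dB scale of
#' speech-reception thresholds (roughly matching modulation depths of a
#' couple of dB and a ~2 dB penalty for stimulation with an unrelated
#' envelope); they are not estimates from any particular dataset.
#'
#' @param a_100,a_250 Length-3 amplitude vectors (dB) at the 100 ms and
#'   250 ms latencies (periods 360, 180, 120 degrees).
#' @param psi_100,psi_250 Length-3 phase-offset vectors (degrees); the
#'   third entry must be 0 or 180 (the 120-degree sine is not resolvable
#'   on the 60-degree grid).
#' @param a0_100,a0_250 Mean phase-effect offsets (dB, relative to sham).
#' @param unrelated_env_penalty_db Worsening under the unrelated-envelope
#'   condition (dB, default 2).
#' @param dc_effect_db Offset for the two direct-current conditions
#'   (default 0, i.e. no effect).
#' @param subject_sd_db SD of the per-subject baseline offset.
#' @param residual_sd_db SD of the per-record residual (direct mode).
#' @param slope_db Psychometric slope of the virtual listeners.
#' @param n_subjects Cohort size (default 17).
#' @param baseline_db Baseline SRT in dB SNR (default -6, a typical
#'   multi-talker babble scale; cancels under sham normalization).
#' @return A list of class `envt_truth`.
#' @export
ground_truth <- function(a_100 = c(1.0, 0.8, 0.4),
                         psi_100 = c(26, 90, 0),
                         a0_100 = 0.9,
                         a_250 = c(1.0, 0.8, 0.6),
                         psi_250 = c(346, 120, 180),
                         a0_250 = 0.4,
                         unrelated_env_penalty_db = 2,
                         dc_effect_db = 0,
                         subject_sd_db = 1.5,
                         residual_sd_db = 0.5,
                         slope_db = 1,
                         n_subjects = 17,
                         baseline_db = -6) {
  for (a in list(a_100, a_250)) {
    if (length(a) != 3 || any(a < 0)) stop_envtacs("amplitudes must be 3 nonnegative values")
  }
  for (p in list(psi_100, psi_250)) {
    if (length(p) != 3) stop_envtacs("phase offsets must have length 3")
    if (!wrap_deg(p[3]) %in% c(0, 180)) {
      stop_envtacs("psi3 must be 0 or 180 degrees (sine not resolvable at the alias limit)")
    }
  }
  if (subject_sd_db < 0 || residual_sd_db < 0) stop_envtacs("sds must be >= 0")
  structure(
    list(
      a_100 = a_100, psi_100 = psi_100, a0_100 = a0_100,
      a_250 = a_250, psi_250 = psi_250, a0_250 = a0_250,
      unrelated_env_penalty_db = unrelated_env_penalty_db,
      dc_effect_db = dc_effect_db, sham_effect_db = 0,
      subject_sd_db = subject_sd_db, residual_sd_db = residual_sd_db,
      slope_db = slope_db, n_subjects = as.integer(n_subjects),
      baseline_db = baseline_db
    ),
    class = "envt_truth"
  )
}

# condition effect relative to sham, in dB
condition_effect <- function(truth, kind, phase_deg, latency_ms) {
  if (kind == "sham") {
    return(truth$sham_effect_db)
  }
  if (kind %in% c("dc_plus", "dc_minus")) {
    return(truth$dc_effect_db)
  }
  if (kind == "unrelated_env") {
    return(truth$unrelated_env_penalty_db)
  }
  if (kind == "env_tacs") {
    a <- if (latency_ms == 100) truth$a_100 else truth$a_250
    psi <- if (latency_ms == 100) truth$psi_100 else truth$psi_250
    a0 <- if (latency_ms == 100) truth$a0_100 else truth$a0_250
    phi <- deg2rad(phase_deg)
    return(a0 + sum(a * cos((1:3) * phi - deg2rad(psi))))
  }
  stop_envtacs(sprintf("unknown condition kind '%s'", kind))
}

# Spectral power profile of the speech-like generator: a smooth sum of
# raised-cosine bumps (centres 1..11 Hz, width 3 Hz) with fixed weights
# designed so that (a) the amplitude spectrum is broadband over 1-12 Hz
# with its peak near 2 Hz and no support above 12 Hz, and (b) the
# autocorrelation implied by the profile stays below ~0.07 beyond
# 150 ms lag (speech envelopes carry a word/phrase rhythm but no
# dominant periodicity). The weights are a fixed design constant of the
# generator, not a free parameter.
speech_profile_power <- function(freqs) {
  centres <- c(seq(1, 11, by = 1), 2)
  widths <- c(rep(3, 11), 1.6) # broad floor plus a narrow word-rhythm bump
  weights <- c(
    0.8532, 0.2650, 0.6210, 0.7808, 0.6990, 0.6370,
    0.8472, 0.4065, 0.6374, 0.1395, 0.2098, 1.0000
  )
  S <- numeric(length(freqs))
  for (i in seq_along(centres)) {
    sel <- abs(freqs - centres[i]) < widths[i] / 2
    S[sel] <- S[sel] +
      weights[i] * 0.5 * (1 + cos(2 * pi * (freqs[sel] - centres[i]) / widths[i]))
  }
  S[freqs > 12] <- 0
  S
}

#' Generate a speech-like envelope with a known spectral profile
#'
#' Draws a Gaussian process by assigning random phases to a fixed smooth
#' amplitude profile with support limited to 0-12 Hz. The profile
#' emulates the statistics of natural speech envelopes: a broadband
#' 1-12 Hz spectrum peaking near the ~2 Hz phrase/word rhythm, and
#' autocorrelation that decays within roughly +-150 ms (no dominant
#' periodicity). The series is shifted by its minimum so the result is
#' a nonnegative raw envelope.
#'
#' @param duration_s Duration in seconds (>= 4).
#' @param rate Sampling rate in Hz (default 100).
#' @param seed Integer seed; identical seeds give identical envelopes.
#' @return A raw [envelope()].
#' @export
gen_speech_like_envelope <- function(duration_s, rate = 100, seed = 1) {
  assert_scalar_num(duration_s, "duration_s", positive = TRUE)
  if (duration_s < 4) stop_envtacs("duration_s must be at least 4 s")
  assert_scalar_num(rate, "rate", positive = TRUE)
  n <- as.integer(round(duration_s * rate))
  freqs <- seq_len(n %/% 2) * rate / n # positive-frequency bins
  amp <- sqrt(speech_profile_power(freqs))

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  phases <- stats::runif(length(freqs), 0, 2 * pi)
  spec <- complex(modulus = 0, argument = 0, length.out = n)
  spec[2:(length(freqs) + 1)] <- amp * exp(1i * phases)
  # hermitian completion for a real series
  spec[n:(n - length(freqs) + if (n %% 2 == 0) 2 else 1)] <-
    Conj(spec[2:(length(freqs) + if (n %% 2 == 0) 0 else 1)])
  if (n %% 2 == 0) spec[n %/% 2 + 1] <- 0 # inside the zeroed band anyway
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x <- x / stats::sd(x)
  envelope(x - min(x), rate, is_raw = TRUE)
}

#' Generate a full 16-condition SRT dataset with known ground truth
#'
#' Simulates one SRT record per subject and condition. Each subject
#' carries a Normal baseline offset; each condition adds its programmed
#' effect (the multiperiodic phase curve for envelope tACS, constants
#' for the controls). In `direct` mode a Normal residual is added to
#' the programmed value; in `staircase` mode a virtual listener with
#' that true threshold is run through the full closed-loop adaptive
#' procedure and the staircase estimate is recorded. One RNG stream is
#' derived per (subject, condition) from the top-level seed, so
#' enlarging the cohort never perturbs existing records.
#'
#' @param truth A [ground_truth()].
#' @param seed Integer seed.
#' @param mode `"direct"` or `"staircase"`.
#' @param params [staircase_params()] used in staircase mode.
#' @return A tibble of class `srt_dataset` with columns `subject`,
#'   `kind`, `phase_deg`, `latency_ms`, `srt_db` (16 rows per subject)
#'   and attributes `truth`, `seed`, `mode`; in staircase mode also a
#'   `traces` attribute (list of `staircase_trace` keyed by
#'   "subject.condition").
#' @export
gen_dataset <- function(truth = ground_truth(), seed = 1,
                        mode = c("direct", "staircase"),
                        params = staircase_params()) {
  stopifnot(inherits(truth, "envt_truth"))
  mode <- match.arg(mode)
  conds <- stim_conditions()
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))

  set.seed(child_seed(seed, 0))
  b_s <- stats::rnorm(truth$n_subjects, 0, truth$subject_sd_db)

  rows <- vector("list", truth$n_subjects * nrow(conds))
  traces <- list()
  i <- 0L
  for (s in seq_len(truth$n_subjects)) {
    for (ci in seq_len(nrow(conds))) {
      i <- i + 1L
      kind <- conds$kind[ci]
      delta <- condition_effect(truth, kind, conds$phase_deg[ci], conds$latency_ms[ci])
      true_srt <- truth$baseline_db + b_s[s] + delta
      set.seed(child_seed(seed, s, ci))
      if (mode == "direct") {
        srt_val <- true_srt + stats::rnorm(1, 0, truth$residual_sd_db)
      } else {
        listener <- psychometric_listener(true_srt, slope_db = truth$slope_db)
        tr <- run_staircase(listener, params)
        srt_val <- attr(tr, "srt_db")
        traces[[sprintf("s%02d.c%02d", s, ci)]] <- tr
      }
      rows[[i]] <- tibble::tibble(
        subject = sprintf("S%02d", s), kind = kind,
        phase_deg = conds$phase_deg[ci], latency_ms = conds$latency_ms[ci],
        srt_db = srt_val
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "truth") <- truth
  attr(out, "seed") <- seed
  attr(out, "mode") <- mode
  if (mode == "staircase") attr(out, "traces") <- traces
  class(out) <- c("srt_dataset", class(out))
  out
}

#' Virtual cohort whose phase effects come from a linear-response model
#'
#' Draws a random susceptibility kernel, computes the exact
#' [linear_response_srt()] phase curve of a speech-like envelope under
#' it, and packages the result as a [ground_truth()] whose envelope-tACS
#' effects are that curve (purely sinusoidal by construction, so the
#' downstream linearity classifier must not report `nonlinear`).
#'
#' @param seed Integer seed for the kernel and envelope.
#' @param kernel_length_s Kernel support in seconds (default 0.5).
#' @param gain_db Scale of the phase modulation in dB (default 1).
#' @param env Optional [envelope()] driving the response (default: a
#'   seeded 20 s speech-like envelope).
#' @param ... Passed to [ground_truth()] (noise levels etc.).
#' @return A list with `chi` (the kernel), `env`, `truth` (the induced
#'   [ground_truth()]) and `srt_curve` (tibble phase_deg/srt_rel_db).
#' @export
gen_linear_listener <- function(seed = 1, kernel_length_s = 0.5, gain_db = 1,
                                env = NULL, ...) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  if (is.null(env)) env <- gen_speech_like_envelope(20, rate = 100, seed = child_seed(seed, 1))
  set.seed(child_seed(seed, 2))
  chi <- stats::rnorm(as.integer(round(kernel_length_s * env$rate)))
  phases <- seq(0, 300, by = 60)
  raw <- vapply(phases, function(p) linear_response_srt(chi, env, p), numeric(1))
  scale <- if (max(abs(raw)) > 0) gain_db / max(abs(raw)) else 0
  curve <- raw * scale
  # express the (exactly sinusoidal) curve as a multiperiodic truth
  fit <- dct_fit(phases, curve)
  truth <- ground_truth(
    a_100 = c(fit$A[1], 0, 0), psi_100 = c(fit$psi_deg[1], 0, 0), a0_100 = fit$A0,
    a_250 = c(fit$A[1], 0, 0), psi_250 = c(fit$psi_deg[1], 0, 0), a0_250 = fit$A0,
    ...
  )
  list(
    chi = chi, env = env, truth = truth,
    srt_curve = tibble::tibble(phase_deg = phases, srt_rel_db = curve)
  )
}

#' Write / read an SRT dataset as CSV
#'
#' The on-disk schema is `subject,kind,phase_deg,latency_ms,srt_db`.
#'
#' @param data An `srt_dataset` (or compatible data frame).
#' @param path File path.
#' @return `write_srt_csv` the path invisibly; `read_srt_csv` a tibble
#'   of class `srt_dataset`.
#' @export
write_srt_csv <- function(data, path) {
  cols <- c("subject", "kind", "phase_deg", "latency_ms", "srt_db")
  utils::write.csv(as.data.frame(data)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_srt_csv
#' @export
read_srt_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "kind", "phase_deg", "latency_ms", "srt_db")
  if (!all(need %in% names(df))) {
    stop_envtacs(sprintf(
      "malformed dataset: missing column(s) %s",
      paste(setdiff(need, names(df)), collapse = ", ")
    ))
  }
  out <- tibble::as_tibble(df[, need])
  class(out) <- c("srt_dataset", class(out))
  out
}
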