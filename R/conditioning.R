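#' Condition an envelope into a safe stimulation current
#'
#' Applies the safety conditioning used for envelope-shaped transcranial
#' currents: the mean is subtracted so the waveform alternates around
#' zero, the first and last `ramp_ms` are multiplied by half-sine ramps
#' (rising 0 to 1 and falling 1 to 0) so the current starts and ends at
#' exactly 0 mA, and the result is rescaled so the largest absolute
#' sample equals `max_abs_mA`.
#'
#' A constant input has nothing left after mean subtraction: the result
#' is an all-zero waveform and a warning is raised rather than dividing
#' by zero during the rescale.
#'
#' @param env An [envelope()].
#' @param max_abs_mA Peak absolute current in mA.
#' @param ramp_ms Duration of each onset/offset ramp in milliseconds
#'   (default 250); the two ramps must fit inside the signal.
#' @return An object of class `envt_stimwave` with fields `samples`
#'   (current in mA), `rate` and `max_abs_mA`.
#' @export
condition_current <- function(env, max_abs_mA, ramp_ms = 250) {
  stopifnot(inherits(env, "envt_envelope"))
  assert_scalar_num(max_abs_mA, "max_abs_mA", positive = TRUE)
  assert_scalar_num(ramp_ms, "ramp_ms", positive = TRUE)
  n <- length(env$samples)
  n_ramp <- as.integer(round(ramp_ms / 1000 * env$rate))
  if (2 * n_ramp >= n) {
    stop_envtacs("2 * ramp_ms must be shorter than the signal duration")
  }
  x <- env$samples - mean(env$samples)
  x <- apply_half_sine_taper(x, n_ramp)
  peak <- max(abs(x))
  if (peak < 1e-12) {
    warning("constant input: conditioned current is identically zero", call. = FALSE)
    x <- numeric(n)
  } else {
    x <- x * (max_abs_mA / peak)
  }
  x[1] <- 0
  x[n] <- 0
  new_stimwave(x, env$rate, max_abs_mA)
}

new_stimwave <- function(samples, rate, max_abs_mA) {
  structure(
    list(samples = samples, rate = rate, max_abs_mA = max_abs_mA),
    class = c("envt_stimwave", "envt_waveform")
  )
}

apply_half_sine_taper <- function(x, n_ramp) {
  n <- length(x)
  if (n_ramp >= 2) {
    up <- sin(pi / 2 * (seq_len(n_ramp) - 1) / (n_ramp - 1))
    x[seq_len(n_ramp)] <- x[seq_len(n_ramp)] * up
    x[n - seq_len(n_ramp) + 1] <- x[n - seq_len(n_ramp) + 1] * up
  } else {
    x[1] <- 0
    x[n] <- 0
  }
  x
}

#' Enumerate the 16 stimulation conditions
#'
#' The condition battery comprises four controls (sham burst, anodal and
#' cathodal direct current, unrelated-sentence envelope) and twelve
#' envelope-tACS conditions: six phase shifts (0 to 300 degrees in steps
#' of 60) crossed with two latencies (100 and 250 ms).
#'
#' @return A 16-row tibble with columns `kind`, `phase_deg`, `latency_ms`
#'   (phase and latency are `NA` for the controls).
#' @examples
#' stim_conditions()
#' @export
stim_conditions <- function() {
  controls <- tibble::tibble(
    kind = c("sham", "dc_plus", "dc_minus", "unrelated_env"),
    phase_deg = NA_real_,
    latency_ms = NA_real_
  )
  tacs <- tidyr::expand_grid(
    kind = "env_tacs",
    latency_ms = c(100, 250),
    phase_deg = seq(0, 300, by = 60)
  )
  dplyr::bind_rows(controls, tacs[, c("kind", "phase_deg", "latency_ms")])
}

#' Build the stimulation current for one experimental condition
#'
#' Dispatches on the condition kind:
#' * `env_tacs`: phase-shift the target envelope, delay it by the
#'   latency, then condition it into a current;
#' * `unrelated_env`: condition the unrelated envelope (no shift/delay);
#' * `dc_plus` / `dc_minus`: a constant plateau at the positive/negative
#'   current limit with half-sine onset and offset ramps;
#' * `sham`: a tapered burst built from the first 500 ms of the target
#'   envelope (100 ms ramps), zero for the rest of the stimulus.
#'
#' @param target_env Raw [envelope()] of the target speech.
#' @param cond A one-row data frame as returned by [stim_conditions()],
#'   or a list with fields `kind`, `phase_deg`, `latency_ms`.
#' @param max_abs_mA Peak absolute current in mA.
#' @param unrelated_env Raw [envelope()] of an unrelated sentence;
#'   required for `kind = "unrelated_env"`.
#' @param ramp_ms Onset/offset ramp duration in ms (default 250).
#' @param sham_ms Duration of the sham burst in ms (default 500).
#' @return An `envt_stimwave` of the same length as `target_env`.
#' @export
make_condition_current <- function(target_env, cond, max_abs_mA,
                                   unrelated_env = NULL, ramp_ms = 250,
                                   sham_ms = 500) {
  stopifnot(inherits(target_env, "envt_envelope"))
  kind <- as.character(cond$kind)
  rate <- target_env$rate
  n <- length(target_env$samples)
  switch(kind,
    env_tacs = {
      shifted <- phase_shift_envelope(target_env, cond$phase_deg)
      delayed <- delay_envelope(shifted, cond$latency_ms)
      condition_current(delayed, max_abs_mA, ramp_ms = ramp_ms)
    },
    unrelated_env = {
      if (is.null(unrelated_env)) {
        stop_envtacs("unrelated_env condition requires an `unrelated_env` envelope")
      }
      condition_current(unrelated_env, max_abs_mA, ramp_ms = ramp_ms)
    },
    dc_plus = dc_current(n, rate, max_abs_mA, ramp_ms, sign = +1),
    dc_minus = dc_current(n, rate, max_abs_mA, ramp_ms, sign = -1),
    sham = {
      n_burst <- as.integer(round(sham_ms / 1000 * rate))
      if (n_burst > n) stop_envtacs("stimulus shorter than the sham burst")
      seg <- envelope(target_env$samples[seq_len(n_burst)], rate,
        is_raw = isTRUE(target_env$is_raw)
      )
      burst <- condition_current(seg, max_abs_mA, ramp_ms = 100)
      new_stimwave(c(burst$samples, numeric(n - n_burst)), rate, max_abs_mA)
    },
    stop_envtacs(sprintf("unknown condition kind '%s'", kind))
  )
}

dc_current <- function(n, rate, max_abs_mA, ramp_ms, sign) {
  n_ramp <- as.integer(round(ramp_ms / 1000 * rate))
  if (2 * n_ramp >= n) stop_envtacs("2 * ramp_ms must be shorter than the signal")
  x <- apply_half_sine_taper(rep(sign * max_abs_mA, n), n_ramp)
  x[1] <- 0
  x[n] <- 0
  new_stimwave(x, rate, max_abs_mA)
}

#' Export a current waveform as CSV
#'
#' Writes a two-column CSV (`time_s,current_mA`) for inspection or
#' downstream playback.
#'
#' @param wave An `envt_stimwave` (or any waveform).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_current_csv <- function(wave, path) {
  stopifnot(inherits(wave, "envt_waveform"))
  df <- as_tibble(wave)
  names(df) <- c("time_s", "current_mA")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
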