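#' Parameters of the adaptive up-down staircase
#'
#' Defaults follow the standard speech-in-noise protocol: start at
#' 10 dB SNR, step 3 dB until four reversals have occurred, then 1 dB;
#' about 25 sentences per run; the threshold is the mean SNR of the last
#' 10 presentations. A sentence counts as passed when at least half of
#' its key words are repeated correctly.
#'
#' @param initial_snr_db Starting SNR in dB.
#' @param big_step_db Step size (dB) before `reversals_before_small`
#'   reversals have been logged.
#' @param small_step_db Step size (dB) afterwards.
#' @param reversals_before_small Number of reversals tracked at the big
#'   step.
#' @param n_trials Number of sentence presentations.
#' @param n_tail Number of trailing presentations averaged into the
#'   threshold.
#' @param pass_fraction Fraction of key words needed to count a sentence
#'   as passed.
#' @param n_keywords Key words per sentence.
#' @return A list of class `staircase_params`.
#' @export
staircase_params <- function(initial_snr_db = 10, big_step_db = 3,
                             small_step_db = 1, reversals_before_small = 4,
                             n_trials = 25, n_tail = 10,
                             pass_fraction = 0.5, n_keywords = 5) {
  if (big_step_db <= 0 || small_step_db <= 0) stop_envtacs("step sizes must be > 0")
  if (n_tail > n_trials) stop_envtacs("n_tail must not exceed n_trials")
  if (pass_fraction <= 0 || pass_fraction >= 1) stop_envtacs("pass_fraction must be in (0, 1)")
  structure(
    list(
      initial_snr_db = initial_snr_db, big_step_db = big_step_db,
      small_step_db = small_step_db,
      reversals_before_small = reversals_before_small,
      n_trials = as.integer(n_trials), n_tail = as.integer(n_tail),
      pass_fraction = pass_fraction, n_keywords = as.integer(n_keywords)
    ),
    class = "staircase_params"
  )
}

#' Simulated listener with a logistic psychometric function
#'
#' Each key word is reported correctly with probability
#' `(1 - lapse) * plogis((snr - srt_true_db) / slope_db)`, so at
#' `snr = srt_true_db` (and no lapses) half the key words are correct.
#' `slope_db = 0` gives a deterministic step listener (all-correct above
#' threshold, none below, coin-flip keywords exactly at it), handy for
#' convergence checks.
#'
#' @param srt_true_db True threshold (dB SNR) where the per-keyword
#'   probability is 0.5.
#' @param slope_db Spread of the logistic in dB (`>= 0`).
#' @param lapse Probability of failing a keyword regardless of SNR
#'   (`0 <= lapse < 0.5`).
#' @return A list of class `psychometric_listener`.
#' @export
psychometric_listener <- function(srt_true_db, slope_db = 1, lapse = 0) {
  assert_scalar_num(srt_true_db, "srt_true_db")
  if (!is.numeric(slope_db) || slope_db < 0) stop_envtacs("slope_db must be >= 0")
  if (lapse < 0 || lapse >= 0.5) stop_envtacs("lapse must be in [0, 0.5)")
  structure(
    list(srt_true_db = srt_true_db, slope_db = slope_db, lapse = lapse),
    class = "psychometric_listener"
  )
}

keyword_prob <- function(listener, snr_db) {
  p <- if (listener$slope_db == 0) {
    ifelse(snr_db > listener$srt_true_db, 1,
      ifelse(snr_db < listener$srt_true_db, 0, 0.5)
    )
  } else {
    stats::plogis((snr_db - listener$srt_true_db) / listener$slope_db)
  }
  (1 - listener$lapse) * p
}

#' Sentence-level pass rule from keyword counts
#'
#' A sentence passes when the fraction of correctly repeated key words
#' reaches `pass_fraction`; a pass lowers the SNR for the next sentence,
#' a fail raises it.
#'
#' @param n_correct Correct key words.
#' @param n_keywords Total key words (> 0).
#' @param pass_fraction Required fraction (default 0.5).
#' @return Logical.
#' @export
keyword_pass <- function(n_correct, n_keywords, pass_fraction = 0.5) {
  if (any(n_keywords <= 0)) stop_envtacs("n_keywords must be > 0")
  if (any(n_correct < 0) || any(n_correct > n_keywords)) {
    stop_envtacs("n_correct must be between 0 and n_keywords")
  }
  n_correct / n_keywords >= pass_fraction
}

#' One step of the up-down rule
#'
#' The step is `big_step_db` while fewer than `reversals_before_small`
#' reversals have been logged before the current trial, and
#' `small_step_db` afterwards; a pass moves the SNR down, a fail up.
#'
#' @param current_snr Current SNR (dB).
#' @param passed Logical outcome of the current sentence.
#' @param n_reversals_so_far Reversals logged before the current trial.
#' @param params A [staircase_params()].
#' @return Next SNR in dB.
#' @export
staircase_update <- function(current_snr, passed, n_reversals_so_far,
                             params = staircase_params()) {
  step <- if (n_reversals_so_far < params$reversals_before_small) {
    params$big_step_db
  } else {
    params$small_step_db
  }
  if (passed) current_snr - step else current_snr + step
}

#' Simulate one sentence presentation
#'
#' Draws the number of correctly repeated key words from a binomial with
#' the listener's psychometric per-keyword probability at the presented
#' SNR. Uses the current R random stream.
#'
#' @param listener A [psychometric_listener()].
#' @param snr_db Presented SNR (dB).
#' @param n_keywords Key words in the sentence.
#' @param pass_fraction Sentence pass rule (default 0.5).
#' @return A one-row tibble with `snr_db`, `n_keywords`, `n_correct`,
#'   `passed`.
#' @export
simulate_trial <- function(listener, snr_db, n_keywords = 5,
                           pass_fraction = 0.5) {
  stopifnot(inherits(listener, "psychometric_listener"))
  p <- keyword_prob(listener, snr_db)
  n_correct <- stats::rbinom(1, n_keywords, p)
  tibble::tibble(
    snr_db = snr_db, n_keywords = n_keywords, n_correct = n_correct,
    passed = keyword_pass(n_correct, n_keywords, pass_fraction)
  )
}

#' Run a closed-loop adaptive staircase against a simulated listener
#'
#' Presents exactly `n_trials` sentences, adapting the SNR with
#' [staircase_update()]. A trial is flagged as a reversal when the
#' direction of the SNR change it triggers differs from the previous
#' change; the first trial cannot be a reversal. The sentence reception
#' threshold is the mean presented SNR of the last `n_tail` trials.
#'
#' @param listener A [psychometric_listener()].
#' @param params A [staircase_params()].
#' @param seed Optional integer seed; when given, the run is
#'   reproducible and the global random stream is restored afterwards.
#' @return A tibble of class `staircase_trace` with one row per trial
#'   (`trial`, `snr_db`, `n_correct`, `passed`, `is_reversal`) and
#'   attributes `srt_db`, `reversal_indices`, `params`.
#' @export
run_staircase <- function(listener, params = staircase_params(), seed = NULL) {
  stopifnot(inherits(listener, "psychometric_listener"))
  if (!is.null(seed)) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(seed)
  }
  n <- params$n_trials
  snr <- numeric(n)
  n_correct <- integer(n)
  passed <- logical(n)
  is_rev <- logical(n)
  cur <- params$initial_snr_db
  n_rev <- 0L
  last_dir <- 0L
  for (k in seq_len(n)) {
    snr[k] <- cur
    tr <- simulate_trial(listener, cur, params$n_keywords, params$pass_fraction)
    n_correct[k] <- tr$n_correct
    passed[k] <- tr$passed
    dir <- if (passed[k]) -1L else 1L
    if (last_dir != 0L && dir != last_dir) {
      is_rev[k] <- TRUE
      n_rev <- n_rev + 1L
    }
    # step chosen from the reversal count before this trial
    cur <- staircase_update(cur, passed[k], n_rev - is_rev[k], params)
    last_dir <- dir
  }
  srt <- mean(snr[(n - params$n_tail + 1):n])
  out <- tibble::tibble(
    trial = seq_len(n), snr_db = snr, n_correct = n_correct,
    passed = passed, is_reversal = is_rev
  )
  attr(out, "srt_db") <- srt
  attr(out, "reversal_indices") <- which(is_rev)
  attr(out, "params") <- params
  class(out) <- c("staircase_trace", class(out))
  out
}

#' Threshold estimate of a staircase trace
#'
#' @param trace A `staircase_trace`.
#' @return The SRT in dB (mean presented SNR of the tail trials).
#' @export
srt <- function(trace) {
  stopifnot(inherits(trace, "staircase_trace"))
  attr(trace, "srt_db")
}
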