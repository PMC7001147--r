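#' Fold a phase onto a shorter period
#'
#' Maps `phase` to `(360 / period) * phase mod 360`, so a test for
#' variation at period `period` (360 divided by an integer) becomes a
#' uniform-versus-concentrated test on the full circle.
#'
#' @param phase_deg Phase(s) in degrees.
#' @param period_deg Period in degrees; must divide 360.
#' @return Folded phase(s) in `[0, 360)`.
#' @examples
#' fold_to_period(60, 120) # 180
#' @export
fold_to_period <- function(phase_deg, period_deg) {
  assert_scalar_num(period_deg, "period_deg", positive = TRUE)
  k <- 360 / period_deg
  if (abs(k - round(k)) > 1e-9) {
    stop_envtacs("period_deg must be a divisor of 360")
  }
  wrap_deg(round(k) * phase_deg)
}

#' Representable periods of an equally spaced phase grid
#'
#' With `n_phases` equally spaced phases, variation can be resolved at
#' the periods `360 / k` for `k = 1, ..., n_phases / 2`: six phases give
#' 360, 180 and 120 degrees, with 120 the smallest resolvable period.
#'
#' @param n_phases Number of equally spaced sample phases (even).
#' @return Numeric vector of periods in degrees, decreasing.
#' @export
representable_periods <- function(n_phases = 6) {
  if (n_phases < 2 || n_phases %% 2 != 0) {
    stop_envtacs("n_phases must be an even number >= 2")
  }
  360 / seq_len(n_phases / 2)
}

mr_statistic <- function(angles_rad, ranks) {
  n <- length(ranks)
  Mod(sum(ranks * exp(1i * angles_rad))) / n^1.5
}

#' Moore-Rayleigh test for weighted circular data
#'
#' Rank-weighted modification of the Rayleigh test: the weights are
#' replaced by their ranks (mid-ranks on ties, with a warning when all
#' weights tie), each observation contributes a vector of length equal
#' to its rank in its angular direction, and the test statistic is
#' `R* = |sum r_i exp(i theta_i)| / n^(3/2)`. The p-value is Monte
#' Carlo: under the default null (`"uniform"`, Moore's original) angles
#' are redrawn uniformly on the circle with the ranks fixed; under
#' `"permutation"` the ranks are shuffled against the observed angles.
#' Both use the add-one correction `(1 + #{null >= observed}) / (n_mc + 1)`.
#'
#' @param angles_deg Angles in degrees.
#' @param weights Nonnegative weights (e.g. SRT minus the minimal
#'   overall SRT).
#' @param n_mc Number of Monte-Carlo draws (default 10000).
#' @param seed Integer seed.
#' @param null `"uniform"` (default) or `"permutation"`.
#' @return A one-row tibble of class `envt_circ_test` with `statistic`,
#'   `p_value`, `n`, `n_mc`, `null`.
#' @export
moore_rayleigh_test <- function(angles_deg, weights, n_mc = 10000, seed = 1,
                                null = c("uniform", "permutation")) {
  null <- match.arg(null)
  n <- length(angles_deg)
  if (length(weights) != n) stop_envtacs("angles and weights must have equal length")
  if (n < 4) stop_envtacs("need at least 4 observations")
  if (any(weights < 0)) stop_envtacs("weights must be nonnegative")
  if (length(unique(weights)) == 1L) {
    warning("all weights equal: mid-ranks used, test reduces to angle balance", call. = FALSE)
  }
  ranks <- rank(weights) # mid-ranks on ties
  th <- deg2rad(wrap_deg(angles_deg))
  obs <- mr_statistic(th, ranks)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  if (null == "uniform") {
    # vectorized: rows = draws; statistic = |t(exp(i theta)) %*% ranks|
    phis <- matrix(stats::runif(n_mc * n, 0, 2 * pi), nrow = n_mc)
    sims <- Mod(cos(phis) %*% ranks + 1i * (sin(phis) %*% ranks)) / n^1.5
  } else {
    u <- exp(1i * th)
    perm <- vapply(seq_len(n_mc), function(i) sample.int(n), integer(n))
    rm_ <- matrix(ranks[perm], nrow = n)
    sims <- Mod(crossprod(rm_, Re(u)) + 1i * crossprod(rm_, Im(u))) / n^1.5
  }
  p <- (1 + sum(sims >= obs)) / (n_mc + 1)
  out <- tibble::tibble(
    statistic = obs, p_value = p, n = n, n_mc = n_mc, null = null
  )
  class(out) <- c("envt_circ_test", class(out))
  out
}

#' Rayleigh test of circular uniformity
#'
#' Classical Rayleigh test on the mean resultant length, with the
#' standard finite-sample correction of the p-value
#' (`p = exp(sqrt(1 + 4n + 4(n^2 - R^2)) - (1 + 2n))`).
#'
#' @param angles_deg Angles in degrees (n >= 4).
#' @return A list with `r_bar` (mean resultant length), `z` (`n r_bar^2`)
#'   and `p_value`.
#' @export
rayleigh_test <- function(angles_deg) {
  n <- length(angles_deg)
  if (n < 4) stop_envtacs("need at least 4 angles")
  th <- deg2rad(angles_deg)
  R <- Mod(sum(exp(1i * th)))
  r_bar <- R / n
  z <- n * r_bar^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
  list(r_bar = r_bar, z = z, p_value = min(1, p))
}

#' Benjamini-Hochberg and Benjamini-Hochberg-Yekutieli adjustments
#'
#' Thin wrappers over [stats::p.adjust()]: `bh_adjust()` is the step-up
#' false-discovery-rate procedure for independent or positively
#' dependent tests, `bhy_adjust()` its conservative variant that
#' inflates by the harmonic sum `c(m) = sum(1/i)` and is valid under
#' arbitrary dependence.
#'
#' @param pvals Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length, capped at 1.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1)) stop_envtacs("p-values must be in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' @rdname bh_adjust
#' @export
bhy_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1)) stop_envtacs("p-values must be in [0, 1]")
  stats::p.adjust(pvals, method = "BY")
}

#' Moore-Rayleigh tests of a phase profile at the three grid periods
#'
#' Pools all (subject, phase) observations, subtracts the minimal value
#' so weights are nonnegative, folds the phases onto each representable
#' period (360, 180, 120 degrees) and applies [moore_rayleigh_test()] at
#' each, adjusting the three p-values with [bh_adjust()].
#'
#' @param phases_deg Phase of each observation (degrees).
#' @param values SRT (or SRT difference) of each observation, any units.
#' @param periods_deg Periods to test (default `c(360, 180, 120)`).
#' @param n_mc,seed,null Passed to [moore_rayleigh_test()].
#' @return A tibble with one row per period: `period_deg`, `statistic`,
#'   `p_raw`, `p_adjusted`, `n`, `n_mc`.
#' @export
phase_profile_tests <- function(phases_deg, values,
                                periods_deg = c(360, 180, 120),
                                n_mc = 10000, seed = 1,
                                null = "uniform") {
  if (length(phases_deg) != length(values)) {
    stop_envtacs("phases and values must have equal length")
  }
  w <- values - min(values)
  rows <- purrr::map(periods_deg, function(p) {
    res <- moore_rayleigh_test(
      fold_to_period(phases_deg, p), w,
      n_mc = n_mc, seed = child_seed(seed, round(p)), null = null
    )
    tibble::tibble(
      period_deg = p, statistic = res$statistic, p_raw = res$p_value,
      n = res$n, n_mc = n_mc
    )
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- bh_adjust(out$p_raw)
  out[, c("period_deg", "statistic", "p_raw", "p_adjusted", "n", "n_mc")]
}

#' Test whether the phase profile differs between the two latencies
#'
#' Forms, for each subject and phase, the difference between the SRT at
#' the long and at the short latency, subtracts the minimum so weights
#' are nonnegative, and subjects the differences to Moore-Rayleigh tests
#' at the periods 360, 180 and 120 degrees with Benjamini-Hochberg
#' adjustment across the three periods.
#'
#' @param srt_short,srt_long Data frames with columns `subject`,
#'   `phase_deg`, `srt_db`, one row per subject and phase, covering the
#'   same subjects and phases.
#' @param n_mc,seed,null Passed to [moore_rayleigh_test()].
#' @return A 3-row tibble as in [phase_profile_tests()].
#' @export
latency_difference_test <- function(srt_short, srt_long, n_mc = 10000,
                                    seed = 1, null = "uniform") {
  key <- c("subject", "phase_deg")
  a <- tibble::as_tibble(srt_short[, c(key, "srt_db")])
  b <- tibble::as_tibble(srt_long[, c(key, "srt_db")])
  a <- a[order(a$subject, a$phase_deg), ]
  b <- b[order(b$subject, b$phase_deg), ]
  if (nrow(a) != nrow(b) ||
    !identical(a$subject, b$subject) ||
    !identical(a$phase_deg, b$phase_deg)) {
    stop_envtacs("the two latencies must cover matching subjects and phases")
  }
  diff <- b$srt_db - a$srt_db
  phase_profile_tests(a$phase_deg, diff, n_mc = n_mc, seed = seed, null = null)
}
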