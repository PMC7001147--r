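#' Run configuration for a simulated experiment
#'
#' A flat, JSON-serializable description that fully determines one run:
#' the seed, the generator truth, staircase parameters, and analysis
#' options.
#'
#' @param seed Integer seed.
#' @param truth A [ground_truth()].
#' @param mode `"direct"` or `"staircase"`.
#' @param params [staircase_params()] (staircase mode).
#' @param alpha Significance level.
#' @param n_mc Monte-Carlo draws for the circular tests.
#' @param folds Cross-validation folds for the LASSO.
#' @return A list of class `envt_config`.
#' @export
run_config <- function(seed = 1, truth = ground_truth(),
                       mode = c("direct", "staircase"),
                       params = staircase_params(),
                       alpha = 0.05, n_mc = 10000, folds = 10) {
  mode <- match.arg(mode)
  structure(
    list(
      seed = as.integer(seed), truth = truth, mode = mode, params = params,
      alpha = alpha, n_mc = as.integer(n_mc), folds = as.integer(folds)
    ),
    class = "envt_config"
  )
}

#' Simulate a full experiment from a configuration
#'
#' Thin wrapper over [gen_dataset()]: same config in, same dataset out,
#' byte for byte.
#'
#' @param config An [run_config()].
#' @return An `srt_dataset`.
#' @export
run_experiment <- function(config = run_config()) {
  stopifnot(inherits(config, "envt_config"))
  gen_dataset(config$truth, seed = config$seed, mode = config$mode,
    params = config$params)
}

#' Paired comparisons of every condition against sham
#'
#' For each of the fifteen non-sham conditions: the paired mean SRT
#' difference versus sham across subjects, the paired t statistic and
#' its two-sided p-value, adjusted with the Benjamini-Hochberg-Yekutieli
#' procedure over the fifteen comparisons. Degenerate zero-variance
#' differences are handled at the boundary (p = 0 for a nonzero shift,
#' p = 1 for identical data).
#'
#' @param data An `srt_dataset` (all 16 conditions, sham present for
#'   every subject).
#' @return A 15-row tibble: `kind`, `phase_deg`, `latency_ms`,
#'   `mean_diff_db`, `t`, `df`, `p_raw`, `p_adjusted`.
#' @export
compare_to_sham <- function(data) {
  data <- tibble::as_tibble(data)
  sham <- data[data$kind == "sham", c("subject", "srt_db")]
  if (nrow(sham) == 0) stop_envtacs("no sham condition in the dataset")
  names(sham)[2] <- "sham_db"
  others <- data[data$kind != "sham", ]
  keys <- unique(others[, c("kind", "phase_deg", "latency_ms")])
  rows <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sel <- others$kind == keys$kind[i] &
      (is.na(keys$phase_deg[i]) | others$phase_deg %in% keys$phase_deg[i]) &
      (is.na(keys$latency_ms[i]) | others$latency_ms %in% keys$latency_ms[i])
    cond <- others[sel, c("subject", "srt_db")]
    m <- merge(cond, sham, by = "subject")
    if (nrow(m) < nrow(sham)) stop_envtacs("sham missing for some subjects")
    d <- m$srt_db - m$sham_db
    n <- length(d)
    sd_d <- stats::sd(d)
    if (sd_d < 1e-12) {
      tval <- if (abs(mean(d)) < 1e-12) 0 else sign(mean(d)) * Inf
      p <- if (abs(mean(d)) < 1e-12) 1 else 0
    } else {
      tt <- stats::t.test(m$srt_db, m$sham_db, paired = TRUE)
      tval <- unname(tt$statistic)
      p <- tt$p.value
    }
    rows[[i]] <- tibble::tibble(
      kind = keys$kind[i], phase_deg = keys$phase_deg[i],
      latency_ms = keys$latency_ms[i],
      mean_diff_db = mean(d), t = tval, df = n - 1, p_raw = p
    )
  }
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- bhy_adjust(out$p_raw)
  out
}

#' Full statistical analysis of a 16-condition SRT dataset
#'
#' Runs the complete analysis plan on a dataset (synthetic or supplied):
#' \enumerate{
#'   \item sham-normalize per subject (each subject's sham SRT is
#'     subtracted from all of their records, so the mean sham level is
#'     exactly 0 dB);
#'   \item Moore-Rayleigh tests of the phase profiles per latency at the
#'     periods 360/180/120 degrees, BH-adjusted within latency;
#'   \item the latency-difference test at the same periods;
#'   \item per latency: the multiperiodic DCT fit of the pooled mean
#'     profile, LASSO/LARS selection with covariance-test inference,
#'     the linearity classification, and the extrema of the
#'     significant-terms fit;
#'   \item best-phase alignment per subject with a Rayleigh uniformity
#'     test and an aligned refit;
#'   \item the fifteen paired comparisons against sham (BHY-adjusted).
#' }
#'
#' The result is a pure function of `(data, config)`.
#'
#' @param data An `srt_dataset`.
#' @param config An [run_config()]; its `alpha`, `n_mc`, `folds`, `seed`
#'   drive the analysis.
#' @return A list of class `analysis_report`; see the fields in the
#'   return value (`moore_rayleigh`, `latency_difference`, `fits`,
#'   `best_phase`, `sham_comparison`, `normalized`).
#' @export
analyze <- function(data, config = run_config()) {
  data <- validate_dataset(data)
  alpha <- config$alpha
  normalized <- sham_normalize(data)
  tacs <- normalized[normalized$kind == "env_tacs", ]

  mr <- dplyr::bind_rows(lapply(c(100, 250), function(lat) {
    d <- tacs[tacs$latency_ms == lat, ]
    res <- phase_profile_tests(d$phase_deg, d$srt_db,
      n_mc = config$n_mc, seed = child_seed(config$seed, 10, lat)
    )
    res$latency_ms <- lat
    res
  }))
  mr <- mr[, c("latency_ms", setdiff(names(mr), "latency_ms"))]

  ld <- latency_difference_test(
    tacs[tacs$latency_ms == 100, ],
    tacs[tacs$latency_ms == 250, ],
    n_mc = config$n_mc, seed = child_seed(config$seed, 11)
  )

  fits <- lapply(c(100, 250), function(lat) {
    d <- tacs[tacs$latency_ms == lat, ]
    pooled <- stats::aggregate(srt_db ~ phase_deg, data = d, FUN = mean)
    dct <- dct_fit(pooled$phase_deg, pooled$srt_db)
    sel <- lasso_select(d,
      folds = config$folds, seed = child_seed(config$seed, 12, lat),
      alpha = alpha
    )
    list(
      latency_ms = lat, dct = dct, selection = sel,
      linearity = classify_linearity(sel, alpha),
      extrema = extrema(sel$fit_significant),
      mean_profile = tibble::as_tibble(pooled)
    )
  })
  names(fits) <- c("lat100", "lat250")

  best <- lapply(c(100, 250), function(lat) {
    d <- tacs[tacs$latency_ms == lat, ]
    best_phase_align(d, seed = child_seed(config$seed, 13, lat), alpha = alpha)
  })
  names(best) <- c("lat100", "lat250")

  sham_cmp <- compare_to_sham(data)

  structure(
    list(
      moore_rayleigh = mr, latency_difference = ld, fits = fits,
      best_phase = best, sham_comparison = sham_cmp,
      normalized = normalized, alpha = alpha,
      config = list(
        seed = config$seed, n_mc = config$n_mc, folds = config$folds
      )
    ),
    class = "analysis_report"
  )
}

validate_dataset <- function(data) {
  data <- tibble::as_tibble(data)
  need <- c("subject", "kind", "phase_deg", "latency_ms", "srt_db")
  if (!all(need %in% names(data))) {
    stop_envtacs(sprintf(
      "malformed dataset: missing column(s) %s",
      paste(setdiff(need, names(data)), collapse = ", ")
    ))
  }
  bad <- which(!is.finite(data$srt_db))
  if (length(bad) > 0) {
    stop_envtacs(sprintf(
      "malformed dataset: non-finite srt_db in row(s) %s",
      paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  counts <- table(data$subject)
  if (any(counts != 16)) {
    off <- names(counts)[counts != 16]
    stop_envtacs(sprintf(
      "each subject needs exactly 16 condition records; offending subject(s): %s",
      paste(utils::head(off, 5), collapse = ", ")
    ))
  }
  data
}

#' Sham-normalize a dataset per subject
#'
#' Subtracts each subject's sham SRT from all of that subject's records;
#' sham rows become exactly 0 dB.
#'
#' @param data An `srt_dataset`.
#' @return The normalized tibble.
#' @export
sham_normalize <- function(data) {
  data <- tibble::as_tibble(data)
  sham <- data[data$kind == "sham", c("subject", "srt_db")]
  if (nrow(sham) == 0) stop_envtacs("no sham condition in the dataset")
  names(sham)[2] <- "sham_db"
  out <- dplyr::left_join(data, sham, by = "subject")
  out$srt_db <- out$srt_db - out$sham_db
  out$sham_db <- NULL
  out
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Envelope-tACS analysis report\n")
  cat("=============================\n\n")
  cat("Moore-Rayleigh tests (per latency, BH-adjusted over 3 periods):\n")
  print(as.data.frame(x$moore_rayleigh), digits = 3)
  cat("\nLatency-difference test:\n")
  print(as.data.frame(x$latency_difference), digits = 3)
  for (f in x$fits) {
    cat(sprintf(
      "\nLatency %d ms: linearity = %s; fitted minimum %.0f deg (%.2f dB), maximum %.0f deg (%.2f dB)\n",
      f$latency_ms, f$linearity, f$extrema$phi_min, f$extrema$srt_min,
      f$extrema$phi_max, f$extrema$srt_max
    ))
    print(as.data.frame(f$selection$amplitudes), digits = 3)
  }
  for (lat in c("lat100", "lat250")) {
    b <- x$best_phase[[lat]]
    cat(sprintf(
      "\nBest-phase distribution (%s): Rayleigh p = %.4g\n",
      sub("lat", "", lat), b$rayleigh$p_value
    ))
  }
  cat("\nPaired comparisons vs sham (BHY-adjusted, m = 15):\n")
  print(as.data.frame(x$sham_comparison), digits = 3)
  invisible(x)
}

#' Serialize / restore an analysis report as JSON
#'
#' Writes the tabular content of an [analyze()] report to JSON and reads
#' it back; data frames round-trip losslessly up to double precision.
#'
#' @param report An `analysis_report`.
#' @param path File path.
#' @return `write_report` the path invisibly; `read_report` a list with
#'   the same tabular fields.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "analysis_report"))
  ser_fit <- function(f) {
    list(
      latency_ms = f$latency_ms,
      dct = list(A0 = f$dct$A0, A = f$dct$A, psi_deg = f$dct$psi_deg),
      amplitudes = f$selection$amplitudes,
      terms = f$selection$terms,
      lambda_cv = f$selection$lambda_cv,
      linearity = f$linearity,
      extrema = f$extrema,
      mean_profile = f$mean_profile
    )
  }
  obj <- list(
    moore_rayleigh = report$moore_rayleigh,
    latency_difference = report$latency_difference,
    fits = lapply(report$fits, ser_fit),
    best_phase = lapply(report$best_phase, function(b) {
      list(
        best_phases = b$best_phases,
        rayleigh_p = b$rayleigh$p_value,
        refit_amplitudes = b$refit$amplitudes
      )
    }),
    sham_comparison = report$sham_comparison,
    alpha = report$alpha,
    config = report$config
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
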