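#' Multiperiodic (discrete cosine) fit of an SRT-versus-phase profile
#'
#' Decomposes a profile sampled at the six equally spaced phases
#' 0, 60, ..., 300 degrees into
#' `SRT(phi) = A0 + A1 cos(phi - psi1) + A2 cos(2 phi - psi2) +
#' A3 cos(3 phi - psi3)`,
#' the three periods (360, 180, 120 degrees) resolvable on the grid.
#' `A0` is the profile mean. For `k = 1, 2` the cosine/sine projections
#' give `A_k` and `psi_k`; at the alias limit `k = 3` the sine component
#' vanishes identically on the grid (`sin(3 phi_j) = 0`), so only the
#' magnitude and sign of the cosine projection are estimable and `psi3`
#' is restricted to 0 or 180 degrees. The reconstruction is exact at the
#' six sample phases (the transform is a bijection there).
#'
#' @param phases_deg The sampled phases; must be `0, 60, ..., 300` in
#'   some order.
#' @param srt_db Profile value at each phase (dB).
#' @return An object of class `multiperiodic_fit`: a list with fields
#'   `A0`, `A` (A1..A3), `psi_deg` (psi1..psi3).
#' @examples
#' phi <- seq(0, 300, by = 60)
#' fit <- dct_fit(phi, 2 * cos(deg2rad_(phi - 30)))
#' fit$A # ~ c(2, 0, 0)
#' @export
dct_fit <- function(phases_deg, srt_db) {
  grid <- seq(0, 300, by = 60)
  if (length(phases_deg) != 6L || length(srt_db) != 6L ||
    !isTRUE(all.equal(sort(wrap_deg(phases_deg)), grid, tolerance = 1e-9))) {
    stop_envtacs("dct_fit needs the 6 equally spaced phases 0, 60, ..., 300 degrees")
  }
  ord <- order(wrap_deg(phases_deg))
  phi <- deg2rad(grid)
  y <- srt_db[ord]
  A0 <- mean(y)
  A <- numeric(3)
  psi <- numeric(3)
  for (k in 1:2) {
    Ck <- sum(y * cos(k * phi)) / 3
    Sk <- sum(y * sin(k * phi)) / 3
    A[k] <- sqrt(Ck^2 + Sk^2)
    psi[k] <- if (A[k] > 0) wrap_deg(rad2deg(atan2(Sk, Ck))) else 0
  }
  c3 <- sum(y * cos(3 * phi)) / 6
  A[3] <- abs(c3)
  psi[3] <- if (c3 >= 0) 0 else 180
  new_multiperiodic_fit(A0, A, psi)
}

new_multiperiodic_fit <- function(A0, A, psi_deg) {
  structure(
    list(A0 = A0, A = A, psi_deg = psi_deg),
    class = "multiperiodic_fit"
  )
}

#' @export
print.multiperiodic_fit <- function(x, ...) {
  cat("Multiperiodic fit: SRT(phi) = A0 + sum_k Ak cos(k phi - psi_k)\n")
  cat(sprintf("  A0 = %.3f dB\n", x$A0))
  for (k in 1:3) {
    cat(sprintf(
      "  A%d = %.3f dB at psi%d = %.1f deg (period %d deg)\n",
      k, x$A[k], k, x$psi_deg[k], 360 %/% k
    ))
  }
  invisible(x)
}

# exported convenience used in examples
#' Degrees-to-radians helper
#' @param x Angle in degrees.
#' @return Angle in radians.
#' @export
deg2rad_ <- function(x) deg2rad(x)

#' Evaluate a multiperiodic fit at arbitrary phases
#'
#' @param fit A `multiperiodic_fit`.
#' @param phi_deg Phase(s) in degrees.
#' @return Reconstructed value(s) in dB.
#' @export
reconstruct <- function(fit, phi_deg) {
  stopifnot(inherits(fit, "multiperiodic_fit"))
  phi <- deg2rad(phi_deg)
  out <- rep(fit$A0, length(phi))
  for (k in 1:3) {
    out <- out + fit$A[k] * cos(k * phi - deg2rad(fit$psi_deg[k]))
  }
  out
}

#' Extrema of a multiperiodic fit
#'
#' Grid search of the reconstruction over `[0, 360)` degrees.
#'
#' @param fit A `multiperiodic_fit`.
#' @param grid_deg Grid resolution in degrees (default 1; must divide 360).
#' @return A list with `phi_min`, `srt_min`, `phi_max`, `srt_max`.
#' @export
extrema <- function(fit, grid_deg = 1) {
  stopifnot(inherits(fit, "multiperiodic_fit"))
  if (abs(360 / grid_deg - round(360 / grid_deg)) > 1e-9) {
    stop_envtacs("grid_deg must divide 360")
  }
  phi <- seq(0, 360 - grid_deg, by = grid_deg)
  v <- reconstruct(fit, phi)
  list(
    phi_min = phi[which.min(v)], srt_min = min(v),
    phi_max = phi[which.max(v)], srt_max = max(v)
  )
}

trig_design <- function(phases_deg) {
  phi <- deg2rad(phases_deg)
  # sin(3 phi) vanishes identically on 60-degree grids and is excluded
  cbind(
    cos1 = cos(phi), sin1 = sin(phi),
    cos2 = cos(2 * phi), sin2 = sin(2 * phi),
    cos3 = cos(3 * phi)
  )
}

term_amplitude <- c(cos1 = 1L, sin1 = 1L, cos2 = 2L, sin2 = 2L, cos3 = 3L)

# within-subject centering (projects out unpenalized subject intercepts)
center_within <- function(M, subject) {
  M <- as.matrix(M)
  for (s in unique(subject)) {
    i <- subject == s
    M[i, ] <- sweep(M[i, , drop = FALSE], 2, colMeans(M[i, , drop = FALSE]))
  }
  M
}

#' LASSO/LARS selection of multiperiodic components with covariance-test
#' inference
#'
#' Stacks all subjects' SRT-versus-phase observations at one latency and
#' regresses them on the five-column trigonometric design
#' `{cos phi, sin phi, cos 2phi, sin 2phi, cos 3phi}` (the `sin 3phi`
#' column is identically zero on 60-degree grids). Subject intercepts
#' are unpenalized (projected out), the LASSO path is computed with the
#' LARS algorithm, the penalty is chosen by subject-stratified k-fold
#' cross-validation, and each variable's entry along the path is scored
#' with the covariance-test statistic.
#'
#' Entry p-values come from a Monte-Carlo null (default): the statistic
#' at the r-th entry of a global-null draw on the same design, with the
#' effective rank `r` discounted by the number of earlier entries already
#' declared significant, so the first noise entry after genuine signals
#' is still compared against a first-entry null. `null = "exp1"` gives
#' the classical Exp(1) reference instead. Amplitude-level p-values
#' combine each cos/sin pair's smaller entry p with a Sidak correction
#' for the pair size (the `cos 3phi` term stands alone).
#'
#' @param profiles Data frame with columns `subject`, `phase_deg`,
#'   `srt_db` (one latency; at least 2 subjects on a common phase grid).
#' @param folds Cross-validation folds (default 10).
#' @param seed Integer seed controlling fold assignment and the
#'   Monte-Carlo null.
#' @param alpha Significance level used for the sequential rank
#'   discounting and the `significant` flags (default 0.05).
#' @param null `"mc"` (default) or `"exp1"`.
#' @param n_null Monte-Carlo null draws (default 2000).
#' @return An object of class `envt_selection`: list with `terms`
#'   (per-column entry order, knot, statistic, entry p), `amplitudes`
#'   (per-period CV-selected flag, amplitude and p-value),
#'   `fit_significant` (a [dct_fit()]-style `multiperiodic_fit` refit by
#'   least squares on the significant terms), `cv` (fraction grid and
#'   error curve), `lambda_cv`, `sigma2`, `n`, `alpha`.
#' @export
lasso_select <- function(profiles, folds = 10, seed = 1, alpha = 0.05,
                         null = c("mc", "exp1"), n_null = 2000) {
  null <- match.arg(null)
  profiles <- tibble::as_tibble(profiles)
  need <- c("subject", "phase_deg", "srt_db")
  if (!all(need %in% names(profiles))) {
    stop_envtacs("profiles needs columns subject, phase_deg, srt_db")
  }
  subjects <- unique(profiles$subject)
  if (length(subjects) < 2) stop_envtacs("need at least 2 subjects")
  n <- nrow(profiles)
  X_raw <- trig_design(profiles$phase_deg)
  if (n <= ncol(X_raw) + length(subjects)) {
    stop_envtacs("fewer observations than model degrees of freedom")
  }
  y_c <- drop(center_within(matrix(profiles$srt_db), profiles$subject))
  X_c <- center_within(X_raw, profiles$subject)
  norms <- sqrt(colSums(X_c^2))
  if (any(norms < 1e-10)) stop_envtacs("degenerate design: constant column after centering")
  X_s <- sweep(X_c, 2, norms, "/")

  # error variance from the full least-squares fit (subject intercepts
  # already projected out; rank-aware for the aligned 5-phase design,
  # where the trigonometric columns are collinear with the intercepts)
  qrx <- qr(X_c)
  rss <- sum(stats::resid(stats::lm.fit(X_c, y_c))^2)
  df <- n - length(subjects) - qrx$rank
  sigma2 <- max(rss / df, 1e-12 * mean(profiles$srt_db^2) + 1e-300)

  path <- lars_path(X_s, y_c)

  # ---- cross-validation over the path fraction, stratified by subject
  old_seed <- get0(".Random.seed", envir = globalenv())
  if (!is.null(old_seed)) on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(child_seed(seed, 1))
  folds <- min(folds, length(subjects))
  fold_of <- sample(rep_len(seq_len(folds), length(subjects)))
  names(fold_of) <- as.character(subjects)
  fracs <- seq(0, 1, length.out = 101)
  cv_err <- matrix(NA_real_, nrow = folds, ncol = length(fracs))
  for (f in seq_len(folds)) {
    test_sub <- subjects[fold_of[as.character(subjects)] == f]
    tr <- !(profiles$subject %in% test_sub)
    if (all(tr) || !any(tr)) next
    ytr <- drop(center_within(matrix(profiles$srt_db[tr]), profiles$subject[tr]))
    Xtr <- center_within(X_raw[tr, , drop = FALSE], profiles$subject[tr])
    ntr <- sqrt(colSums(Xtr^2))
    pth <- lars_path(sweep(Xtr, 2, ntr, "/"), ytr)
    lmax <- lambda_max(pth)
    yte <- drop(center_within(matrix(profiles$srt_db[!tr]), profiles$subject[!tr]))
    Xte <- center_within(X_raw[!tr, , drop = FALSE], profiles$subject[!tr])
    Xte <- sweep(Xte, 2, ntr, "/")
    for (i in seq_along(fracs)) {
      b <- lars_solution(pth, fracs[i] * lmax)
      cv_err[f, i] <- mean((yte - Xte %*% b)^2)
    }
  }
  cv_mean <- colMeans(cv_err, na.rm = TRUE)
  frac_hat <- fracs[which.min(cv_mean)]
  lambda_cv <- frac_hat * lambda_max(path)
  beta_cv_s <- lars_solution(path, lambda_cv)
  beta_cv <- beta_cv_s / norms # back to the unscaled design

  # ---- covariance tests along the path
  ct <- covariance_tests(path, sigma2)
  terms <- tibble::tibble(
    term = colnames(X_raw)[ct$var],
    entry_order = ct$entry_order,
    lambda = ct$lambda,
    statistic = pmax(ct$statistic, 0)
  )
  if (null == "mc") {
    null_tab <- mc_null_table(X_s, n_draws = n_null, seed = child_seed(seed, 2))
    p_entry <- numeric(nrow(terms))
    n_signif_before <- 0L
    for (i in seq_len(nrow(terms))) {
      r <- i - n_signif_before
      p_entry[i] <- mc_null_p(null_tab, r, terms$statistic[i])
      if (p_entry[i] < alpha) n_signif_before <- n_signif_before + 1L
    }
  } else {
    p_entry <- exp(-terms$statistic)
  }
  terms$p_entry <- p_entry

  # ---- amplitude-level summaries
  amp_rows <- lapply(1:3, function(k) {
    cols <- names(term_amplitude)[term_amplitude == k]
    cols <- intersect(cols, colnames(X_raw))
    m <- length(cols)
    p_cols <- terms$p_entry[match(cols, terms$term)]
    p_min <- if (all(is.na(p_cols))) 1 else min(p_cols, na.rm = TRUE)
    p_amp <- 1 - (1 - p_min)^m
    idx <- match(cols, colnames(X_raw))
    ck <- unname(beta_cv[idx[1]])
    sk <- if (m > 1) unname(beta_cv[idx[2]]) else 0
    tibble::tibble(
      k = k, period_deg = 360 / k,
      amplitude_cv = sqrt(ck^2 + sk^2),
      selected_cv = any(abs(beta_cv_s[idx]) > 1e-12),
      p_value = min(1, p_amp)
    )
  })
  amplitudes <- dplyr::bind_rows(amp_rows)
  amplitudes$significant <- amplitudes$p_value < alpha

  # ---- least-squares refit on the significant terms only
  sig_cols <- which(term_amplitude[colnames(X_raw)] %in% amplitudes$k[amplitudes$significant])
  A <- numeric(3)
  psi <- numeric(3)
  if (length(sig_cols) > 0) {
    b_sig <- stats::lm.fit(X_c[, sig_cols, drop = FALSE], y_c)$coefficients
    b_sig[is.na(b_sig)] <- 0
    coefs <- stats::setNames(numeric(ncol(X_raw)), colnames(X_raw))
    coefs[sig_cols] <- b_sig
    for (k in 1:2) {
      ck <- coefs[paste0("cos", k)]
      sk <- coefs[paste0("sin", k)]
      A[k] <- sqrt(ck^2 + sk^2)
      psi[k] <- if (A[k] > 0) wrap_deg(rad2deg(atan2(sk, ck))) else 0
    }
    A[3] <- abs(coefs["cos3"])
    psi[3] <- if (coefs["cos3"] >= 0) 0 else 180
  }
  fit_sig <- new_multiperiodic_fit(mean(profiles$srt_db), A, psi)

  structure(
    list(
      terms = terms, amplitudes = amplitudes, fit_significant = fit_sig,
      beta_cv = stats::setNames(beta_cv, colnames(X_raw)),
      lambda_cv = lambda_cv, frac_cv = frac_hat,
      cv = tibble::tibble(fraction = fracs, cv_mse = cv_mean),
      sigma2 = sigma2, n = n, n_subjects = length(subjects),
      alpha = alpha, null = null, seed = seed
    ),
    class = "envt_selection"
  )
}

#' @export
print.envt_selection <- function(x, ...) {
  cat(sprintf(
    "LASSO/LARS selection: n = %d (%d subjects), CV fraction %.2f, sigma^2 = %.3g\n",
    x$n, x$n_subjects, x$frac_cv, x$sigma2
  ))
  print(x$amplitudes)
  invisible(x)
}

#' Classify the phase response as linear, nonlinear or absent
#'
#' Under linear-response theory the dependence of the threshold on the
#' stimulation phase must be a pure 360-degree sinusoid; any significant
#' 180- or 120-degree component evidences a nonlinearity.
#'
#' @param selection An `envt_selection` from [lasso_select()].
#' @param alpha Significance level (default: the one used in the fit).
#' @return `"nonlinear"`, `"linear"` or `"no_modulation"`.
#' @export
classify_linearity <- function(selection, alpha = NULL) {
  stopifnot(inherits(selection, "envt_selection"))
  alpha <- alpha %||% selection$alpha
  sig <- selection$amplitudes$p_value < alpha
  if (any(sig[selection$amplitudes$k %in% c(2, 3)])) {
    "nonlinear"
  } else if (sig[selection$amplitudes$k == 1]) {
    "linear"
  } else {
    "no_modulation"
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Threshold predicted by a linear-response model
#'
#' Computes `SRT(phi) = dt * sum_t chi(t_b - t) y_phi(t)` over the
#' stimulus window `[t_a, t_b]`: a discrete linear functional of the
#' phase-shifted envelope with susceptibility kernel `chi`. Because the
#' phase-shifted envelope is `cos(phi) y0 - sin(phi) H[y0]`, any such
#' functional is exactly sinusoidal in `phi` (a pure 360-degree
#' component), which is what makes higher harmonics a nonlinearity
#' signature.
#'
#' @param chi Numeric susceptibility kernel sampled at the envelope rate;
#'   recycled/truncated to the window length (aligned to the window end).
#' @param env An [envelope()].
#' @param phi_deg Stimulation phase in degrees.
#' @param window_s Length-2 vector `c(t_a, t_b)` in seconds (default the
#'   full envelope support).
#' @return The predicted threshold (arbitrary units, scales with `chi`).
#' @export
linear_response_srt <- function(chi, env, phi_deg, window_s = NULL) {
  stopifnot(inherits(env, "envt_envelope"))
  n <- length(env$samples)
  rate <- env$rate
  if (is.null(window_s)) window_s <- c(0, (n - 1) / rate)
  if (length(window_s) != 2 || window_s[1] >= window_s[2]) {
    stop_envtacs("window_s must be c(t_a, t_b) with t_a < t_b")
  }
  i0 <- as.integer(round(window_s[1] * rate)) + 1L
  i1 <- as.integer(round(window_s[2] * rate)) + 1L
  if (i0 < 1L || i1 > n) stop_envtacs("window outside the envelope support")
  yphi <- phase_shift_envelope(env, phi_deg)$samples[i0:i1]
  m <- length(yphi)
  chi <- as.numeric(chi)
  if (!all(is.finite(chi))) stop_envtacs("kernel must be finite")
  # kern[j] = chi(t_b - t'_j): zero-pad chi to the window length, reverse
  kern <- rev(rep_len(c(chi, numeric(m)), m))
  sum(kern * yphi) / rate
}

#' Align each subject's profile to its best phase and refit
#'
#' Determines, per subject, the phase with the lowest SRT (ties broken
#' toward the smallest phase), relabels phases so that this best phase
#' becomes 0 degrees, drops the (by construction minimal) 0-degree
#' observation to avoid selection bias, and reruns [lasso_select()] on
#' the remaining five points per subject. The per-subject best phases
#' are returned together with a [rayleigh_test()] of their uniformity.
#'
#' @param profiles Data frame with `subject`, `phase_deg`, `srt_db`
#'   (one 6-point profile per subject).
#' @param seed,alpha,... Passed to [lasso_select()].
#' @return A list with `best_phases` (tibble subject/best_phase_deg),
#'   `rayleigh` (test of the best-phase distribution), `aligned`
#'   (relabeled profiles without the 0-degree point), `refit`
#'   (`envt_selection` on the aligned data).
#' @export
best_phase_align <- function(profiles, seed = 1, alpha = 0.05, ...) {
  profiles <- tibble::as_tibble(profiles)
  best <- profiles |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(
      best_phase_deg = .data$phase_deg[order(.data$srt_db, .data$phase_deg)][1],
      .groups = "drop"
    )
  aligned <- profiles |>
    dplyr::left_join(best, by = "subject") |>
    dplyr::mutate(phase_deg = wrap_deg(.data$phase_deg - .data$best_phase_deg)) |>
    dplyr::filter(.data$phase_deg != 0) |>
    dplyr::select("subject", "phase_deg", "srt_db")
  refit <- lasso_select(aligned, seed = seed, alpha = alpha, ...)
  ray <- if (nrow(best) >= 4) {
    rayleigh_test(best$best_phase_deg)
  } else {
    list(r_bar = NA_real_, z = NA_real_, p_value = NA_real_)
  }
  list(
    best_phases = best,
    rayleigh = ray,
    aligned = aligned,
    refit = refit
  )
}
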