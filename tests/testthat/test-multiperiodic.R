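test_that("the 6-point DCT fit recovers programmed components exactly", {
  # constant profile: only the mean survives
  f0 <- dct_fit(phase_grid, rep(3.5, 6))
  expect_equal(f0$A0, 3.5)
  expect_equal(f0$A, rep(0, 3))

  # a pure 360-degree cosine with known amplitude and offset
  f1 <- dct_fit(phase_grid, 2 * cos(deg2rad_(phase_grid - 30)))
  expect_equal(f1$A[1], 2, tolerance = 1e-12)
  expect_equal(f1$psi_deg[1], 30, tolerance = 1e-9)
  expect_lt(f1$A[2], 1e-12)
  expect_lt(f1$A[3], 1e-12)

  # alias-limit term: sign goes into psi3
  f3 <- dct_fit(phase_grid, -1.2 * cos(3 * deg2rad_(phase_grid)))
  expect_equal(f3$A[3], 1.2, tolerance = 1e-12)
  expect_equal(f3$psi_deg[3], 180)

  expect_error(dct_fit(c(0, 45, 90, 135, 180, 225), rnorm(6)), "equally spaced")
  expect_error(dct_fit(phase_grid[-1], rnorm(5)), "equally spaced")
})

test_that("DCT fit and reconstruction are inverse bijections with Parseval", {
  set.seed(3)
  for (i in 1:20) {
    y <- rnorm(6, sd = 2)
    f <- dct_fit(phase_grid, y)
    expect_equal(reconstruct(f, phase_grid), y, tolerance = 1e-12)
    # population variance splits over the three periods
    expect_equal(
      mean((y - mean(y))^2),
      (f$A[1]^2 + f$A[2]^2) / 2 + f$A[3]^2,
      tolerance = 1e-10
    )
  }
  # evaluation conventions
  fa <- new_multiperiodic_fit(1.5, c(0, 0, 0), c(0, 0, 0))
  expect_equal(reconstruct(fa, c(0, 123, 270)), rep(1.5, 3))
  fb <- new_multiperiodic_fit(1, c(2, 0, 0), c(40, 0, 0))
  expect_equal(reconstruct(fb, 40), 3)
})

test_that("extrema locate cosine extremes on the search grid", {
  f <- new_multiperiodic_fit(0, c(1, 0, 0), c(30, 0, 0))
  e <- extrema(f)
  expect_equal(e$phi_max, 30)
  expect_equal(e$phi_min, 210)

  # pure 120-degree term: two further minima 120 degrees apart
  f3 <- new_multiperiodic_fit(0, c(0, 0, 1), c(0, 0, 0))
  v <- reconstruct(f3, 0:359)
  mins <- sort(which(abs(v - min(v)) < 1e-9) - 1)
  expect_equal(diff(mins), c(120, 120))

  # 1-degree grid agrees with a brute-force fine grid within resolution
  set.seed(4)
  y <- rnorm(6)
  fit <- dct_fit(phase_grid, y)
  e1 <- extrema(fit, grid_deg = 1)
  fine <- seq(0, 360 - 0.01, by = 0.01)
  vf <- reconstruct(fit, fine)
  expect_lte(min(abs(c(
    fine[which.min(vf)] - e1$phi_min,
    fine[which.min(vf)] - e1$phi_min + 360,
    fine[which.min(vf)] - e1$phi_min - 360
  ))), 1)
  expect_equal(e1$srt_min, min(vf), tolerance = 1e-3)
  expect_error(extrema(fit, grid_deg = 7), "divide")
})

test_that("lasso selection recovers strong components and matches glmnet", {
  skip_if_not_installed("glmnet")
  truth <- ground_truth(residual_sd_db = 0.3)
  d <- tacs_slice(gen_dataset(truth, seed = 2, mode = "direct"), 250)
  sel <- lasso_select(d, seed = 2, n_null = 500)
  expect_true(all(sel$amplitudes$selected_cv))
  expect_true(all(sel$amplitudes$significant))
  expect_equal(sel$amplitudes$amplitude_cv, truth$a_250, tolerance = 0.35)

  # independent check of the lasso solution at the chosen penalty:
  # glmnet on the identically preprocessed design must agree
  X <- trig_design(d$phase_deg)
  Xc <- X
  yc <- d$srt_db
  for (s in unique(d$subject)) {
    i <- d$subject == s
    Xc[i, ] <- sweep(Xc[i, , drop = FALSE], 2, colMeans(Xc[i, , drop = FALSE]))
    yc[i] <- yc[i] - mean(yc[i])
  }
  norms <- sqrt(colSums(Xc^2))
  Xs <- sweep(Xc, 2, norms, "/")
  g <- glmnet::glmnet(Xs, yc,
    lambda = sel$lambda_cv / nrow(Xs), intercept = FALSE,
    standardize = FALSE, thresh = 1e-14
  )
  expect_equal(unname(sel$beta_cv * norms), as.numeric(g$beta), tolerance = 1e-6)

  expect_error(lasso_select(d[d$subject == "S01", ]), "2 subjects")
  expect_error(lasso_select(d[, c("subject", "srt_db")]), "columns")
})

test_that("linearity classification follows the significant periods", {
  # strong pure-360 truth -> linear
  lin <- ground_truth(
    a_100 = c(1.5, 0, 0), a_250 = c(1.5, 0, 0), psi_250 = c(40, 0, 0),
    residual_sd_db = 0.3
  )
  d <- tacs_slice(gen_dataset(lin, seed = 5, mode = "direct"), 250)
  expect_equal(classify_linearity(lasso_select(d, seed = 5, n_null = 500)), "linear")

  # strong 120-degree component -> nonlinear
  nl <- ground_truth(a_250 = c(0, 0, 1.2), psi_250 = c(0, 0, 0), residual_sd_db = 0.3)
  d2 <- tacs_slice(gen_dataset(nl, seed = 6, mode = "direct"), 250)
  expect_equal(classify_linearity(lasso_select(d2, seed = 6, n_null = 500)), "nonlinear")

  # no programmed modulation, quiet noise -> no_modulation (fixed seed)
  none <- ground_truth(
    a_100 = c(0, 0, 0), a_250 = c(0, 0, 0), a0_100 = 0, a0_250 = 0,
    residual_sd_db = 0.3
  )
  d3 <- tacs_slice(gen_dataset(none, seed = 8, mode = "direct"), 250)
  expect_equal(classify_linearity(lasso_select(d3, seed = 8, n_null = 500)), "no_modulation")
})

test_that("linear-response thresholds are exactly sinusoidal in phase", {
  env <- gen_speech_like_envelope(10, 100, seed = 9)
  # zero kernel: zero response at every phase
  expect_equal(
    vapply(phase_grid, function(p) linear_response_srt(0, env, p), numeric(1)),
    rep(0, 6)
  )

  # impulse kernel on an integer-period cosine: closed-form check
  rate <- 100
  t <- seq(0, 10 - 1 / rate, by = 1 / rate)
  ce <- envelope(1 + cos(2 * pi * 2 * t), rate)
  got <- vapply(phase_grid, function(p) linear_response_srt(1, ce, p), numeric(1))
  fit <- dct_fit(phase_grid, got)
  expect_equal(fit$A[1], 1 / rate, tolerance = 1e-9)
  expect_lt(fit$A[2] / fit$A[1], 1e-9)
  expect_lt(fit$A[3] / fit$A[1], 1e-9)

  # random kernels on random envelopes: higher harmonics vanish
  for (s in 1:5) {
    set.seed(s)
    chi <- rnorm(40)
    envs <- gen_speech_like_envelope(8, 100, seed = 100 + s)
    srts <- vapply(phase_grid, function(p) linear_response_srt(chi, envs, p), numeric(1))
    f <- dct_fit(phase_grid, srts)
    expect_lt(f$A[2] / f$A[1], 1e-9)
    expect_lt(f$A[3] / f$A[1], 1e-9)
  }
  expect_error(linear_response_srt(1, env, 0, window_s = c(0, 99)), "window")
})

test_that("best-phase alignment relabels minima to zero and tests uniformity", {
  # all subjects minimal at 60 degrees
  subs <- sprintf("S%02d", 1:17)
  prof <- tidyr::expand_grid(subject = subs, phase_deg = phase_grid)
  set.seed(11)
  prof$srt_db <- 1 - 2 * (prof$phase_deg == 60) + rnorm(nrow(prof), 0, 0.1)
  out <- best_phase_align(prof, seed = 1, n_null = 300)
  expect_true(all(out$best_phases$best_phase_deg == 60))
  expect_lt(out$rayleigh$p_value, 0.01)

  # the dropped 0-degree point was each subject's minimum
  for (s in subs) {
    orig_min <- min(prof$srt_db[prof$subject == s])
    expect_true(all(out$aligned$srt_db[out$aligned$subject == s] >= orig_min))
  }
  expect_equal(sort(unique(out$aligned$phase_deg)), phase_grid[-1])
  expect_equal(nrow(out$aligned), 17 * 5)
  expect_s3_class(out$refit$amplitudes, "tbl_df")

  # ties break toward the smallest phase
  tied <- tidyr::expand_grid(subject = c("a", "b", "c"), phase_deg = phase_grid)
  tied$srt_db <- rep(c(0, 0, 1, 1, 1, 1), 3)
  bt <- best_phase_align(tied, seed = 1, n_null = 100)
  expect_true(all(bt$best_phases$best_phase_deg == 0))
})

test_that("ground-truth amplitudes are recovered with small bias at 0.5 dB noise", {
  truth <- ground_truth() # residual sd 0.5 dB
  est <- matrix(NA, 100, 3)
  for (r in 1:100) {
    d <- tacs_slice(gen_dataset(truth, seed = 400 + r, mode = "direct"), 250)
    pooled <- stats::aggregate(srt_db ~ phase_deg, data = d, FUN = mean)
    est[r, ] <- dct_fit(pooled$phase_deg, pooled$srt_db)$A
  }
  bias <- colMeans(est) - truth$a_250
  expect_true(all(abs(bias) < 0.1 * truth$a_250))
})

test_that("tidy and glance summarise fits and selections", {
  f <- dct_fit(phase_grid, 2 * cos(deg2rad_(phase_grid - 30)) + 1)
  td <- tidy(f)
  expect_equal(td$amplitude_db[1], 1)
  expect_equal(td$amplitude_db[2], 2, tolerance = 1e-9)
  gl <- glance(f)
  expect_equal(gl$modulation_depth_db, 4, tolerance = 1e-3)
  expect_equal(gl$dominant_period_deg, 360)
})
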