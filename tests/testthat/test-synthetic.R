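test_that("speech-like envelopes are nonnegative, band-limited and deterministic", {
  env <- gen_speech_like_envelope(20, 100, seed = 1)
  expect_gte(min(env$samples), 0)
  expect_true(env$is_raw)
  expect_equal(duration(env), 20)

  env2 <- gen_speech_like_envelope(20, 100, seed = 1)
  expect_identical(env$samples, env2$samples)
  env3 <- gen_speech_like_envelope(20, 100, seed = 2)
  expect_false(identical(env$samples, env3$samples))

  sp <- amplitude_spectrum(gen_speech_like_envelope(60, 100, seed = 7), resolution_hz = 0.5)
  pk <- sp$freq_hz[which.max(sp$amplitude)]
  expect_gte(pk, 1.5)
  expect_lte(pk, 2.5)
  expect_lt(max(sp$amplitude[sp$freq_hz > 13]), 0.01 * max(sp$amplitude))

  expect_error(gen_speech_like_envelope(2, 100, seed = 1), "at least 4")
})

test_that("the generated dataset enumerates the condition battery deterministically", {
  truth <- ground_truth(n_subjects = 5)
  d <- gen_dataset(truth, seed = 3)
  expect_equal(nrow(d), 5 * 16)
  counts <- table(d$subject)
  expect_true(all(counts == 16))
  per_subj <- d[d$subject == "S01", c("kind", "phase_deg", "latency_ms")]
  expect_equal(as.data.frame(per_subj), as.data.frame(stim_conditions()),
    ignore_attr = TRUE
  )

  d2 <- gen_dataset(truth, seed = 3)
  expect_identical(d$srt_db, d2$srt_db)

  # enlarging the cohort preserves the existing subjects' records
  big <- gen_dataset(ground_truth(n_subjects = 7), seed = 3)
  expect_equal(
    big$srt_db[big$subject %in% sprintf("S%02d", 1:5)],
    d$srt_db,
    tolerance = 1e-12
  )
  expect_error(gen_dataset(truth, seed = 1, mode = "nope"), "arg")
})

test_that("noise-free direct mode reproduces the programmed curves exactly", {
  truth <- ground_truth(subject_sd_db = 0, residual_sd_db = 0, n_subjects = 3)
  d <- sham_normalize(gen_dataset(truth, seed = 1, mode = "direct"))
  for (lat in c(100, 250)) {
    a <- if (lat == 100) truth$a_100 else truth$a_250
    psi <- if (lat == 100) truth$psi_100 else truth$psi_250
    a0 <- if (lat == 100) truth$a0_100 else truth$a0_250
    slice <- d[d$kind == "env_tacs" & d$latency_ms == lat & d$subject == "S01", ]
    slice <- slice[order(slice$phase_deg), ]
    expected <- a0 + vapply(slice$phase_deg, function(p) {
      sum(a * cos((1:3) * deg2rad_(p) - deg2rad_(psi)))
    }, numeric(1))
    expect_equal(slice$srt_db, expected, tolerance = 1e-12)
    fit <- dct_fit(slice$phase_deg, slice$srt_db)
    expect_equal(fit$A, a, tolerance = 1e-10)
    expect_equal(fit$A0, a0, tolerance = 1e-12)
  }
  # controls sit at their programmed offsets
  expect_equal(unique(d$srt_db[d$kind == "unrelated_env"]), truth$unrelated_env_penalty_db)
  expect_equal(unique(d$srt_db[d$kind %in% c("dc_plus", "dc_minus")]), 0)
})

test_that("the unrelated-envelope penalty reproduces its programmed 2 dB on average", {
  truth <- ground_truth(residual_sd_db = 0.5)
  diffs <- vapply(1:200, function(r) {
    d <- gen_dataset(truth, seed = 700 + r, mode = "direct")
    mean(d$srt_db[d$kind == "unrelated_env"]) - mean(d$srt_db[d$kind == "sham"])
  }, numeric(1))
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs) - 2), 2 * se + 0.02)
})

test_that("staircase mode agrees with direct mode up to procedure noise", {
  truth <- ground_truth(subject_sd_db = 0.5, residual_sd_db = 0.3, n_subjects = 17)
  dd <- gen_dataset(truth, seed = 5, mode = "direct")
  ds <- gen_dataset(truth, seed = 5, mode = "staircase")
  md <- stats::aggregate(srt_db ~ kind + phase_deg + latency_ms,
    data = dd, FUN = mean, na.action = NULL
  )
  ms <- stats::aggregate(srt_db ~ kind + phase_deg + latency_ms,
    data = ds, FUN = mean, na.action = NULL
  )
  m <- merge(md, ms, by = c("kind", "phase_deg", "latency_ms"))
  expect_true(all(abs(m$srt_db.x - m$srt_db.y) < 0.6))
  expect_length(attr(ds, "traces"), 17 * 16)
  expect_s3_class(attr(ds, "traces")[[1]], "staircase_trace")
})

test_that("linear-response listeners never classify as nonlinear", {
  for (s in c(1, 2, 3)) {
    gl <- gen_linear_listener(seed = s, residual_sd_db = 0.3, subject_sd_db = 1)
    d <- tacs_slice(gen_dataset(gl$truth, seed = 50 + s, mode = "direct"), 250)
    cls <- classify_linearity(lasso_select(d, seed = s, n_null = 500))
    expect_true(cls %in% c("linear", "no_modulation"))
  }
  # the programmed curve is a pure 360-degree sinusoid
  gl <- gen_linear_listener(seed = 4)
  f <- dct_fit(gl$srt_curve$phase_deg, gl$srt_curve$srt_rel_db)
  expect_lt(f$A[2], 1e-9 * max(f$A[1], 1e-12))
  expect_lt(f$A[3], 1e-9 * max(f$A[1], 1e-12))

  # a zero kernel induces no modulation at all
  gl0 <- gen_linear_listener(seed = 5, gain_db = 0)
  expect_true(all(abs(gl0$srt_curve$srt_rel_db) < 1e-12))
})

test_that("ground-truth validation catches bad parameters", {
  expect_error(ground_truth(a_100 = c(-1, 0, 0)), "nonnegative")
  expect_error(ground_truth(psi_250 = c(0, 0, 90)), "psi3")
  expect_error(ground_truth(subject_sd_db = -1), ">= 0")
})

test_that("dataset CSV round-trips through the documented schema", {
  d <- gen_dataset(ground_truth(n_subjects = 3), seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_srt_csv(d, path)
  d2 <- read_srt_csv(path)
  expect_equal(d2$srt_db, d$srt_db)
  expect_equal(d2$kind, d$kind)
  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(a = 1), bad, row.names = FALSE)
  expect_error(read_srt_csv(bad), "missing column")
})
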