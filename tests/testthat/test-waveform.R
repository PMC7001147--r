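test_that("envelope extraction recovers known modulators", {
  rate <- 8000
  t <- seq(0, 2 - 1 / rate, by = 1 / rate)
  interior <- seq(rate %/% 2, length(t) - rate %/% 2)

  # constant-amplitude carrier -> constant unit envelope
  tone <- waveform(sin(2 * pi * 1000 * t), rate)
  env <- extract_envelope(tone)
  expect_true(all(abs(env$samples[interior] - 1) < 1e-2))

  # amplitude-modulated carrier -> envelope tracks the modulator
  mod <- 1 + 0.5 * cos(2 * pi * 4 * t)
  am <- waveform(mod * sin(2 * pi * 1000 * t), rate)
  env2 <- extract_envelope(am)
  expect_gt(cor(env2$samples[interior], mod[interior]), 0.99)

  # all-zero audio -> all-zero envelope
  z <- extract_envelope(waveform(numeric(rate), rate))
  expect_true(all(z$samples == 0))
})

test_that("envelope extraction validates its inputs", {
  expect_error(
    extract_envelope(waveform(rnorm(100), 100), cutoff_hz = 60),
    "Nyquist"
  )
  expect_error(
    extract_envelope(waveform(rnorm(30), 1000), cutoff_hz = 12),
    "need more than"
  )
})

test_that("phase shift rotates sinusoids and inverts at 180 degrees", {
  rate <- 100
  t <- seq(0, 10 - 1 / rate, by = 1 / rate)
  env <- envelope(1 + 0.5 * cos(2 * pi * 4 * t), rate)
  interior <- seq(rate, length(t) - rate)

  # identity at 0 degrees (zero-mean copy)
  p0 <- phase_shift_envelope(env, 0)
  expect_equal(p0$samples, env$samples - mean(env$samples))

  # 180 degrees is negation of the zero-mean envelope
  p180 <- phase_shift_envelope(env, 180)
  expect_equal(p180$samples, -(env$samples - mean(env$samples)), tolerance = 1e-10)

  # 90 degrees advances the cosine by pi/2
  p90 <- phase_shift_envelope(env, 90)
  expect_equal(
    p90$samples[interior],
    0.5 * cos(2 * pi * 4 * t[interior] + pi / 2),
    tolerance = 1e-6
  )
})

test_that("phase-shift composition, wrap-around and spectral magnitude invariants hold", {
  env <- gen_speech_like_envelope(30, 100, seed = 4)
  y0 <- env$samples - mean(env$samples)
  scale <- max(abs(y0))

  for (pair in list(c(50, 70), c(123.4, 321.0), c(200, 200))) {
    a <- phase_shift_envelope(phase_shift_envelope(env, pair[1]), pair[2])
    b <- phase_shift_envelope(env, pair[1] + pair[2])
    expect_lt(max(abs(a$samples - b$samples)) / scale, 1e-9)
  }
  # 360 degrees = identity; 180 twice = identity
  expect_lt(max(abs(phase_shift_envelope(env, 360)$samples - y0)) / scale, 1e-9)
  twice <- phase_shift_envelope(phase_shift_envelope(env, 180), 180)
  expect_lt(max(abs(twice$samples - y0)) / scale, 1e-9)

  # magnitude spectrum preserved at every positive frequency bin
  m0 <- Mod(fft(y0))
  m1 <- Mod(fft(phase_shift_envelope(env, 77)$samples))
  expect_lt(max(abs(m0 - m1)) / max(m0), 1e-9)
})

test_that("delay shifts by whole samples with zero fill", {
  rate <- 100
  env <- gen_speech_like_envelope(10, rate, seed = 1)
  expect_equal(delay_envelope(env, 0), env)

  # impulse moves by round(tau * rate)
  imp <- envelope(c(numeric(49), 1, numeric(450)), rate)
  d <- delay_envelope(imp, 120)
  expect_equal(which(d$samples == 1), 50 + 12)
  expect_true(all(d$samples[1:12] == 0))
  expect_length(d$samples, 500)

  # sinusoid delayed by tau equals phase shift by -360 f tau on the interior
  t <- seq(0, 20 - 1 / rate, by = 1 / rate)
  s <- envelope(1 + cos(2 * pi * 2 * t), rate)
  ds <- delay_envelope(s, 250)
  interior <- seq(2 * rate, length(t) - rate)
  expect_equal(
    ds$samples[interior] - 1,
    cos(2 * pi * 2 * t[interior] - deg2rad_(360 * 2 * 0.25)),
    tolerance = 1e-9
  )

  expect_error(delay_envelope(env, 20000), "exceeds")
  expect_error(delay_envelope(env, -5), ">= 0")
})

test_that("current conditioning enforces zero endpoints, amplitude and zero mean", {
  env <- gen_speech_like_envelope(10, 100, seed = 2)
  w <- condition_current(env, max_abs_mA = 0.9, ramp_ms = 250)
  expect_identical(w$samples[1], 0)
  expect_identical(w$samples[length(w$samples)], 0)
  expect_equal(max(abs(w$samples)), 0.9)

  # the pre-taper signal is exactly mean-subtracted, so the conditioned
  # current integrates to ~0 relative to its scale
  expect_lt(abs(mean(w$samples)) / max(abs(w$samples)), 0.05)

  expect_warning(
    wz <- condition_current(envelope(rep(2, 1000), 100), 1),
    "constant"
  )
  expect_true(all(wz$samples == 0))

  expect_error(condition_current(env, 1, ramp_ms = 6000), "shorter")
})

test_that("the 16-condition battery builds valid currents of every kind", {
  conds <- stim_conditions()
  expect_equal(nrow(conds), 16)
  expect_equal(sum(conds$kind == "env_tacs"), 12)
  expect_setequal(unique(conds$phase_deg[conds$kind == "env_tacs"]), phase_grid)

  env <- gen_speech_like_envelope(8, 100, seed = 5)
  unrel <- gen_speech_like_envelope(8, 100, seed = 6)
  for (i in seq_len(nrow(conds))) {
    w <- make_condition_current(env, conds[i, ], max_abs_mA = 0.9, unrelated_env = unrel)
    expect_identical(w$samples[1], 0)
    expect_identical(w$samples[length(w$samples)], 0)
    expect_lte(max(abs(w$samples)), 0.9 + 1e-12)
  }

  # sham: nonzero only within the first 500 ms
  sham <- make_condition_current(env, list(kind = "sham"), 0.9)
  expect_true(all(sham$samples[(0.5 * 100 + 1):800] == 0))
  expect_gt(max(abs(sham$samples[1:50])), 0)

  # dc plateau at +max between the ramps
  dcp <- make_condition_current(env, list(kind = "dc_plus"), 0.9, ramp_ms = 100)
  expect_true(all(abs(dcp$samples[15:785] - 0.9) < 1e-12))
  dcm <- make_condition_current(env, list(kind = "dc_minus"), 0.9, ramp_ms = 100)
  expect_true(all(abs(dcm$samples[15:785] + 0.9) < 1e-12))

  # env_tacs equals the shift -> delay -> condition composition
  ours <- make_condition_current(
    env, list(kind = "env_tacs", phase_deg = 0, latency_ms = 100), 0.9
  )
  byhand <- condition_current(
    delay_envelope(phase_shift_envelope(env, 0), 100), 0.9
  )
  expect_equal(ours$samples, byhand$samples)

  expect_error(make_condition_current(env, list(kind = "nope"), 1), "unknown")
  expect_error(make_condition_current(env, list(kind = "unrelated_env"), 1), "unrelated_env")
})

test_that("waveform objects validate and export", {
  expect_error(waveform(c(1, NA), 10), "finite")
  expect_error(waveform(1, 10), "2 samples")
  expect_error(envelope(c(-1, 1), 10), "nonnegative")
  expect_error(waveform(1:10, -1), "> 0")

  w <- condition_current(gen_speech_like_envelope(5, 100, seed = 1), 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_current_csv(w, path)
  df <- read.csv(path)
  expect_named(df, c("time_s", "current_mA"))
  expect_equal(df$current_mA, w$samples)
  expect_equal(df$time_s[2], 1 / 100)
})
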