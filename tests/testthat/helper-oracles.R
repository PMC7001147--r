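# shared test utilities and independent oracles

# Best & Fisher (1979) von Mises sampler; independent of any package code
rvonmises <- function(n, mu_deg, kappa) {
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0
  while (i < n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      i <- i + 1
      out[i] <- sign(u[3] - 0.5) * acos(f)
    }
  }
  (mu_deg + out * 180 / pi) %% 360
}

# correlation that tolerates zero-variance edge cases
safe_cor <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) {
    return(NA_real_)
  }
  cor(a, b)
}

# 6-phase grid used throughout
phase_grid <- seq(0, 300, by = 60)

# quick env_tacs profile slice of a dataset at one latency
tacs_slice <- function(data, latency) {
  d <- sham_normalize(data)
  d[d$kind == "env_tacs" & d$latency_ms == latency, ]
}
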