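# Shared oracles, independent of the package's own integrator.

# Exact pooled moments of two merged water bodies (the discrete two-box
# merge): areas a1, a2 with means m, second central moments v.
pool_mean <- function(a1, m1, a2, m2) (a1 * m1 + a2 * m2) / (a1 + a2)

pool_comoment <- function(a1, com1, mi1, mj1, a2, com2, mi2, mj2) {
  # E[x_i x_j] over the union minus product of pooled means
  exx <- (a1 * (com1 + mi1 * mj1) + a2 * (com2 + mi2 * mj2)) / (a1 + a2)
  exx - pool_mean(a1, mi1, a2, mi2) * pool_mean(a1, mj1, a2, mj2)
}

# Minimal RK4 driver for an arbitrary rhs; used where a test needs an
# integration that does not go through the package's engine.
rk4_integrate <- function(y0, rhs, dt, n) {
  y <- y0
  for (i in seq_len(n)) {
    k1 <- rhs(y)
    k2 <- rhs(y + dt / 2 * k1)
    k3 <- rhs(y + dt / 2 * k2)
    k4 <- rhs(y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  y
}

# Correlated bivariate normal sample with exact target first/second
# sample moments not enforced; used for Monte-Carlo closure checks.
rbvn <- function(n, mean_r, mean_b, var_r, var_b, cov_rb) {
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  r <- mean_r + sqrt(var_r) * z1
  rho <- cov_rb / sqrt(var_r * var_b)
  b <- mean_b + sqrt(var_b) * (rho * z1 + sqrt(1 - rho^2) * z2)
  list(r = r, b = b)
}

# A cheap, short default run reused across tests.
short_config <- function(...) {
  sim_config(tau = 5, dt = 0.02, ...)
}
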