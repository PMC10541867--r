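test_that("steady-state resource balances Monod growth against mortality", {
  expect_equal(steady_state_resource(bio_params(nu = 1.05, m = 0.05, k = 2)), 0.1)
  expect_equal(steady_state_resource(bio_params(nu = 0.2, m = 0.1, k = 7)), 7)
  expect_equal(steady_state_resource(bio_params(nu = 1.05, m = 0.05, k = 4)), 0.2)
  expect_error(
    steady_state_resource(bio_params(nu = 0.04, m = 0.05)),
    "no steady state"
  )
})

test_that("with zero second moments the means follow mean-field kinetics", {
  bp <- bio_params()
  for (r in c(0.05, 0.5, 2)) {
    for (b in c(0.01, 0.3)) {
      td <- reaction_tendencies(tracer_moments(r, b), bp)
      G <- bp$nu * r / (r + bp$k)
      expect_equal(td[["mean_r"]], -G * b + bp$alpha * bp$m * b)
      expect_equal(td[["mean_b"]], G * b - bp$m * b)
      expect_equal(td[["var_r"]], 0)
      expect_equal(td[["var_b"]], 0)
      expect_equal(td[["cov_rb"]], 0)
    }
  }
  # at r* the consumer is exactly stationary
  td <- reaction_tendencies(tracer_moments(0.1, 0.7), bp)
  expect_equal(td[["mean_b"]], 0, tolerance = 1e-15)
})

test_that("the covariance closure term shifts mean growth as derived", {
  bp <- bio_params()
  base <- reaction_tendencies(tracer_moments(1, 0.0249), bp)
  # var_r = var_b = 0 but cov_rb != 0 is not a valid moment set
  # (Cauchy-Schwarz), so probe the closure term through its coefficient:
  # d(mean_b)/d(cov) = nu k / (r + k)^2
  vr <- 1e-4
  vb <- 1e-4
  cv <- 1e-4 # admissible: cv^2 = vr*vb
  td <- reaction_tendencies(tracer_moments(1, 0.0249, vr, vb, cv), bp)
  coef_cov <- bp$nu * bp$k / (1 + bp$k)^2
  coef_var <- bp$nu * bp$k * 0.0249 / (1 + bp$k)^3
  expect_equal(
    td[["mean_b"]] - base[["mean_b"]],
    coef_cov * cv - coef_var * vr,
    tolerance = 1e-12
  )
  # the cov coefficient itself matches the hand-derived 2.333e-4 per 0.001
  expect_equal(coef_cov * 0.001, 1.05 * 2 * 0.001 / 9)
})

test_that("positive covariance strictly enhances closed biomass growth", {
  bp <- bio_params()
  for (cv in c(1e-4, 0.01, 0.05)) {
    mom <- tracer_moments(0.8, 0.1, var_r = cv, var_b = cv, cov_rb = cv)
    base <- tracer_moments(0.8, 0.1, var_r = cv, var_b = cv, cov_rb = 0)
    expect_gt(
      reaction_tendencies(mom, bp)[["mean_b"]],
      reaction_tendencies(base, bp)[["mean_b"]]
    )
  }
})

test_that("with full remineralization reactions conserve total tracer", {
  bp <- bio_params(alpha = 1)
  set.seed(3)
  for (i in 1:20) {
    vr <- runif(1, 0, 0.3)
    vb <- runif(1, 0, 0.3)
    mom <- tracer_moments(
      runif(1, 0, 2), runif(1, 0, 1),
      vr, vb, runif(1, -1, 1) * sqrt(vr * vb)
    )
    td <- reaction_tendencies(mom, bp)
    expect_equal(td[["mean_r"]] + td[["mean_b"]], 0, tolerance = 1e-15)
  }
  # and with alpha = 0 the loss is exactly the export rate m * b
  td0 <- reaction_tendencies(tracer_moments(1, 0.4), bio_params(alpha = 0))
  expect_equal(td0[["mean_r"]] + td0[["mean_b"]], -0.05 * 0.4)
})

test_that("closed mean uptake matches Monte-Carlo sampling of Monod growth", {
  # The closure approximates E[nu r b / (r + k)] by a second-order
  # expansion about the means; sampled and closed values must agree to
  # the size of the dropped third-order terms.
  set.seed(101)
  n <- 4e5
  bp <- bio_params()
  for (case in list(
    list(r = 1, b = 0.3, vr = 0.01, vb = 0.004, rho = 0.8),
    list(r = 0.5, b = 0.1, vr = 0.004, vb = 0.002, rho = -0.6)
  )) {
    cv <- case$rho * sqrt(case$vr * case$vb)
    s <- rbvn(n, case$r, case$b, case$vr, case$vb, cv)
    sampled <- mean(bp$nu * s$r * s$b / (s$r + bp$k))
    # evaluate the closure at the realized sample moments so Monte-Carlo
    # noise in the inputs cancels and only the truncation error remains
    mr <- mean(s$r)
    mb <- mean(s$b)
    closed <- bp$nu * mr * mb / (mr + bp$k) -
      bp$nu * bp$k * mb * stats::var(s$r) / (mr + bp$k)^3 +
      bp$nu * bp$k * stats::cov(s$r, s$b) / (mr + bp$k)^2
    # dropped terms are O(sigma^3): bound them generously
    expect_equal(sampled, closed, tolerance = 5e-4)
  }
  # and the truncation error shrinks with the moment magnitudes
  err_at_scale <- function(scale) {
    s <- rbvn(n, 1, 0.3, 0.02 * scale, 0.008 * scale, 0.008 * scale)
    sampled <- mean(bp$nu * s$r * s$b / (s$r + bp$k))
    mr <- mean(s$r)
    mb <- mean(s$b)
    closed <- bp$nu * mr * mb / (mr + bp$k) -
      bp$nu * bp$k * mb * stats::var(s$r) / (mr + bp$k)^3 +
      bp$nu * bp$k * stats::cov(s$r, s$b) / (mr + bp$k)^2
    abs(sampled - closed)
  }
  expect_lt(err_at_scale(0.2), err_at_scale(1))
})

test_that("quadratic mortality uses the exact second-moment mean loss", {
  qp <- bio_params(mortality_form = "quadratic", m_quad = 0.05)
  # homogeneous limit: plain m' b^2
  td <- quadratic_mortality_tendencies(tracer_moments(1, 0.4), qp)
  G <- qp$nu * 1 / (1 + qp$k)
  expect_equal(td[["mean_b"]], G * 0.4 - 0.05 * 0.16)
  # <b^2> = b^2 + var_b exactly: check against a discrete two-point field
  vb <- 0.5
  td <- quadratic_mortality_tendencies(tracer_moments(1, 1, var_b = vb), qp)
  b_field <- c(1 - sqrt(vb), 1 + sqrt(vb)) # mean 1, variance vb
  expect_equal(G * 1 - td[["mean_b"]], mean(0.05 * b_field^2))
  expect_equal(mean(0.05 * b_field^2), 0.075)
  # dispatch guards
  expect_error(
    quadratic_mortality_tendencies(tracer_moments(1, 1), bio_params()),
    "quadratic"
  )
  expect_error(bio_params(mortality_form = "quadratic"), "m_quad")
})

test_that("reaction_tendencies dispatches on the mortality form", {
  qp <- bio_params(mortality_form = "quadratic", m_quad = 0.07)
  mom <- tracer_moments(0.6, 0.2, 0.01, 0.01, 0.005)
  expect_equal(
    reaction_tendencies(mom, qp),
    quadratic_mortality_tendencies(mom, qp)
  )
})
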