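test_that("the SOIREE preset encodes the campaign setup", {
  cfg <- soiree_config()
  expect_equal(cfg$shape$W, 5)
  expect_equal(cfg$shape$L, 5)
  expect_equal(cfg$thickness, 10)
  expect_equal(cfg$forcing$gamma0, 0.12)
  expect_equal(cfg$forcing$kappa0, 0.1)
  expect_equal(cfg$bio$nu, 1.05)
  expect_equal(cfg$bio$m, 0.05)
  expect_equal(cfg$bio$k, 2)
  expect_equal(cfg$bio$alpha, 0)
  expect_equal(cfg$bio$fe_to_c, 1e-5)
  expect_equal(cfg$tau, 42)
  expect_equal(cfg$dt, 0.01)
  expect_equal(cfg$mode, "heterogeneous")
  # the surrounding iron is the ecosystem steady state
  expect_equal(steady_state_resource(cfg$bio), cfg$surrounding$mean_r)
  # the fertilization pulse raises patch iron by 0.9 over the surrounding
  expect_equal(cfg$initial$mean_r - cfg$surrounding$mean_r, 0.9)
  # initial second moments are zero everywhere
  expect_equal(cfg$initial$var_r + cfg$initial$var_b + cfg$initial$cov_rb, 0)
})

test_that("a surrounding-equal steady initial state is a fixed point", {
  # full recycling makes the steady state exact: growth balances
  # mortality for the consumer AND remineralization closes the resource
  # budget, so an unperturbed patch must not drift
  bp <- bio_params(alpha = 1)
  sur <- surrounding_state(steady_state_resource(bp), 0.0249)
  cfg <- sim_config(
    bio = bp, surrounding = sur,
    initial = tracer_moments(sur$mean_r, sur$mean_b),
    tau = 3, dt = 0.02
  )
  traj <- run_simulation(cfg)
  # geometry evolves, tracers do not
  expect_gt(dplyr::last(traj$A_km2), traj$A_km2[1])
  expect_equal(traj$mean_r, rep(sur$mean_r, nrow(traj)), tolerance = 1e-12)
  expect_equal(traj$mean_b, rep(sur$mean_b, nrow(traj)), tolerance = 1e-12)
  expect_equal(max(abs(traj$var_r)), 0)
  expect_equal(max(abs(traj$cov_rb)), 0)

  # without recycling the consumer is still stationary but export slowly
  # draws down the unreplenished resource (the surrounding is therefore
  # held fixed by construction, not by its own dynamics)
  bp0 <- bio_params(alpha = 0)
  traj0 <- run_simulation(sim_config(
    bio = bp0, surrounding = sur,
    initial = tracer_moments(sur$mean_r, sur$mean_b),
    tau = 3, dt = 0.02
  ))
  expect_lt(max(abs(traj0$mean_b - 0.0249)), 1e-3)
  expect_true(all(diff(traj0$mean_r) < 0))
})

test_that("with no forcing the dynamics reduce to the mean-field ODEs", {
  skip_if_not_installed("deSolve")
  cfg <- sim_config(
    forcing = forcing_laws(0, 0, 10), tau = 20, dt = 0.01
  )
  traj <- run_simulation(cfg)
  # geometry frozen
  expect_equal(traj$A_km2, rep(traj$A_km2[1], nrow(traj)), tolerance = 1e-14)
  # no dilution ever: zero initial moments stay zero
  expect_equal(max(abs(traj$var_b)), 0)
  # independent adaptive integration of the closed-patch kinetics
  bp <- cfg$bio
  ref <- deSolve::ode(
    c(r = 1, b = 0.0249), seq(0, 20, 0.5),
    function(t, y, p) {
      G <- bp$nu * y[1] / (y[1] + bp$k)
      list(c(-G * y[2] + bp$alpha * bp$m * y[2], G * y[2] - bp$m * y[2]))
    },
    NULL, rtol = 1e-11, atol = 1e-13
  )
  idx <- match(round(seq(0, 20, 0.5), 8), round(traj$time_day, 8))
  expect_equal(traj$mean_r[idx], unname(ref[, "r"]), tolerance = 1e-8)
  expect_equal(traj$mean_b[idx], unname(ref[, "b"]), tolerance = 1e-8)
  # with alpha = 0, total tracer decreases monotonically (export)
  total <- traj$mean_r + traj$mean_b
  expect_true(all(diff(total) < 0))
  # and the two modes coincide when no heterogeneity is ever generated
  wm <- run_simulation(sim_config(
    forcing = forcing_laws(0, 0, 10), tau = 20, dt = 0.01,
    mode = "well_mixed"
  ))
  expect_equal(traj$mean_b, wm$mean_b, tolerance = 1e-12)
})

test_that("well-mixed mode solves the mean-field system with dilution", {
  skip_if_not_installed("deSolve")
  cfg <- sim_config(
    forcing = forcing_laws(0.3, 0.2, 10), tau = 15, dt = 0.01,
    mode = "well_mixed"
  )
  traj <- run_simulation(cfg)
  expect_equal(max(abs(traj$var_r)), 0)
  expect_equal(max(abs(traj$cov_rb)), 0)
  bp <- cfg$bio
  fl <- cfg$forcing
  sur <- cfg$surrounding
  ref <- deSolve::ode(
    c(W2 = 25, L2 = 25, r = 1, b = 0.0249), seq(0, 15, 0.5),
    function(t, y, p) {
      W <- sqrt(y[1])
      L <- sqrt(y[2])
      S <- W + L
      gam <- strain_at_size(fl, S)
      kap <- diffusion_at_size(fl, S)
      dil <- kap * (y[1] + y[2]) / (W * L) / (W * L) # (dA/dt)/A
      G <- bp$nu * y[3] / (y[3] + bp$k)
      list(c(
        2 * kap - 2 * gam * y[1],
        2 * kap + 2 * gam * y[2],
        -G * y[4] + dil * (sur$mean_r - y[3]),
        G * y[4] - bp$m * y[4] + dil * (sur$mean_b - y[4])
      ))
    },
    NULL, rtol = 1e-11, atol = 1e-13
  )
  idx <- match(round(seq(0, 15, 0.5), 8), round(traj$time_day, 8))
  expect_equal(traj$mean_b[idx], unname(ref[, "b"]), tolerance = 1e-8)
  expect_equal(traj$W_km[idx]^2, unname(ref[, "W2"]), tolerance = 1e-8)
})

test_that("the stepper shows 4th-order accuracy under dt refinement", {
  run_at <- function(dt) {
    traj <- run_simulation(sim_config(tau = 4, dt = dt))
    dplyr::last(traj$mean_b)
  }
  ref <- run_at(0.005)
  e1 <- abs(run_at(0.16) - ref)
  e2 <- abs(run_at(0.08) - ref)
  # RK4: halving dt cuts the error ~16x (allow a broad band)
  expect_gt(e1 / e2, 8)
  expect_lt(e2, 1e-8)
})

test_that("step_patch agrees with the engine and guards its state", {
  cfg <- soiree_config(dt = 0.01)
  stepped <- step_patch(cfg$shape, cfg$initial, cfg)
  traj <- run_simulation(soiree_config(tau = 0.01, dt = 0.01))
  expect_equal(stepped$shape$W, traj$W_km[2], tolerance = 1e-14)
  expect_equal(stepped$moments$mean_b, traj$mean_b[2], tolerance = 1e-14)
  expect_false(stepped$clamped)
  # second moments produced by one dilution step are admissible
  m <- stepped$moments
  expect_gte(m$var_r, 0)
  expect_lte(m$cov_rb^2, m$var_r * m$var_b * (1 + 1e-9))
})

test_that("identical configurations give bit-identical trajectories", {
  a <- run_simulation(sim_config(tau = 3, dt = 0.02))
  b <- run_simulation(sim_config(tau = 3, dt = 0.02))
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("inflating internal mixing recovers the well-mixed means", {
  fl <- forcing_laws(0.3, 0.3, 10)
  wm <- run_simulation(sim_config(
    forcing = fl, tau = 10, dt = 0.01, mode = "well_mixed"
  ))
  het <- run_simulation(sim_config(forcing = fl, tau = 10, dt = 0.01))
  het_mixed <- run_simulation(sim_config(
    forcing = fl, tau = 10, dt = 0.01, mixing_factor = 1e4
  ))
  gap_plain <- max(abs(het$mean_b - wm$mean_b)) / max(wm$mean_b)
  gap_mixed <- max(abs(het_mixed$mean_b - wm$mean_b)) / max(wm$mean_b)
  expect_lt(gap_mixed, 0.01)
  expect_lt(gap_mixed, gap_plain / 5)
})

test_that("halving the time step leaves the LBA essentially unchanged", {
  lba_at <- function(dt) {
    lagrangian_biomass_anomaly(run_simulation(sim_config(
      forcing = forcing_laws(0.3, 0.3, 10), tau = 15, dt = dt
    )))
  }
  expect_equal(lba_at(0.02), lba_at(0.01), tolerance = 1e-3)
})

test_that("ensembles are order-independent and tolerate member failure", {
  cfg <- sim_config(tau = 4, dt = 0.05)
  ens <- run_ensemble(cfg,
    gamma0 = c(0.05, 0.4), kappa0 = c(0.05, 0.4),
    modes = c("well_mixed", "heterogeneous")
  )
  expect_s3_class(ens, "patch_ensemble")
  expect_equal(nrow(ens), 8)
  expect_true(all(is.na(ens$error)))
  expect_true(all(ens$lba_MgC > 0))
  # rows are a pure function of (gamma0, kappa0, mode): rerun a member
  # standalone and compare
  solo <- run_simulation(sim_config(
    forcing = forcing_laws(0.4, 0.05, 10), tau = 4, dt = 0.05
  ))
  row <- dplyr::filter(
    ens, gamma0 == 0.4, kappa0 == 0.05, mode == "heterogeneous"
  )
  expect_equal(row$lba_MgC, lagrangian_biomass_anomaly(solo))
  expect_equal(row$dilution_factor, dilution_factor(solo))
})

test_that("trajectory glance summarizes the bloom", {
  g <- glance(run_simulation(soiree_config(tau = 20)))
  expect_equal(nrow(g), 1)
  expect_gt(g$peak_ratio, 10)
  expect_gt(g$lba_MgC, 0)
  expect_equal(g$export_MgC_per_day, 0.05 * g$lba_MgC)
  expect_gt(g$dilution_factor, 1)
})
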