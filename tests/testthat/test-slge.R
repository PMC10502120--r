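gp_fig <- growth_params(1.2, 100, 1)  # the reference parameterization

test_that("noise-free simulation reproduces the deterministic curve", {
  cfg <- slge_config(gp_fig, sigma = 0, n_iter = 2, t0 = 1,
                     t_final = 20, n_steps = 1000, seed = 1)
  ens <- simulate_slge(cfg)
  exact <- logistic_solution(gp_fig, ens$times - 1)
  expect_lt(max(abs(ens$abundances[1, ] - exact) / exact), 2e-3)
  expect_identical(ens$abundances[1, ], ens$abundances[2, ])

  # first-order convergence: halving dt moves the path by < 1e-3 rel.
  cfg2 <- slge_config(gp_fig, sigma = 0, n_iter = 1, t0 = 1,
                      t_final = 20, n_steps = 2000, seed = 1)
  ens2 <- simulate_slge(cfg2)
  on_coarse <- ens2$abundances[1, seq(1, length(ens2$times), by = 2)]
  expect_lt(max(abs(on_coarse - ens$abundances[1, ]) / exact), 1e-3)
})

test_that("ensembles are reproducible and paths are seed-substreamed", {
  cfg <- slge_config(gp_fig, sigma = 0.1, n_iter = 10, t_final = 10,
                     seed = 99)
  e1 <- simulate_slge(cfg)
  e2 <- simulate_slge(cfg)
  expect_identical(e1$abundances, e2$abundances)
  # growing the ensemble must not reshuffle existing paths
  cfg_big <- slge_config(gp_fig, sigma = 0.1, n_iter = 25,
                         t_final = 10, seed = 99)
  e3 <- simulate_slge(cfg_big)
  expect_identical(e3$abundances[1:10, ], e1$abundances)
})

test_that("stationary-window ensemble mean sits at the carrying capacity", {
  # representative conditions: r = 1.2, K = 100, sigma = 0.1, 100 paths
  ens <- simulate_slge(slge_config(gp_fig, sigma = 0.1, seed = 42))
  b <- phase_boundaries(gp_fig, t0 = 1)
  stat_idx <- ens$times >= b$s4
  expect_lt(abs(mean(ens$abundances[, stat_idx]) - 100) / 100, 0.10)
  expect_true(all(ens$abundances >= 0))
  expect_identical(ncol(ens$deltas), ncol(ens$abundances) - 1L)
})

test_that("ensemble spread in the stationary window grows with sigma", {
  b <- phase_boundaries(gp_fig, t0 = 1)
  spread <- vapply(c(0.01, 0.1, 0.2), function(s) {
    ens <- simulate_slge(slge_config(gp_fig, sigma = s, seed = 7))
    mean(apply(ens$abundances[, ens$times >= b$s4], 2, sd))
  }, numeric(1))
  expect_true(all(diff(spread) > 0))
})

test_that("stochastic-K variant reduces to the deterministic path at sigma 0", {
  cfg0 <- slge_config(gp_fig, sigma = 0, n_iter = 3, t_final = 30,
                      seed = 5)
  det <- simulate_slge(cfg0)
  stk <- simulate_slge_stochastic_k(cfg0)
  expect_identical(det$abundances, stk$abundances)
})

test_that("stochastic-K ensembles stay sigmoidal with median near K", {
  cfg <- slge_config(gp_fig, sigma = 0.1, seed = 21,
                     noise_target = "carrying_capacity")
  ens <- simulate_slge(cfg)
  b <- phase_boundaries(gp_fig, t0 = 1)
  med <- median(ens$abundances[, ens$times >= b$s4])
  expect_lt(abs(med - 100) / 100, 0.10)
  # phase-signature signs match the abundance-noise simulator
  ens_x <- simulate_slge(slge_config(gp_fig, sigma = 0.1, seed = 21))
  for (ph in c("acceleration", "deceleration")) {
    m_k <- median(phase_window_correlation(ens, b, ph), na.rm = TRUE)
    m_x <- median(phase_window_correlation(ens_x, b, ph), na.rm = TRUE)
    expect_identical(sign(m_k), sign(m_x))
  }
})

test_that("harvest shifts the stable point to K(1 - H/r)", {
  expect_identical(equilibrium_with_harvest(gp_fig, 0), 100)
  expect_equal(equilibrium_with_harvest(gp_fig, 0.6), 50)
  expect_identical(equilibrium_with_harvest(gp_fig, 1.2), 0)
  expect_identical(equilibrium_with_harvest(gp_fig, 5), 0)

  for (frac in c(0.1, 0.5, 0.9)) {
    H <- frac * gp_fig$r
    cfg <- slge_config(gp_fig, sigma = 0, harvest = H, n_iter = 1,
                       t0 = 0, t_final = 200, seed = 1)
    ens <- simulate_slge(cfg)
    settled <- ens$abundances[1, ncol(ens$abundances)]
    expect_lt(abs(settled - equilibrium_with_harvest(gp_fig, H)) /
                equilibrium_with_harvest(gp_fig, H), 1e-3)
  }
})

test_that("deterministic acceleration window gives strongly positive coupling", {
  cfg <- slge_config(gp_fig, sigma = 0, n_iter = 1, seed = 1)
  ens <- simulate_slge(cfg)
  b <- phase_boundaries(gp_fig, t0 = 1)
  expect_gt(phase_window_correlation(ens, b, "acceleration")[1], 0.9)
})

test_that("windows with too few grid points yield NA, not errors", {
  gp_slow <- growth_params(0.4, 100, 1)
  cfg <- slge_config(gp_slow, sigma = 0, n_iter = 2, t0 = 1,
                     t_final = 100, n_steps = 1, seed = 1)
  ens <- simulate_slge(cfg)
  b <- phase_boundaries(gp_slow, t0 = 1)
  # mid-log spans ~2 time units here: at most 2 grid points at dt = 1
  expect_true(all(is.na(phase_window_correlation(ens, b, "midlog"))))
})

test_that("invalid simulator settings are refused with clear messages", {
  expect_error(slge_config(gp_fig, sigma = -0.1), "sigma")
  expect_error(slge_config(gp_fig, harvest = -1), "harvest")
  cfg <- slge_config(growth_params(3, 100, 1), n_steps = 5)
  expect_error(simulate_slge(cfg), "overshoot")
})
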