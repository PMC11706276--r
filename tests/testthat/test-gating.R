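test_that("Boltzmann sigmoid hits its analytic anchor points", {
  expect_equal(boltzmann_fraction(-17.56, -17.56, 6, "rising"), 0.5)
  expect_equal(boltzmann_fraction(-40, -40, 3.2, "falling"), 0.5)
  # solve 1/(1+e^x) = 0.1 -> x = ln 9
  k <- 6
  expect_equal(boltzmann_fraction(-30 + k * log(9), -30, k, "falling"), 0.1,
               tolerance = 1e-12)
  v <- seq(-100, 60, by = 1)
  f <- boltzmann_fraction(v, -20, 7, "rising")
  expect_true(all(f > 0 & f < 1))
  expect_error(boltzmann_fraction(0, 0, -1, "rising"), "positive")
  expect_error(boltzmann_fraction(0, 0, 0, "falling"), "positive")
})

test_that("steady-state inactivation respects the persistent floor", {
  full <- synthetic_channel(persistent_frac = 1)
  expect_equal(steady_state_inactivation(full, c(-120, -40, 40)), rep(1, 3))
  none <- synthetic_channel(persistent_frac = 0, v_half_inact = -55)
  expect_equal(steady_state_inactivation(none, -55), 0.5)
  wt <- nav_variant("WT")
  expect_gt(steady_state_inactivation(wt, -120), 0.999)
  # floor reached at strong depolarization
  expect_equal(steady_state_inactivation(wt, 100), wt$persistent_frac,
               tolerance = 1e-6)
  n16 <- nav_variant("N1662D")
  expect_equal(steady_state_inactivation(n16, 100), 0.8, tolerance = 1e-6)
})

test_that("steady states are monotone in voltage", {
  v <- seq(-120, 60, by = 1)
  for (nm in c("WT", "N1662D", "Q1494K")) {
    p <- nav_variant(nm)
    expect_true(all(diff(steady_state_activation(p, v)) > 0))
    expect_true(all(diff(steady_state_inactivation(p, v)) < 0))
  }
})

test_that("gate time constants anchor to the recovery and test potentials", {
  wt <- nav_variant("WT")
  expect_equal(gate_tau(wt, "h", -120), 1.19, tolerance = 1e-9)
  expect_equal(gate_tau(wt, "h", -10), wt$tau_inact_ms, tolerance = 1e-9)
  n16 <- nav_variant("N1662D")
  expect_equal(gate_tau(n16, "h", -120), 0.54, tolerance = 1e-9)
  lib <- load_variant_table()
  v <- seq(-140, 60, by = 2)
  for (i in seq_len(nrow(lib))) {
    p <- as_variant_params(lib[i, ])
    expect_true(all(gate_tau(p, "h", v) > 0))
    expect_true(all(gate_tau(p, "m", v) > 0))
    expect_lte(gate_tau(p, "m", 0), 0.5)
  }
})

test_that("ohmic current vanishes at the reversal potential and with closed gates", {
  p <- synthetic_channel()
  expect_equal(channel_current(p, m = 1, h = 1, v = p$e_na_mV, g_max = 10), 0)
  expect_equal(channel_current(p, m = 0.7, h = 0, v = -10, g_max = 10), 0)
  # Ohm's law: 10 nS fully open, 10 mV below reversal -> -100 pA
  expect_equal(channel_current(p, m = 1, h = 1, v = p$e_na_mV - 10, g_max = 10), -100)
})

test_that("exponential-Euler gating update is exact and composes", {
  wt <- nav_variant("WT")
  s0 <- list(m = 0.3, h = 0.9)
  expect_identical(advance_gating(wt, s0, -40, 0), s0)
  # complete relaxation
  s_inf <- advance_gating(wt, s0, -40, 1e6)
  expect_equal(s_inf$m, steady_state_activation(wt, -40), tolerance = 1e-12)
  expect_equal(s_inf$h, steady_state_inactivation(wt, -40), tolerance = 1e-12)
  # half-life: after tau * ln 2 the gate is halfway to steady state
  v <- -50
  tau_h <- gate_tau(wt, "h", v)
  s1 <- advance_gating(wt, s0, v, tau_h * log(2))
  h_inf <- steady_state_inactivation(wt, v)
  expect_equal(s1$h, h_inf + (s0$h - h_inf) / 2, tolerance = 1e-12)
  # n small steps equal one large step at constant voltage
  s_many <- s0
  for (i in 1:50) s_many <- advance_gating(wt, s_many, v, 0.02)
  s_once <- advance_gating(wt, s0, v, 50 * 0.02)
  expect_equal(s_many$m, s_once$m, tolerance = 1e-12)
  expect_equal(s_many$h, s_once$h, tolerance = 1e-12)
  expect_error(advance_gating(wt, s0, v, -1), "non-negative")
})

test_that("gates stay in [0, 1] under arbitrary update sequences", {
  set.seed(42)
  for (nm in c("WT", "N1662D", "Q1494E")) {
    p <- nav_variant(nm)
    s <- list(m = runif(1), h = runif(1))
    for (i in 1:200) {
      s <- advance_gating(p, s, runif(1, -130, 60), runif(1, 0, 5))
      expect_true(s$m >= 0 && s$m <= 1)
      expect_true(s$h >= 0 && s$h <= 1)
    }
  }
})
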