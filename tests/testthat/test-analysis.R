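test_that("Boltzmann fits recover generating parameters from perfect data", {
  pts <- boltzmann_points(-30, 6, "rising", v = seq(-70, 10, by = 5))
  f <- fit_boltzmann(pts, "rising")
  expect_equal(f$v_half, -30, tolerance = 1e-4)
  expect_equal(f$k, 6, tolerance = 1e-4)
  pts <- boltzmann_points(-51.7, 4.5, "falling")
  f <- fit_boltzmann(pts, "falling")
  expect_equal(f$v_half, -51.7, tolerance = 1e-4)
  expect_equal(f$k, 4.5, tolerance = 1e-4)
})

test_that("degenerate Boltzmann inputs raise errors", {
  expect_error(fit_boltzmann(tibble::tibble(v = seq(-60, -20, 10), y = 0.5), "rising"),
               "constant")
  expect_error(fit_boltzmann(tibble::tibble(v = c(-60, -40), y = c(1, 0)), "falling"),
               "4 points")
  expect_error(fit_boltzmann(tibble::tibble(v = seq(-60, -20, 10), y = seq(0.6, 1, 0.1)),
                             "rising"), "half-maximum")
})

test_that("single-exponential fits recover tau from clean and noisy recovery data", {
  t <- c(0.5, 1, 2, 4, 8)
  f <- fit_exponential(tibble::tibble(t = t, y = 1 - exp(-t / 1)), "fixed")
  expect_equal(f$tau, 1, tolerance = 1e-6)
  t2 <- c(0.1, 0.2, 0.5, 1, 2, 3, 5, 8, 12, 20, 30)
  f2 <- fit_exponential(tibble::tibble(t = t2, y = 1 - exp(-t2 / 2)), "fixed")
  expect_equal(f2$tau, 2, tolerance = 1e-6)
  # Monte-Carlo bias under Gaussian noise: mean tau within 5 percent
  set.seed(11)
  tt <- exp(seq(log(0.1), log(30), length.out = 12))
  taus <- replicate(200, {
    y <- 1 - exp(-tt / 1.19) + rnorm(12, 0, 0.02)
    suppressWarnings(fit_exponential(tibble::tibble(t = tt, y = y), "fixed")$tau)
  })
  expect_lt(abs(mean(taus) - 1.19) / 1.19, 0.05)
  expect_error(fit_exponential(tibble::tibble(t = c(0, 1, 2, 3), y = 1:4 / 4)),
               "positive")
  expect_warning(fit_exponential(tibble::tibble(t = c(1, 2, 3, 4, 5),
                                                y = c(0.5, 0.9, 0.2, 0.95, 1))),
                 "non-monotone")
})

test_that("a fully inactivating channel has negligible persistent current", {
  p <- synthetic_channel(persistent_frac = 0, v_half_inact = -80, tau_inact = 1.5)
  tr <- run_voltage_clamp(p, protocol_activation(), recording_conditions(g_max_nS = 10))
  m <- measure_persistent(tr)
  expect_false(m$nd)
  expect_lt(m$percent, 0.01)
})

test_that("persistent measurement validates its inputs", {
  wt <- nav_variant("WT")
  tr <- run_voltage_clamp(wt, protocol_inactivation(), recording_conditions())
  expect_error(measure_persistent(tr), "no step sweep")
  hold <- voltage_protocol(
    "zero", -120,
    tibble::tibble(segment = c("baseline", "step"), level_mV = c(-120, NA),
                   duration_ms = c(2, 40), role = c("fixed", "swept_level")),
    sweep_values = -10
  )
  tr0 <- run_voltage_clamp(synthetic_channel(), hold, recording_conditions(g_max_nS = 0))
  expect_error(measure_persistent(tr0), "zero peak")
})

test_that("simulate-then-analyze round-trips hold across slope factors", {
  # identifiability: fitted midpoints within 1 mV and tau within 10 percent
  # of the configured values for any plausible slope factor
  lib <- load_variant_table()
  for (nm in c("WT", "N1662D", "Q1494K")) {
    for (k in c(4, 9)) {
      p <- as_variant_params(lib[lib$name == nm, ])
      p$k_act_mV <- k
      p$k_inact_mV <- k
      p <- as_variant_params(unclass(p))
      r <- characterize_variant(p)
      expect_lt(abs(r$v_half_act_mV - p$v_half_act_mV), 1,
                label = sprintf("%s k=%g v_half_act", nm, k))
      expect_lt(abs(r$v_half_inact_mV - p$v_half_inact_mV), 1,
                label = sprintf("%s k=%g v_half_inact", nm, k))
      expect_lt(abs(r$tau_rec_ms - p$tau_rec_ms) / p$tau_rec_ms, 0.1,
                label = sprintf("%s k=%g tau_rec", nm, k))
    }
  }
})

test_that("activation analysis recovers the configured slope factor", {
  # with slow inactivation the peak conductance equals the steady-state
  # conductance, so the fitted k matches k_act
  p <- synthetic_channel(v_half_act = -25, k_act = 7, v_half_inact = -60,
                         persistent_frac = 0, tau_inact = 60)
  tr <- run_voltage_clamp(p, protocol_activation(), recording_conditions(g_max_nS = 10))
  f <- activation_analysis(tr)
  expect_lt(abs(f$k - 7) / 7, 0.02)
  expect_lt(abs(f$v_half - (-25)), 0.5)
})

test_that("recovery analysis needs paired pulses and enough intervals", {
  wt <- nav_variant("WT")
  tr_act <- run_voltage_clamp(wt, protocol_activation(), recording_conditions())
  expect_error(recovery_analysis(tr_act), "paired-pulse")
  short <- protocol_recovery(intervals_ms = c(0.1, 1, 5, 20, 30))
  tr <- run_voltage_clamp(wt, short, recording_conditions())
  expect_error(recovery_analysis(tr), "6 interpulse")
})

test_that("fit objects expose broom-style tidy and glance methods", {
  f <- fit_boltzmann(boltzmann_points(-30, 6, "rising"), "rising")
  td <- generics::tidy(f)
  expect_equal(td$term, c("v_half", "k"))
  gl <- generics::glance(f)
  expect_equal(gl$n_points, f$n_points)
  t <- c(0.5, 1, 2, 4, 8)
  fr <- fit_exponential(tibble::tibble(t = t, y = 1 - exp(-t / 2)))
  expect_equal(generics::tidy(fr)$estimate[1], 2, tolerance = 1e-6)
})
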