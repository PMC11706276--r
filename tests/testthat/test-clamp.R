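test_that("a protocol held at the holding potential produces constant current", {
  wt <- nav_variant("WT")
  hold <- voltage_protocol(
    "hold", -120,
    tibble::tibble(segment = c("a", "b"), level_mV = c(-120, NA),
                   duration_ms = c(5, 10), role = c("fixed", "swept_level")),
    sweep_values = -120
  )
  tr <- run_voltage_clamp(wt, hold, recording_conditions(g_max_nS = 10))
  expect_lt(diff(range(tr$i_pA)), 1e-9)
})

test_that("a step to the reversal potential draws no current", {
  # reversal placed inside the protocol's sweep range
  p <- synthetic_channel(e_na = 55)
  tr <- run_voltage_clamp(p, protocol_activation(), recording_conditions(g_max_nS = 10))
  at_rev <- tr[tr$segment == "step" & tr$sweep == p$e_na_mV, ]
  expect_gt(nrow(at_rev), 0)
  expect_true(all(abs(at_rev$i_pA) < 1e-9))
})

test_that("non-inactivating variants retain at least half the peak at 100 ms", {
  n16 <- nav_variant("N1662D")
  long <- voltage_protocol(
    "long-step", -120,
    tibble::tibble(segment = c("baseline", "step"), level_mV = c(-120, NA),
                   duration_ms = c(2, 100), role = c("fixed", "swept_level")),
    sweep_values = -10
  )
  tr <- run_voltage_clamp(n16, long, recording_conditions())
  step <- tr[tr$segment == "step", ]
  pk <- min(step$i_pA)
  late <- step$i_pA[nrow(step)]
  expect_gte(late / pk, 0.5)
})

test_that("calibrated models reproduce the published peak current densities", {
  for (nm in c("WT", "N1662D", "Q1494K")) {
    p <- nav_variant(nm)
    tr <- run_voltage_clamp(p, protocol_activation(), recording_conditions())
    iv <- peak_iv(tr)
    dens <- abs(iv$density_pA_per_pF[iv$v_mV == -10])
    expect_equal(dens, p$peak_density_pA_per_pF, tolerance = 1e-6)
  }
})

test_that("the conductance transform inverts the ohmic current model", {
  # h pinned at 1: peak conductance at strong depolarization equals g_max
  p <- synthetic_channel(persistent_frac = 1, v_half_act = -30)
  g_max <- 12
  tr <- run_voltage_clamp(p, protocol_activation(),
                          recording_conditions(g_max_nS = g_max))
  iv <- peak_iv(tr)
  v <- 45
  g <- iv$i_peak_pA[iv$v_mV == v] / (v - p$e_na_mV)
  expect_equal(g, g_max * steady_state_activation(p, v), tolerance = 0.01)
})

test_that("persistent measurement is invariant to conductance scaling", {
  wt <- nav_variant("WT")
  p1 <- measure_persistent(run_voltage_clamp(wt, protocol_activation(),
                                             recording_conditions(g_max_nS = 5)))
  p2 <- measure_persistent(run_voltage_clamp(wt, protocol_activation(),
                                             recording_conditions(g_max_nS = 50)))
  expect_equal(p1$ratio_pct, p2$ratio_pct, tolerance = 1e-9)
})

test_that("halving the integration step changes fitted parameters by < 0.1 percent", {
  wt <- nav_variant("WT")
  r1 <- characterize_variant(wt, dt = 0.02)
  r2 <- characterize_variant(wt, dt = 0.01)
  expect_lt(abs(r2$v_half_act_mV - r1$v_half_act_mV) / abs(r1$v_half_act_mV), 1e-3)
  expect_lt(abs(r2$v_half_inact_mV - r1$v_half_inact_mV) / abs(r1$v_half_inact_mV), 1e-3)
  expect_lt(abs(r2$tau_rec_ms - r1$tau_rec_ms) / r1$tau_rec_ms, 1e-3)
  expect_lt(abs(r2$persistent_pct - r1$persistent_pct) / r1$persistent_pct, 1e-3)
})

test_that("traces export to wide CSV with a YAML sidecar", {
  wt <- nav_variant("WT")
  tr <- run_voltage_clamp(wt, protocol_recovery(), recording_conditions())
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(c(tmp, paste0(tmp, ".yaml"))), add = TRUE)
  export_traces(tr, tmp, seed = 7)
  wide <- utils::read.csv(tmp, check.names = FALSE)
  expect_equal(names(wide)[1], "time_ms")
  expect_length(grep("^sweep_", names(wide)), 11L)
  meta <- yaml::read_yaml(paste0(tmp, ".yaml"))
  expect_equal(meta$variant, "WT")
  expect_equal(meta$holding_mV, -120)
  expect_equal(meta$seed, 7)
  # swept-duration sweeps are NA-padded to the longest
  expect_true(anyNA(wide$`sweep_0.1`))
  expect_false(anyNA(wide$sweep_30))
})
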