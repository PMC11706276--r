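passive_ais <- function(g_leak_nS = 0.5) {
  ais_model(g_leak_nS = g_leak_nS, gkv_scale = 0, gnav16_scale = 0)
}

test_that("a passive membrane without stimulus rests at the leak reversal", {
  ais <- passive_ais()
  r <- run_hybrid_sim(ais, dapc_config(record_every = 10L), 0)
  expect_lt(max(abs(r$vm_mV - ais$e_leak_mV)), 1e-9)
})

test_that("the leak-only step response matches the closed-form RC solution", {
  ais <- passive_ais()
  cfg <- dapc_config(stim_start_ms = 50, stim_dur_ms = 400)
  amp <- 10
  r <- run_hybrid_sim(ais, cfg, amp)
  tau <- ais$c_m_pF / ais$g_leak_nS                      # ms
  t <- r$time_ms
  expected <- ifelse(
    t < 50, ais$e_leak_mV,
    ifelse(t < 450,
           ais$e_leak_mV + (amp / ais$g_leak_nS) * (1 - exp(-(t - 50) / tau)),
           NA)
  )
  keep <- !is.na(expected)
  expect_lt(max(abs(r$vm_mV[keep] - expected[keep])), 0.1)
})

test_that("every simulation satisfies the current-balance invariant", {
  ais <- ais_model()
  cfg <- dapc_config(variant = nav_variant("N1662D"), na12_fraction = 0.1,
                     stim_start_ms = 50, stim_dur_ms = 300)
  r <- run_hybrid_sim(ais, cfg, 14)                      # spiking sweep
  dt <- cfg$dt_ms
  n <- nrow(r)
  lhs <- ais$c_m_pF * diff(r$vm_mV) / dt
  rhs <- (r$i_stim_pA - r$i_leak_pA - r$i_kv_pA - r$i_nav16_pA - r$i_nav12_pA)[-n]
  i_max <- max(abs(rhs))
  expect_lt(max(abs(lhs - rhs)), 1e-6 * i_max)
})

test_that("spike detection counts threshold crossings with a refractory period", {
  t <- seq(0, 1000, by = 0.1)
  expect_length(detect_spikes(rep(-70, length(t)), t), 0L)
  # one synthetic action potential
  ap <- -70 + 100 * exp(-(t - 500)^2 / 2)
  expect_length(detect_spikes(ap, t), 1L)
  # 40 Hz synthetic spike train over 1 s (one positive lobe per 25 ms)
  train <- -70 + 100 * pmax(sin(2 * pi * t / 25), 0)^20
  expect_length(detect_spikes(train[t < 1000], t[t < 1000]), 40L)
})

test_that("the stimulus protocol spans -2 to +24 pA in 2 pA increments", {
  cfg <- dapc_config()
  expect_length(cfg$stim_amplitudes_pA, 14L)
  expect_equal(range(cfg$stim_amplitudes_pA), c(-2, 24))
})

test_that("a passive membrane never fires", {
  ais <- passive_ais()
  io <- input_output_curve(ais, fast_dapc(stim_amplitudes_pA = c(0, 12, 24)))
  expect_true(all(io$mean_freq_hz == 0))
  # below the passive-block band the membrane is not classified depolarized
  expect_false(any(io$sustained[io$stim_pA <= 20]))
})

test_that("Pearson correlation matches hand-computed values and validates input", {
  x <- c(1, 2, 3)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_equal(pearson_r(x, c(1, 3, 2)), 0.5)
  expect_error(pearson_r(c(1, 1, 1), x), "constant")
  expect_error(pearson_r(1:2, 1:2), "3 paired")
})

test_that("wild-type current never produces sustained depolarization", {
  ais0 <- ais_model(gnav16_scale = 0)
  expect_warning(
    fs <- fraction_sweep(ais0, nav_variant("WT"), c(0.2, 1), 12,
                         config = fast_dapc()),
    "no fraction"
  )
  expect_equal(nrow(fs), 0L)
})

test_that("fraction sweep returns one pair per sustained fraction", {
  ais0 <- ais_model(gnav16_scale = 0)
  fs <- fraction_sweep(ais0, nav_variant("N1662D"), 0.2, 12, config = fast_dapc())
  expect_equal(nrow(fs), 1L)
  expect_gt(fs$plateau_vm_mV, -18)
})

test_that("halving dt leaves the spike count unchanged and the plateau within 0.5 mV", {
  ais <- ais_model()
  cfg1 <- fast_dapc(variant = nav_variant("N1662D"), na12_fraction = 0.2)
  cfg2 <- fast_dapc(variant = nav_variant("N1662D"), na12_fraction = 0.2, dt_ms = 0.01)
  ais0 <- ais_model(gnav16_scale = 0)
  r1 <- run_hybrid_sim(ais0, cfg1, 12)
  r2 <- run_hybrid_sim(ais0, cfg2, 12)
  d1 <- detect_sustained_depolarization(r1)
  d2 <- detect_sustained_depolarization(r2)
  expect_equal(length(detect_spikes(r1)), length(detect_spikes(r2)))
  expect_lt(abs(d1$plateau_vm_mV - d2$plateau_vm_mV), 0.5)
  # repetitively spiking configuration (away from the block bifurcation)
  s1 <- run_hybrid_sim(ais, fast_dapc(), 12)
  s2 <- run_hybrid_sim(ais, fast_dapc(dt_ms = 0.01), 12)
  expect_equal(length(detect_spikes(s1)), length(detect_spikes(s2)))
})
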