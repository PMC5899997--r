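test_that("steady-state gate is a Boltzmann with the expected anchors", {
  # midpoint by symmetry, both directions, any slope
  for (s in c(1, 5.4, 6.4, 12))
    for (d in c("increasing", "decreasing"))
      expect_equal(steadyStateGate(-65.3, -65.3, s, d), 0.5)
  # closed form of the logistic: V12 + slope * ln 9 gives 0.1 (decreasing)
  expect_equal(steadyStateGate(-65.3 + 5.4 * log(9), -65.3, 5.4,
                               "decreasing"), 0.1)
  expect_equal(steadyStateGate(-19.5 + 6.4 * log(9), -19.5, 6.4,
                               "increasing"), 0.9)
  # strict monotonicity over a voltage grid
  V <- seq(-150, 50, by = 1)
  expect_true(all(diff(steadyStateGate(V, -19.5, 6.4, "increasing")) > 0))
  expect_true(all(diff(steadyStateGate(V, -65.3, 5.4, "decreasing")) < 0))
  expect_error(steadyStateGate(0, -20, 0, "increasing"), "slope")
  expect_error(steadyStateGate(0, -20, -3, "decreasing"), "slope")
})

test_that("inactivation time constant interpolates between its anchors", {
  p <- makeParams(tauInact0mVms = 0.30, tauRecM80mVms = 5.63)
  expect_equal(gateTimeConstant(0, p, "inactivation"), 0.30)
  expect_equal(gateTimeConstant(-80, p, "inactivation"), 5.63)
  # between anchors: bounded by them (log-linear interpolation)
  mid <- gateTimeConstant(-40, p, "inactivation")
  expect_gt(mid, 0.30)
  expect_lt(mid, 5.63)
  expect_equal(mid, sqrt(0.30 * 5.63))  # log-linear at the midpoint voltage
  # clamped outside the anchor range
  expect_equal(gateTimeConstant(-150, p, "inactivation"), 5.63)
  expect_equal(gateTimeConstant(50, p, "inactivation"), 0.30)
  # activation tau is proportional, tauActms at 0 mV
  expect_equal(gateTimeConstant(0, p, "activation"), p@tauActms)
  expect_equal(gateTimeConstant(-80, p, "activation"),
               p@tauActms * 5.63 / 0.30)
  expect_error(gateTimeConstant(-200, p, "inactivation"), "range")
})

test_that("standard protocols match the published step layouts", {
  ps <- buildStandardProtocols()
  expect_named(ps, c("activation", "inactivation", "recovery"))
  # activation: 16 test voltages, -100 to +50 in 10 mV increments
  expect_equal(nSweeps(ps$activation), 16L)
  expect_equal(sweepValues(ps$activation), seq(-100, 50, 10))
  expect_equal(holdingVoltage(ps$activation), -80)
  # inactivation: 150 ms pre-pulses, -150 to 0, tail at -10 mV
  expect_equal(nSweeps(ps$inactivation), 16L)
  pre <- ps$inactivation@epochs
  expect_equal(pre$duration_ms[pre$label == "prepulse"], 150)
  expect_equal(pre$voltage_mV[pre$label == "tail"], -10)
  # recovery: the displayed interval ladder plus longer points
  expect_true(all(c(0, 1, 2, 5, 10, 20) %in% sweepValues(ps$recovery)))
  # degenerate interval: P2 immediately follows P1
  et0 <- epochTimes(ps$recovery, which(sweepValues(ps$recovery) == 0))
  expect_equal(et0$start_ms[et0$label == "P2"],
               et0$end_ms[et0$label == "P1"])
  for (p in ps) expect_true(validObject(p))
})

test_that("simulated sweeps obey the conductance and polarity contracts", {
  prot <- stepProtocol(c(-100, 0))
  # zero conductance: currents identically zero without noise
  z <- simulateSweep(makeParams(gmaxDensity = 0), 12, prot, 2L)
  expect_true(all(z == 0))
  # inward current is negative at a 0 mV step (V < Erev)
  tr <- simulateSweep(makeParams(gmaxDensity = 0.5), 12, prot, 2L)
  expect_lt(min(tr), -100)
  expect_equal(tr[which.max(abs(tr))], min(tr))
  # a step to -100 mV deactivates: no transient inward peak
  tr2 <- simulateSweep(makeParams(gmaxDensity = 0.5), 12, prot, 1L)
  expect_lt(max(abs(tr2)), 1)
  # peak magnitude is linear in gmax with everything else fixed
  tr4 <- simulateSweep(makeParams(gmaxDensity = 2), 12, prot, 2L)
  expect_equal(min(tr4) / min(tr), 4, tolerance = 1e-10)
})

test_that("holding-state current starts at its equilibrium value", {
  prot <- stepProtocol(0, holdMs = 5)
  p <- makeParams(gmaxDensity = 0.5)
  tr <- simulateSweep(p, 12, prot, 1L)
  # within the holding epoch the current equals the closed-form equilibrium
  eq <- instantPeak(p, 12, -80)
  expect_equal(tr[10], eq, tolerance = 1e-6)
  expect_lt(abs(eq), 2)   # near zero for wild-type parameters at -80 mV
})

test_that("instantaneous-gating limit reproduces the closed-form peak", {
  # with fast kinetics and non-inactivating h at the step voltage the
  # steady current equals gmax * C * m_inf^p * h_inf * (V - Erev)
  p <- makeParams(gmaxDensity = 0.5, inactV12mV = 50, tauActms = 0.05,
                  tauInact0mVms = 1, tauRecM80mVms = 1)
  prot <- stepProtocol(c(-30, 0, 20), dt = 0.01)
  for (i in 1:3) {
    tr <- simulateSweep(p, 10, prot, i)
    V <- sweepValues(prot)[i]
    expect_equal(tr[length(tr)], instantPeak(p, 10, V), tolerance = 1e-3)
    expect_equal(min(tr), instantPeak(p, 10, V), tolerance = 5e-3)
  }
})

test_that("the simulator refuses sampling coarser than tau/5", {
  prot <- stepProtocol(0, dt = 0.02)   # tau_m = 0.03 ms at 0 mV
  expect_error(simulateSweep(wildTypeParams(), 12, prot, 1L), "accuracy")
  # fine sampling is accepted
  expect_silent(simulateSweep(wildTypeParams(), 12, stepProtocol(0), 1L))
})

test_that("noise streams are reproducible and seed-sensitive", {
  prot <- stepProtocol(0, stepMs = 5)
  p <- makeParams(gmaxDensity = 0.5)
  set.seed(42); a <- simulateSweep(p, 12, prot, 1L, noiseSdpA = 10)
  set.seed(42); b <- simulateSweep(p, 12, prot, 1L, noiseSdpA = 10)
  set.seed(43); c <- simulateSweep(p, 12, prot, 1L, noiseSdpA = 10)
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("cohort generation respects size, variability and seeds", {
  # empty cohort
  coh0 <- generateCohort(cohortSpec("X", 0, seed = 1))
  expect_length(coh0$cells, 0)
  expect_equal(nrow(coh0$truth), 0)
  # cv = 0: every cell shares the cohort means exactly
  protos <- buildStandardProtocols()
  spec <- cohortSpec("WT", 3, noiseSdpA = 0, seed = 5)
  coh <- generateCohort(spec, protos, noise = FALSE)
  expect_length(coh$cells, 3)
  expect_equal(unique(coh$truth$act_V12_mV), -19.5)
  expect_equal(unique(coh$truth$tau_rec_ms), 5.63)
  expect_equal(unique(coh$truth$Ipeak_density_pA_per_pF), -127.5)
  # capacitance still varies cell to cell
  expect_gt(stats::sd(coh$truth$capacitance_pF), 0)
  # determinism: identical spec+seed gives identical recordings
  coh2 <- generateCohort(spec, protos, noise = FALSE)
  expect_identical(coh$cells[[2]]@recordings, coh2$cells[[2]]@recordings)
  spec3 <- cohortSpec("WT", 3, noiseSdpA = 0, seed = 6)
  coh3 <- generateCohort(spec3, protos, noise = FALSE)
  expect_false(identical(coh$cells[[1]]@recordings,
                         coh3$cells[[1]]@recordings))
})
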