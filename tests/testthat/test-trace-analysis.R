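test_that("peak measurement preserves sign and subtracts baseline", {
  t <- seq(0.1, 20, by = 0.1)
  expect_equal(peakCurrent(rep(0, length(t)), t, c(5, 15)), 0)
  # constructed single negative deflection
  tr <- -1200 * exp(-((t - 10) / 1.5)^2)
  expect_equal(peakCurrent(tr, t, c(5, 15), smoothN = 1L), -1200)
  # baseline offset is removed using the pre-step window
  expect_equal(peakCurrent(tr + 250, t, c(5, 15), baselineWindow = c(0, 2),
                           smoothN = 1L), -1200, tolerance = 1e-6)
  # positive deflections keep their sign
  expect_equal(peakCurrent(-tr, t, c(5, 15), smoothN = 1L), 1200)
  expect_error(peakCurrent(tr, t, c(30, 40)), "window")
})

test_that("reversal potential comes from the depolarised I-V limb", {
  V <- seq(-100, 50, 10)
  G <- steadyStateGate(V, -19.5, 6.4, "increasing")
  I <- 40 * G * (V - 65)
  # an exactly linear limb extrapolates exactly
  expect_equal(estimateReversal(V, 40 * (V - 65)), 65, tolerance = 1e-9)
  # residual gating curvature in the limb leaves a sub-0.1 mV error
  expect_equal(estimateReversal(V, I), 65, tolerance = 2e-3)
  # scale invariance
  expect_equal(estimateReversal(V, 7.3 * I), estimateReversal(V, I))
  # degenerate input falls back with a warning
  expect_warning(er <- estimateReversal(V, rep(0, length(V))), "fallback")
  expect_equal(er, 65)
  expect_warning(er2 <- estimateReversal(V, rep(0, length(V)),
                                         fallback = 60), "fallback")
  expect_equal(er2, 60)
})

test_that("conductance transform divides by driving force", {
  gv <- conductanceCurve(0, -1000, 65)
  expect_equal(gv$G, -1000 / (0 - 65))           # 15.38 nS
  expect_equal(conductanceCurve(c(-20, 0, 20), c(0, 0, 0), 65)$G,
               c(0, 0, 0))
  # points near the reversal potential are excluded
  gv2 <- conductanceCurve(seq(-100, 70, 5), rep(1, 35), 65)
  expect_false(any(abs(gv2$V - 65) < 5))
  # simulated instantaneous-gating currents return the gating curve shape
  V <- seq(-100, 50, 10)
  act <- steadyStateGate(V, -19.5, 6.4, "increasing")
  avail <- steadyStateGate(V, -90, 8, "decreasing")
  I <- 12 * act * avail * (V - 65)
  gv3 <- conductanceCurve(V, I, 65)
  expect_equal(gv3$G / max(gv3$G),
               (act * avail)[abs(V - 65) >= 5] / max(act * avail),
               tolerance = 1e-12)
})

test_that("Boltzmann fits recover exact parameters and stay equivariant", {
  V <- seq(-100, 50, 10)
  y <- 3.2 / (1 + exp((-19.5 - V) / 6.4))
  f <- fitBoltzmann(V, y, "increasing")
  expect_true(f@converged)
  expect_equal(f@V12mV, -19.5, tolerance = 1e-6)
  expect_equal(f@VslopemV, 6.4, tolerance = 1e-6)
  expect_equal(f@A, 3.2, tolerance = 1e-6)
  expect_equal(f@B, 0, tolerance = 1e-6)
  # the fitted value at V12 is the mid-amplitude (A+B)/2
  expect_equal(predictBoltzmann(f, f@V12mV), (f@A + f@B) / 2)
  # decreasing orientation: A is the hyperpolarised maximum
  yd <- 0.2 + 0.8 / (1 + exp((V + 65.3) / 5.4))
  fd <- fitBoltzmann(V, yd, "decreasing")
  expect_equal(fd@V12mV, -65.3, tolerance = 1e-6)
  expect_equal(fd@VslopemV, 5.4, tolerance = 1e-6)
  expect_equal(fd@A, 1.0, tolerance = 1e-6)
  expect_equal(fd@B, 0.2, tolerance = 1e-6)
  # equivariance: shifting voltages shifts V12, slope unchanged
  set.seed(31)
  yn <- y + rnorm(length(V), 0, 0.05)
  f0 <- fitBoltzmann(V, yn, "increasing")
  fs <- fitBoltzmann(V + 12.5, yn, "increasing")
  expect_equal(fs@V12mV - f0@V12mV, 12.5, tolerance = 1e-6)
  expect_equal(fs@VslopemV, f0@VslopemV, tolerance = 1e-6)
})

test_that("noisy Boltzmann fits agree with a grid-search oracle", {
  V <- seq(-100, 50, 10)
  truth <- 1 / (1 + exp((-19.5 - V) / 6.4))
  set.seed(77)
  y <- truth + rnorm(length(V), 0, 0.03)
  f <- fitBoltzmann(V, y, "increasing")
  # oracle: dense grid over (V12, slope); A and B solved linearly at each
  # grid point (the model is linear in them)
  gridFit <- function(v12s, slopes) {
    best <- c(rss = Inf, v12 = NA, slope = NA)
    for (v12 in v12s) for (s in slopes) {
      b <- 1 / (1 + exp((v12 - V) / s))
      co <- stats::coef(stats::lm(y ~ b))
      r <- sum((y - co[1] - co[2] * b)^2)
      if (r < best["rss"]) best <- c(rss = r, v12 = v12, slope = s)
    }
    best
  }
  co <- gridFit(seq(-30, -10, 0.5), seq(4, 9, 0.25))
  co <- gridFit(seq(co["v12"] - 0.5, co["v12"] + 0.5, 0.02),
                seq(co["slope"] - 0.25, co["slope"] + 0.25, 0.01))
  expect_equal(f@V12mV, unname(co["v12"]), tolerance = 0.03)
  expect_equal(f@VslopemV, unname(co["slope"]), tolerance = 0.02)
  expect_lte(f@rss, co[["rss"]] + 1e-10)   # NLS at least as good as the grid
})

test_that("normalisation maps the fitted asymptotes to 0 and 1", {
  V <- seq(-150, 0, 10)
  y <- 40 + 360 / (1 + exp((V + 65.3) / 5.4))
  f <- fitBoltzmann(V, y, "decreasing")
  expect_equal(normalizeToFit(f@B, f), 0)
  expect_equal(normalizeToFit(f@A, f), 1)
  expect_equal(normalizeToFit((f@A + f@B) / 2, f), 0.5)
  # normalising then re-fitting returns the same midpoint and slope
  f2 <- fitBoltzmann(V, normalizeToFit(y, f), "decreasing")
  expect_equal(f2@V12mV, f@V12mV, tolerance = 1e-6)
  expect_equal(f2@VslopemV, f@VslopemV, tolerance = 1e-6)
  expect_equal(f2@A, 1, tolerance = 1e-6)
  expect_equal(f2@B, 0, tolerance = 1e-6)
  bad <- new("BoltzmannFit", A = 1, B = 0, V12mV = 0, VslopemV = 1,
             direction = "increasing", rss = NA_real_, converged = FALSE)
  expect_error(normalizeToFit(0.5, bad), "non-converged")
})

test_that("exponential fits recover exact time constants", {
  t <- seq(0, 40, 0.25)
  y <- 0.4 + 2.5 * exp(-t / 5.63)
  f <- fitExponential(t, y, 1L)
  expect_true(f@converged)
  expect_equal(unname(f@components[1, "tau_ms"]), 5.63, tolerance = 1e-6)
  expect_equal(unname(f@components[1, "amplitude"]), 2.5, tolerance = 1e-6)
  expect_equal(f@offset, 0.4, tolerance = 1e-6)
  # double exponential, 95%/5% amplitude split
  t2 <- seq(0, 15, 0.02)
  y2 <- 950 * exp(-t2 / 0.3) + 50 * exp(-t2 / 3)
  f2 <- fitExponential(t2, y2, 2L)
  expect_true(f2@converged)
  expect_equal(nrow(f2@components), 2L)
  expect_equal(unname(f2@components[1, "tau_ms"]), 0.3, tolerance = 1e-4)
  expect_equal(f2@fastFraction, 0.95, tolerance = 1e-4)
  # a fast fraction below 0.95 is recorded as a note
  y3 <- 600 * exp(-t2 / 0.3) + 400 * exp(-t2 / 3)
  f3 <- fitExponential(t2, y3, 2L)
  expect_true(any(grepl("fast component", f3@notes)))
  # constant input: zero-amplitude fit flagged degenerate
  fc <- fitExponential(t, rep(2, length(t)), 1L)
  expect_false(fc@converged)
  expect_equal(unname(fc@components[1, "amplitude"]), 0)
})

test_that("exponential fits rescale exactly with time", {
  t <- seq(0, 30, 0.5)
  set.seed(9)
  y <- 3 * exp(-t / 4.2) + rnorm(length(t), 0, 0.02)
  f1 <- fitExponential(t, y, 1L)
  f2 <- fitExponential(3 * t, y, 1L)
  expect_equal(unname(f2@components[1, "tau_ms"]), 3 * unname(f1@components[1, "tau_ms"]),
               tolerance = 1e-6)
  expect_equal(unname(f2@components[1, "amplitude"]), unname(f1@components[1, "amplitude"]),
               tolerance = 1e-6)
})

test_that("recovery fits pin the asymptote at one", {
  dt <- c(0, 1, 2, 5, 10, 20, 30, 50)
  r <- 1 - 0.98 * exp(-dt / 5.63)
  f <- fitRecovery(dt, r)
  expect_true(f@converged)
  expect_equal(f@offset, 1)
  expect_equal(unname(f@components[1, "tau_ms"]), 5.63, tolerance = 1e-6)
  expect_equal(unname(f@components[1, "amplitude"]), -0.98, tolerance = 1e-6)
})

test_that("QC tiers follow the current-amplitude and Rs-error cuts", {
  rows <- data.frame(
    cell_id = c("a", "b", "c", "d"), variant_id = "X",
    Ipeak_0mV_pA = c(-400, -2000, -50, -1500),
    Rs_error_mV = c(abs(-400) * 2e-3, abs(-2000) * 3e-3,
                    abs(-50) * 2e-3, abs(-1500) * 2e-3))
  qc <- qcFilter(rows)
  # -0.4 nA: density tier only
  expect_true(qc$qc_density_pass[1]); expect_false(qc$qc_biophysics_pass[1])
  # -2 nA at 3 MOhm: Rs error 6 mV excludes from the biophysics tier
  expect_equal(qc$Rs_error_mV[2], 6)
  expect_true(qc$qc_density_pass[2]); expect_false(qc$qc_biophysics_pass[2])
  # -0.05 nA: excluded from both
  expect_false(qc$qc_density_pass[3]); expect_false(qc$qc_biophysics_pass[3])
  # -1.5 nA at 2 MOhm: both tiers
  expect_true(qc$qc_biophysics_pass[4])
  # nesting holds for arbitrary inputs
  set.seed(12)
  rnd <- data.frame(cell_id = as.character(1:200), variant_id = "Y",
                    Ipeak_0mV_pA = -exp(runif(200, 2, 9)),
                    Rs_error_mV = runif(200, 0, 10))
  qr <- qcFilter(rnd)
  expect_true(all(qr$qc_density_pass[qr$qc_biophysics_pass]))
})

test_that("variant summaries use the right tier and SE definition", {
  rows <- data.frame(
    cell_id = sprintf("c%d", 1:3), variant_id = "V",
    Ipeak_0mV_pA = c(-300, -800, -900),
    Ipeak_density_pA_per_pF = c(-30, -80, -90),
    act_V12_mV = c(-19, -20, -21), act_Vslope_mV = 6.4,
    inact_V12_mV = -65, inact_Vslope_mV = 5.4,
    tau_inact_0mV_ms = 0.3, tau_rec_ms = c(5.5, 5.7, NA),
    Rs_error_mV = 1)
  s <- summarizeVariant(qcFilter(rows))
  dens <- s[s$parameter == "Ipeak_density_pA_per_pF", ]
  expect_equal(dens$n, 3L)     # density tier includes the -0.3 nA cell
  av <- s[s$parameter == "act_V12_mV", ]
  expect_equal(av$n, 2L)       # biophysics tier drops it
  expect_equal(av$mean, -20.5)
  expect_equal(av$se, stats::sd(c(-20, -21)) / sqrt(2))
  tr <- s[s$parameter == "tau_rec_ms", ]
  expect_equal(tr$n, 1L)       # NA excluded; single cell
  expect_equal(tr$se, 0)       # SE undefined, reported 0 with flag
  expect_false(tr$se_defined)
  # duplicate cells give SE exactly 0
  dup <- rows[c(2, 2), ]; dup$cell_id <- c("d1", "d2")
  s2 <- summarizeVariant(qcFilter(dup))
  expect_equal(s2$se[s2$parameter == "act_V12_mV"], 0)
})
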