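#' @include AllClasses.R AllGenerics.R
NULL

#' Steady-state Boltzmann occupancy of a voltage-dependent gate
#'
#' Two-state Boltzmann curve used both for the activation conductance target
#' and for the fast-inactivation availability curve.  The increasing form is
#' \eqn{1/(1+\exp((V_{1/2}-V)/k))}; the decreasing form mirrors it,
#' \eqn{1/(1+\exp((V-V_{1/2})/k))}.  Both equal 0.5 at \code{V12} and are
#' strictly monotone in \code{V}.
#'
#' @param V test voltage(s), mV.
#' @param V12 midpoint voltage, mV.
#' @param slope slope factor, mV (must be > 0).
#' @param direction \code{"increasing"} (activation) or \code{"decreasing"}
#'   (availability).
#' @return occupancy in [0, 1], same length as \code{V}.
#' @examples
#' steadyStateGate(-65.3, -65.3, 5.4, "decreasing")  # 0.5 at the midpoint
#' @export
steadyStateGate <- function(V, V12, slope,
                            direction = c("increasing", "decreasing")) {
  direction <- match.arg(direction)
  if (!is.numeric(slope) || length(slope) != 1L || !is.finite(slope) ||
      slope <= 0)
    stop("invalid parameter: slope factor must be a single positive number")
  if (direction == "increasing") 1 / (1 + exp((V12 - V) / slope))
  else 1 / (1 + exp((V - V12) / slope))
}

## Activation gate steady state: the p-th root of the target activation
## Boltzmann, so that gmax * m^p reproduces the Boltzmann exactly.
mInf <- function(V, params) {
  steadyStateGate(V, params@actV12mV, params@actSlopemV,
                  "increasing")^(1 / params@gateExponent)
}

hInf <- function(V, params) {
  steadyStateGate(V, params@inactV12mV, params@inactSlopemV, "decreasing")
}

tauH <- function(V, params) {
  t0 <- params@tauInact0mVms     # onset anchor at 0 mV
  tR <- params@tauRecM80mVms     # recovery anchor at -80 mV
  f <- pmin(pmax((V + 80) / 80, 0), 1)   # clamp outside [-80, 0]
  exp(log(tR) + f * (log(t0) - log(tR)))
}

tauM <- function(V, params) {
  params@tauActms * tauH(V, params) / params@tauInact0mVms
}

#' Voltage dependence of the gating time constants
#'
#' The inactivation time constant is a log-linear interpolation in voltage
#' between the two measured anchors (the open-state onset time constant at
#' 0 mV and the recovery time constant at -80 mV), clamped outside that
#' range.  The activation time constant is proportional to it
#' (\code{tauActms} at 0 mV), which makes the peak-current conductance
#' readout voltage-independent (see the methods vignette).
#'
#' @param V voltage(s) in mV, within [-150, 50].
#' @param params a [GatingParams].
#' @param gate \code{"activation"} or \code{"inactivation"}.
#' @return time constant(s), ms.
#' @examples
#' p <- wildTypeParams()
#' gateTimeConstant(0, p, "inactivation")    # the 0 mV onset anchor
#' gateTimeConstant(-80, p, "inactivation")  # the -80 mV recovery anchor
#' @export
gateTimeConstant <- function(V, params,
                             gate = c("activation", "inactivation")) {
  gate <- match.arg(gate)
  validObject(params)
  if (any(V < -150 | V > 50))
    stop("voltage out of supported range [-150, 50] mV")
  if (gate == "inactivation") tauH(V, params) else tauM(V, params)
}

#' Wild-type gating parameters
#'
#' Central NaV1.4 wild-type parameter set used as the default simulation
#' target: activation midpoint -19.5 mV (slope 6.4), fast-inactivation
#' midpoint -65.3 mV (slope 5.4), open-state inactivation time constant
#' 0.30 ms at 0 mV, recovery time constant 5.63 ms at -80 mV, reversal
#' +65 mV, m^3 h gating.
#'
#' @param gmaxDensity maximal conductance density, nS/pF.
#' @return a [GatingParams].
#' @export
wildTypeParams <- function(gmaxDensity = 1) {
  new("GatingParams", gmaxDensity = gmaxDensity)
}

## Piecewise-constant voltage segments for one sweep, including the trailing
## holding-pad that equalises total duration across duration-varying sweeps.
protocolSegments <- function(protocol, sweepIndex) {
  ep <- protocol@epochs
  v <- ep$voltage_mV
  d <- ep$duration_ms
  sv <- protocol@sweepValues[sweepIndex]
  if (protocol@sweepDim == "voltage") v[is.na(v)] <- sv else d[is.na(d)] <- sv
  segs <- data.frame(label = ep$label, voltage_mV = v, duration_ms = d,
                     stringsAsFactors = FALSE)
  if (protocol@sweepDim == "duration") {
    pad <- max(protocol@sweepValues) - sv
    if (pad > 0)
      segs <- rbind(segs, data.frame(label = "pad", voltage_mV =
                    protocol@holdingmV, duration_ms = pad))
  }
  segs <- segs[segs$duration_ms > 0, , drop = FALSE]
  rownames(segs) <- NULL
  segs
}

#' Total duration of a protocol sweep (ms)
#'
#' For duration-varying protocols this is the common padded duration shared
#' by every sweep.
#'
#' @param protocol a [VoltageProtocol].
#' @return duration in ms.
#' @export
protocolTotalDuration <- function(protocol) {
  d <- sum(protocol@epochs$duration_ms, na.rm = TRUE)
  if (protocol@sweepDim == "duration") d <- d + max(protocol@sweepValues)
  d
}

#' Epoch onset/offset times for one sweep
#'
#' @param protocol a [VoltageProtocol].
#' @param sweepIndex sweep number.
#' @return data.frame with \code{label}, \code{voltage_mV}, \code{start_ms},
#'   \code{end_ms}.
#' @export
epochTimes <- function(protocol, sweepIndex = 1L) {
  segs <- protocolSegments(protocol, sweepIndex)
  end <- cumsum(segs$duration_ms)
  data.frame(label = segs$label, voltage_mV = segs$voltage_mV,
             start_ms = c(0, end[-length(end)]), end_ms = end,
             stringsAsFactors = FALSE)
}

#' Sample times of a simulated sweep (ms)
#'
#' Samples are taken at the end of each sampling interval:
#' \code{dt, 2 dt, ...}.
#'
#' @param protocol a [VoltageProtocol].
#' @return numeric vector of times in ms.
#' @export
sweepTimes <- function(protocol) {
  n <- round(protocolTotalDuration(protocol) / protocol@sampleIntervalMs)
  seq_len(n) * protocol@sampleIntervalMs
}

#' Simulate one whole-cell current sweep
#'
#' Integrates the Hodgkin-Huxley style gating model
#' \eqn{dm/dt = (m_\infty - m)/\tau_m}, \eqn{dh/dt = (h_\infty - h)/\tau_h}
#' across the protocol's constant-voltage epochs (the per-epoch solution is
#' the exact exponential relaxation, evaluated on the sample grid) and
#' returns the current
#' \eqn{I(t) = g_{max} C\, m^p h (V - E_{rev})} in pA, with optional
#' additive Gaussian noise.  Gating state starts at equilibrium for the
#' holding potential.  Inward current is negative.  The result is
#' deterministic for a fixed RNG state (\code{set.seed}).
#'
#' @param params a [GatingParams].
#' @param capacitancepF cell capacitance, pF.
#' @param protocol a [VoltageProtocol].
#' @param sweepIndex which sweep to simulate.
#' @param noiseSdpA additive white Gaussian noise sd in pA (0 = noiseless).
#' @return numeric vector of currents (pA) at [sweepTimes()].
#' @examples
#' prot <- buildStandardProtocols()$activation
#' set.seed(1)
#' i0 <- simulateSweep(wildTypeParams(0.5), 12, prot, which(
#'   sweepValues(prot) == 0), noiseSdpA = 0)
#' min(i0)  # peak inward current at the 0 mV step
#' @export
simulateSweep <- function(params, capacitancepF, protocol, sweepIndex,
                          noiseSdpA = 0) {
  validObject(params)
  validObject(protocol)
  if (sweepIndex < 1 || sweepIndex > nSweeps(protocol))
    stop("sweepIndex out of range")
  dt <- protocol@sampleIntervalMs
  segs <- protocolSegments(protocol, sweepIndex)
  tm <- tauM(segs$voltage_mV, params)
  th <- tauH(segs$voltage_mV, params)
  if (dt > min(tm, th) / 5)
    stop("sample interval ", dt, " ms exceeds one fifth of the smallest ",
         "gating time constant (", signif(min(tm, th), 3),
         " ms); refusing for accuracy")
  g <- params@gmaxDensity * capacitancepF    # nS
  p <- params@gateExponent
  m <- mInf(protocol@holdingmV, params)
  h <- hInf(protocol@holdingmV, params)
  nTot <- round(protocolTotalDuration(protocol) / dt)
  out <- numeric(nTot)
  at <- 0L
  for (i in seq_len(nrow(segs))) {
    V <- segs$voltage_mV[i]
    n <- round(segs$duration_ms[i] / dt)
    if (n > 0) {
      tl <- seq_len(n) * dt
      mi <- mInf(V, params); hi <- hInf(V, params)
      em <- exp(-tl / tm[i]); eh <- exp(-tl / th[i])
      mt <- mi + (m - mi) * em
      ht <- hi + (h - hi) * eh
      out[at + seq_len(n)] <- g * mt^p * ht * (V - params@eRevmV)
      m <- mt[n]; h <- ht[n]
      at <- at + n
    }
  }
  if (noiseSdpA > 0) out <- out + stats::rnorm(nTot, 0, noiseSdpA)
  out
}

#' Simulate all sweeps of a protocol
#'
#' @inheritParams simulateSweep
#' @return time x sweep matrix of currents (pA); columns named by sweep
#'   value.
#' @export
simulateProtocol <- function(params, capacitancepF, protocol,
                             noiseSdpA = 0) {
  m <- vapply(seq_len(nSweeps(protocol)),
              function(i) simulateSweep(params, capacitancepF, protocol, i,
                                        noiseSdpA),
              numeric(round(protocolTotalDuration(protocol) /
                            protocol@sampleIntervalMs)))
  colnames(m) <- as.character(protocol@sweepValues)
  m
}

#' Calibrate maximal conductance for a target peak current density
#'
#' The peak current at a 0 mV test step is attenuated relative to the
#' instantaneous-gating limit because inactivation develops while the
#' activation gates open.  This helper runs one noiseless probe sweep at
#' unit conductance density and returns the \code{gmaxDensity} for which the
#' measured peak current density at 0 mV equals \code{targetDensity}.
#'
#' @param params a [GatingParams] (its \code{gmaxDensity} is ignored).
#' @param targetDensity desired peak current density at 0 mV, pA/pF
#'   (negative for inward current).
#' @param sampleIntervalMs probe sampling interval, ms.
#' @return conductance density in nS/pF.
#' @export
gmaxForPeakDensity <- function(params, targetDensity,
                               sampleIntervalMs = 0.005) {
  probe <- new("VoltageProtocol", name = "probe",
               holdingmV = -80,
               epochs = data.frame(label = c("hold", "test"),
                                   voltage_mV = c(-80, NA),
                                   duration_ms = c(5, 20)),
               sweepValues = 0, sweepDim = "voltage",
               sampleIntervalMs = sampleIntervalMs)
  unitParams <- params
  unitParams@gmaxDensity <- 1
  tr <- simulateSweep(unitParams, 1, probe, 1L, noiseSdpA = 0)
  peak <- tr[which.max(abs(tr))]
  if (abs(peak) < .Machine$double.eps)
    stop("probe sweep produced no current; cannot calibrate gmax")
  targetDensity / peak
}
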