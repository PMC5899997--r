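#' @import methods
NULL

#' Epoch-based description of a voltage-clamp experiment
#'
#' A \code{VoltageProtocol} describes one clamp experiment as an ordered list
#' of constant-voltage epochs.  Exactly one epoch may vary across sweeps,
#' either in its command voltage (\code{sweepDim = "voltage"}) or in its
#' duration (\code{sweepDim = "duration"}); the per-sweep values are stored in
#' \code{sweepValues}.  Duration-varying protocols are padded at the holding
#' potential so that every sweep has the same total duration.
#'
#' @slot name single character, protocol identifier.
#' @slot holdingmV holding potential in mV; gating state is initialised at
#'   equilibrium for this voltage.
#' @slot epochs data.frame with columns \code{label}, \code{voltage_mV} and
#'   \code{duration_ms}; \code{NA} in \code{voltage_mV} (or
#'   \code{duration_ms}) marks the sweep-varying epoch.
#' @slot sweepValues numeric vector of voltages (mV) or durations (ms)
#'   substituted into the sweep-varying epoch, one per sweep.
#' @slot sweepDim either \code{"voltage"} or \code{"duration"}.
#' @slot sampleIntervalMs sampling interval in ms.
#'
#' @seealso [buildStandardProtocols()], [simulateSweep()]
#' @export
setClass("VoltageProtocol",
  representation(
    name = "character",
    holdingmV = "numeric",
    epochs = "data.frame",
    sweepValues = "numeric",
    sweepDim = "character",
    sampleIntervalMs = "numeric"
  )
)

setValidity("VoltageProtocol", function(object) {
  msg <- character()
  ep <- object@epochs
  if (!all(c("label", "voltage_mV", "duration_ms") %in% names(ep)))
    msg <- c(msg, "epochs must have columns label, voltage_mV, duration_ms")
  else {
    nVarV <- sum(is.na(ep$voltage_mV))
    nVarD <- sum(is.na(ep$duration_ms))
    if (nVarV + nVarD != 1L)
      msg <- c(msg, "exactly one epoch must be sweep-varying (one NA field)")
    if (!identical(object@sweepDim, "voltage") &&
        !identical(object@sweepDim, "duration"))
      msg <- c(msg, "sweepDim must be 'voltage' or 'duration'")
    if (identical(object@sweepDim, "voltage") && nVarV != 1L)
      msg <- c(msg, "sweepDim 'voltage' requires one NA voltage_mV epoch")
    if (identical(object@sweepDim, "duration") && nVarD != 1L)
      msg <- c(msg, "sweepDim 'duration' requires one NA duration_ms epoch")
    durs <- ep$duration_ms[!is.na(ep$duration_ms)]
    if (any(durs <= 0)) msg <- c(msg, "all epoch durations must be > 0")
  }
  if (length(object@sampleIntervalMs) != 1L || object@sampleIntervalMs <= 0)
    msg <- c(msg, "sampleIntervalMs must be a single positive number")
  if (length(object@sweepValues) < 1L)
    msg <- c(msg, "at least one sweep value is required")
  if (identical(object@sweepDim, "duration") && any(object@sweepValues < 0))
    msg <- c(msg, "sweep durations must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Ground-truth gating parameters of a simulated channel population
#'
#' Holds the Hodgkin-Huxley-style parameters from which whole-cell currents
#' are simulated: maximal conductance density, reversal potential, Boltzmann
#' midpoints/slopes for activation and fast inactivation, the open-state
#' inactivation time constant at 0 mV, the recovery time constant at -80 mV,
#' the activation time-constant scale and the activation gate exponent.
#'
#' The two inactivation time constants anchor a log-linear interpolation of
#' tau_h(V) between -80 and 0 mV (clamped outside); the activation time
#' constant is proportional to tau_h so that the peak-current conductance
#' readout is unbiased (see the methods vignette).
#'
#' @slot gmaxDensity maximal conductance per capacitance, nS/pF.
#' @slot eRevmV reversal potential, mV.
#' @slot actV12mV,actSlopemV activation Boltzmann midpoint and slope (mV).
#' @slot inactV12mV,inactSlopemV fast-inactivation midpoint and slope (mV).
#' @slot tauInact0mVms open-state fast-inactivation time constant at 0 mV (ms).
#' @slot tauRecM80mVms recovery time constant at -80 mV (ms).
#' @slot tauActms activation time constant at 0 mV (ms).
#' @slot gateExponent positive integer, activation gate exponent.
#' @export
setClass("GatingParams",
  representation(
    gmaxDensity = "numeric",
    eRevmV = "numeric",
    actV12mV = "numeric",
    actSlopemV = "numeric",
    inactV12mV = "numeric",
    inactSlopemV = "numeric",
    tauInact0mVms = "numeric",
    tauRecM80mVms = "numeric",
    tauActms = "numeric",
    gateExponent = "numeric"
  ),
  prototype(
    gmaxDensity = 1, eRevmV = 65,
    actV12mV = -19.5, actSlopemV = 6.4,
    inactV12mV = -65.3, inactSlopemV = 5.4,
    tauInact0mVms = 0.30, tauRecM80mVms = 5.63,
    tauActms = 0.03, gateExponent = 3
  )
)

setValidity("GatingParams", function(object) {
  msg <- character()
  one <- function(x) length(x) == 1L && is.finite(x)
  for (s in c("gmaxDensity", "eRevmV", "actV12mV", "actSlopemV", "inactV12mV",
              "inactSlopemV", "tauInact0mVms", "tauRecM80mVms", "tauActms",
              "gateExponent"))
    if (!one(slot(object, s))) msg <- c(msg, paste(s, "must be a single finite number"))
  if (!length(msg)) {
    if (object@actSlopemV <= 0 || object@inactSlopemV <= 0)
      msg <- c(msg, "slope factors must be > 0")
    if (object@tauInact0mVms <= 0 || object@tauRecM80mVms <= 0 ||
        object@tauActms <= 0)
      msg <- c(msg, "time constants must be > 0")
    if (object@gmaxDensity < 0) msg <- c(msg, "gmaxDensity must be >= 0")
    if (object@gateExponent < 1 || object@gateExponent != round(object@gateExponent))
      msg <- c(msg, "gateExponent must be a positive integer")
  }
  if (length(msg)) msg else TRUE
})

#' Specification of a simulated cell cohort
#'
#' Describes one variant's cohort of virtual cells: the central gating
#' parameters, per-field coefficients of variation for the cell-to-cell
#' draws, the target peak current density at 0 mV, capacitance and series
#' resistance distributions, current noise and the cohort seed.
#'
#' @slot variantId cohort/variant label.
#' @slot nCells number of cells to simulate.
#' @slot paramMeans a [GatingParams] with the cohort's central parameters.
#' @slot peakDensityMean target mean peak current density at 0 mV (pA/pF,
#'   negative for inward current); the per-cell maximal conductance is
#'   calibrated so that a noiseless measurement returns this density.
#' @slot paramCV named numeric of per-field coefficients of variation; names
#'   among \code{peakDensity, actV12, actSlope, inactV12, inactSlope,
#'   tauInact, tauRec}.  Voltages are drawn normal with sd = |mean| * cv,
#'   positive quantities log-normal with the same cv.
#' @slot capacitancepF length-2 numeric \code{(mean, sd)} in pF.
#' @slot seriesResistanceMOhm length-2 numeric \code{(mean, sd)} in MOhm.
#' @slot noiseSdpA additive Gaussian current noise sd, pA.
#' @slot seed integer cohort seed.
#' @export
setClass("CohortSpec",
  representation(
    variantId = "character",
    nCells = "numeric",
    paramMeans = "GatingParams",
    peakDensityMean = "numeric",
    paramCV = "numeric",
    capacitancepF = "numeric",
    seriesResistanceMOhm = "numeric",
    noiseSdpA = "numeric",
    seed = "numeric"
  ),
  prototype(
    variantId = "WT", nCells = 1L,
    peakDensityMean = -127.5,
    paramCV = c(peakDensity = 0, actV12 = 0, actSlope = 0, inactV12 = 0,
                inactSlope = 0, tauInact = 0, tauRec = 0),
    capacitancepF = c(12, 3),
    seriesResistanceMOhm = c(2, 0.5),
    noiseSdpA = 10, seed = 1
  )
)

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (object@nCells < 0 || object@nCells != round(object@nCells))
    msg <- c(msg, "nCells must be a non-negative integer")
  if (any(object@paramCV < 0)) msg <- c(msg, "coefficients of variation must be >= 0")
  if (length(object@capacitancepF) != 2L || object@capacitancepF[1] <= 0)
    msg <- c(msg, "capacitancepF must be (mean, sd) with mean > 0")
  if (length(object@seriesResistanceMOhm) != 2L ||
      object@seriesResistanceMOhm[1] <= 0)
    msg <- c(msg, "seriesResistanceMOhm must be (mean, sd) with mean > 0")
  if (object@noiseSdpA < 0) msg <- c(msg, "noiseSdpA must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Per-cell sweep data for the three clamp protocols
#'
#' Container for one virtual (or imported) cell: sweep matrices keyed by
#' protocol name, together with the protocol definitions, the cell
#' capacitance and the series resistance.  Sweep matrices are time x sweep,
#' in pA.
#'
#' @slot cellId,variantId identifiers.
#' @slot capacitancepF membrane capacitance, pF.
#' @slot seriesResistanceMOhm pipette series resistance, MOhm.
#' @slot recordings named list of time x sweep current matrices (pA).
#' @slot protocols named list of [VoltageProtocol], same names as
#'   \code{recordings}.
#' @export
setClass("CellRecording",
  representation(
    cellId = "character",
    variantId = "character",
    capacitancepF = "numeric",
    seriesResistanceMOhm = "numeric",
    recordings = "list",
    protocols = "list"
  )
)

setValidity("CellRecording", function(object) {
  msg <- character()
  if (!identical(sort(names(object@recordings)), sort(names(object@protocols))))
    msg <- c(msg, "recordings and protocols must share names")
  for (nm in names(object@recordings)) {
    m <- object@recordings[[nm]]
    p <- object@protocols[[nm]]
    if (!is.matrix(m)) { msg <- c(msg, paste0(nm, ": not a matrix")); next }
    if (!all(is.finite(m))) msg <- c(msg, paste0(nm, ": non-finite current values"))
    if (ncol(m) != length(p@sweepValues))
      msg <- c(msg, paste0(nm, ": one column per sweep required"))
    expRows <- round(protocolTotalDuration(p) / p@sampleIntervalMs)
    if (nrow(m) != expRows)
      msg <- c(msg, paste0(nm, ": expected ", expRows, " rows, got ", nrow(m)))
  }
  if (object@capacitancepF <= 0) msg <- c(msg, "capacitancepF must be > 0")
  if (object@seriesResistanceMOhm < 0)
    msg <- c(msg, "seriesResistanceMOhm must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Result of a Boltzmann fit
#'
#' Sigmoid fit of an amplitude-voltage relation,
#' \eqn{y = B + (A - B) / (1 + \exp(\pm(V_{1/2} - V)/V_{slope}))},
#' where \code{A} is the maximum and \code{B} the minimum amplitude and the
#' sign is set by the fitted direction.  \code{V12mV} is the voltage where
#' the amplitude equals \eqn{(A+B)/2}.
#'
#' @slot A,B maximum and minimum fitted amplitudes.
#' @slot V12mV midpoint voltage, mV.
#' @slot VslopemV slope factor, mV (> 0).
#' @slot direction \code{"increasing"} or \code{"decreasing"} in V.
#' @slot rss residual sum of squares.
#' @slot converged logical convergence flag.
#' @export
setClass("BoltzmannFit",
  representation(
    A = "numeric", B = "numeric",
    V12mV = "numeric", VslopemV = "numeric",
    direction = "character",
    rss = "numeric", converged = "logical"
  )
)

setValidity("BoltzmannFit", function(object) {
  msg <- character()
  if (object@converged) {
    if (!is.finite(object@rss)) msg <- c(msg, "converged fit must have finite rss")
    if (object@VslopemV <= 0) msg <- c(msg, "VslopemV must be > 0")
    if (object@A == object@B) msg <- c(msg, "A and B must differ")
  }
  if (length(msg)) msg else TRUE
})

#' Result of a single- or double-exponential fit
#'
#' Fit of \eqn{y(t) = c_0 + \sum_i a_i \exp(-t/\tau_i)}.  Components are
#' sorted fastest first; \code{fastFraction} is the amplitude share of the
#' fastest component.  When a double-exponential is requested the fast
#' component is the primary result; a fast fraction below 0.95 is recorded
#' in \code{notes}.
#'
#' @slot components matrix with columns \code{amplitude} and \code{tau_ms},
#'   sorted by increasing tau.
#' @slot offset fitted asymptote \eqn{c_0}.
#' @slot fastFraction amplitude share of the fastest component, in [0, 1].
#' @slot rss residual sum of squares.
#' @slot converged logical convergence flag.
#' @slot notes character vector of recorded fit warnings.
#' @export
setClass("ExponentialFit",
  representation(
    components = "matrix",
    offset = "numeric",
    fastFraction = "numeric",
    rss = "numeric",
    converged = "logical",
    notes = "character"
  )
)

setValidity("ExponentialFit", function(object) {
  msg <- character()
  cm <- object@components
  if (!all(c("amplitude", "tau_ms") %in% colnames(cm)))
    msg <- c(msg, "components needs columns amplitude, tau_ms")
  else if (object@converged) {
    if (any(cm[, "tau_ms"] <= 0)) msg <- c(msg, "all tau must be > 0")
    if (is.unsorted(cm[, "tau_ms"])) msg <- c(msg, "components must be sorted fastest first")
    if (object@fastFraction < 0 || object@fastFraction > 1)
      msg <- c(msg, "fastFraction must be in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Two-pulse recovery-from-inactivation curve
#'
#' Peak-current ratios P2/P1 against the recovery interval at the recovery
#' voltage.
#'
#' @slot intervalsMs recovery intervals, ms.
#' @slot ratio P2/P1 peak-current ratios, same length.
#' @export
setClass("RecoveryCurve",
  representation(intervalsMs = "numeric", ratio = "numeric")
)

setValidity("RecoveryCurve", function(object) {
  msg <- character()
  if (length(object@intervalsMs) != length(object@ratio))
    msg <- c(msg, "intervals and ratios must have the same length")
  ok <- is.finite(object@ratio)
  if (any(object@ratio[ok] < -0.05 | object@ratio[ok] > 1.05))
    msg <- c(msg, "ratios must lie in [0, 1.05] (up to noise)")
  if (length(msg)) msg else TRUE
})
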