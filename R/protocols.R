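#' @include AllClasses.R gating-model.R
NULL

#' Construct a voltage protocol
#'
#' @param name protocol name.
#' @param holdingmV holding potential, mV.
#' @param epochs data.frame with columns \code{label}, \code{voltage_mV},
#'   \code{duration_ms}; exactly one \code{NA} marks the sweep-varying
#'   field.
#' @param sweepValues per-sweep values (mV or ms) for the varying epoch.
#' @param sweepDim \code{"voltage"} or \code{"duration"}.
#' @param sampleIntervalMs sampling interval, ms.
#' @return a [VoltageProtocol].
#' @export
voltageProtocol <- function(name, holdingmV, epochs, sweepValues,
                            sweepDim = c("voltage", "duration"),
                            sampleIntervalMs = 0.005) {
  sweepDim <- match.arg(sweepDim)
  new("VoltageProtocol", name = name, holdingmV = holdingmV,
      epochs = epochs, sweepValues = as.numeric(sweepValues),
      sweepDim = sweepDim, sampleIntervalMs = sampleIntervalMs)
}

#' The three standard NaV1.4 clamp protocols
#'
#' Builds the protocol set used throughout the package:
#' \describe{
#'   \item{activation}{from -80 mV holding, 20 ms test steps from -100 to
#'     +50 mV in 10 mV increments (16 sweeps).}
#'   \item{inactivation}{150 ms conditioning pre-pulses from -150 to 0 mV in
#'     10 mV increments (16 sweeps), each followed by a 10 ms tail step to
#'     -10 mV; availability is read from the first 5 ms of the tail.}
#'   \item{recovery}{a 10 ms inactivating pulse to 0 mV, a recovery interval
#'     at -80 mV of 0, 1, 2, 5, 10, 20, 30 or 50 ms, then a second 10 ms
#'     test pulse to 0 mV (P2/P1 two-pulse protocol).}
#' }
#' The 30 and 50 ms recovery points extend the displayed six-interval ladder
#' so that the recovery asymptote is sampled.
#'
#' @param sampleIntervalMs sampling interval, ms (default 0.005 ms; the
#'   simulator refuses intervals coarser than one fifth of the fastest
#'   gating time constant).
#' @param holdingmV holding potential, mV.
#' @param recoveryIntervalsMs recovery-interval ladder, ms.
#' @return named list of three [VoltageProtocol] objects.
#' @examples
#' ps <- buildStandardProtocols()
#' nSweeps(ps$activation)   # 16
#' @export
buildStandardProtocols <- function(sampleIntervalMs = 0.005,
                                   holdingmV = -80,
                                   recoveryIntervalsMs =
                                     c(0, 1, 2, 5, 10, 20, 30, 50)) {
  act <- voltageProtocol(
    "activation", holdingmV,
    data.frame(label = c("hold", "test"),
               voltage_mV = c(holdingmV, NA),
               duration_ms = c(5, 20)),
    sweepValues = seq(-100, 50, by = 10),
    sweepDim = "voltage", sampleIntervalMs = sampleIntervalMs)
  inact <- voltageProtocol(
    "inactivation", holdingmV,
    data.frame(label = c("hold", "prepulse", "tail"),
               voltage_mV = c(holdingmV, NA, -10),
               duration_ms = c(5, 150, 10)),
    sweepValues = seq(-150, 0, by = 10),
    sweepDim = "voltage", sampleIntervalMs = sampleIntervalMs)
  rec <- voltageProtocol(
    "recovery", holdingmV,
    data.frame(label = c("hold", "P1", "gap", "P2"),
               voltage_mV = c(holdingmV, 0, -80, 0),
               duration_ms = c(5, 10, NA, 10)),
    sweepValues = recoveryIntervalsMs,
    sweepDim = "duration", sampleIntervalMs = sampleIntervalMs)
  list(activation = act, inactivation = inact, recovery = rec)
}
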