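#' @include AllClasses.R
NULL

#' Number of sweeps of a protocol or recording
#' @param object a [VoltageProtocol].
#' @return integer sweep count.
#' @export
setGeneric("nSweeps", function(object) standardGeneric("nSweeps"))

#' @rdname nSweeps
#' @export
setMethod("nSweeps", "VoltageProtocol", function(object)
  length(object@sweepValues))

#' Sweep-varying values of a protocol
#' @param object a [VoltageProtocol].
#' @return numeric vector of voltages (mV) or durations (ms).
#' @export
setGeneric("sweepValues", function(object) standardGeneric("sweepValues"))

#' @rdname sweepValues
#' @export
setMethod("sweepValues", "VoltageProtocol", function(object) object@sweepValues)

#' Sampling interval of a protocol (ms)
#' @param object a [VoltageProtocol].
#' @export
setGeneric("sampleInterval", function(object) standardGeneric("sampleInterval"))

#' @rdname sampleInterval
#' @export
setMethod("sampleInterval", "VoltageProtocol", function(object)
  object@sampleIntervalMs)

#' Holding potential of a protocol (mV)
#' @param object a [VoltageProtocol].
#' @export
setGeneric("holdingVoltage", function(object) standardGeneric("holdingVoltage"))

#' @rdname holdingVoltage
#' @export
setMethod("holdingVoltage", "VoltageProtocol", function(object)
  object@holdingmV)

#' Cell identifier
#' @param object a [CellRecording].
#' @export
setGeneric("cellId", function(object) standardGeneric("cellId"))

#' @rdname cellId
#' @export
setMethod("cellId", "CellRecording", function(object) object@cellId)

#' Variant identifier
#' @param object a [CellRecording].
#' @export
setGeneric("variantId", function(object) standardGeneric("variantId"))

#' @rdname variantId
#' @export
setMethod("variantId", "CellRecording", function(object) object@variantId)

#' Membrane capacitance (pF)
#' @param object a [CellRecording].
#' @export
setGeneric("capacitance", function(object) standardGeneric("capacitance"))

#' @rdname capacitance
#' @export
setMethod("capacitance", "CellRecording", function(object)
  object@capacitancepF)

#' Series resistance (MOhm)
#' @param object a [CellRecording].
#' @export
setGeneric("seriesResistance", function(object)
  standardGeneric("seriesResistance"))

#' @rdname seriesResistance
#' @export
setMethod("seriesResistance", "CellRecording", function(object)
  object@seriesResistanceMOhm)

#' Names of the recordings stored in a cell
#' @param object a [CellRecording].
#' @export
setGeneric("recordingNames", function(object)
  standardGeneric("recordingNames"))

#' @rdname recordingNames
#' @export
setMethod("recordingNames", "CellRecording", function(object)
  names(object@recordings))

#' Retrieve one recording (sweep matrix) and its protocol
#' @param object a [CellRecording].
#' @param name protocol name.
#' @return list with elements \code{sweeps} (time x sweep matrix, pA) and
#'   \code{protocol} (a [VoltageProtocol]).
#' @export
setGeneric("getRecording", function(object, name)
  standardGeneric("getRecording"))

#' @rdname getRecording
#' @export
setMethod("getRecording", "CellRecording", function(object, name) {
  if (!name %in% names(object@recordings))
    stop("no recording named '", name, "' in cell ", object@cellId)
  list(sweeps = object@recordings[[name]], protocol = object@protocols[[name]])
})

#' @describeIn VoltageProtocol-class compact display.
#' @param object a \code{VoltageProtocol}.
#' @export
setMethod("show", "VoltageProtocol", function(object) {
  cat("VoltageProtocol '", object@name, "': hold ", object@holdingmV,
      " mV, ", nrow(object@epochs), " epochs, ", nSweeps(object),
      " sweeps (", object@sweepDim, "-varying), dt = ",
      object@sampleIntervalMs, " ms\n", sep = "")
  invisible(NULL)
})

#' @describeIn GatingParams-class compact display.
#' @param object a \code{GatingParams}.
#' @export
setMethod("show", "GatingParams", function(object) {
  cat("GatingParams: gmax ", signif(object@gmaxDensity, 4), " nS/pF, Erev ",
      object@eRevmV, " mV\n  activation V1/2 ", object@actV12mV, " mV (slope ",
      object@actSlopemV, "), inactivation V1/2 ", object@inactV12mV,
      " mV (slope ", object@inactSlopemV, ")\n  tau_inact(0 mV) ",
      object@tauInact0mVms, " ms, tau_rec(-80 mV) ", object@tauRecM80mVms,
      " ms, gate exponent ", object@gateExponent, "\n", sep = "")
  invisible(NULL)
})

#' @describeIn CellRecording-class compact display.
#' @param object a \code{CellRecording}.
#' @export
setMethod("show", "CellRecording", function(object) {
  cat("CellRecording ", object@cellId, " (", object@variantId, "): C = ",
      signif(object@capacitancepF, 3), " pF, Rs = ",
      signif(object@seriesResistanceMOhm, 3), " MOhm, protocols: ",
      paste(names(object@recordings), collapse = ", "), "\n", sep = "")
  invisible(NULL)
})

#' @describeIn BoltzmannFit-class compact display.
#' @param object a \code{BoltzmannFit}.
#' @export
setMethod("show", "BoltzmannFit", function(object) {
  cat("BoltzmannFit (", object@direction, "): V1/2 = ",
      signif(object@V12mV, 4), " mV, slope = ", signif(object@VslopemV, 4),
      " mV, A = ", signif(object@A, 4), ", B = ", signif(object@B, 4),
      if (object@converged) "" else "  [NOT CONVERGED]", "\n", sep = "")
  invisible(NULL)
})

#' @describeIn ExponentialFit-class compact display.
#' @param object an \code{ExponentialFit}.
#' @export
setMethod("show", "ExponentialFit", function(object) {
  cat("ExponentialFit: ", nrow(object@components), " component(s), tau = ",
      paste(signif(object@components[, "tau_ms"], 4), collapse = ", "),
      " ms, fast fraction ", signif(object@fastFraction, 3),
      if (object@converged) "" else "  [NOT CONVERGED]", "\n", sep = "")
  invisible(NULL)
})

#' Extract fitted coefficients
#' @param object a [BoltzmannFit].
#' @param ... unused.
#' @return named numeric vector.
#' @export
setMethod("coef", "BoltzmannFit", function(object, ...)
  c(A = object@A, B = object@B, V12_mV = object@V12mV,
    Vslope_mV = object@VslopemV))

#' @rdname coef-BoltzmannFit-method
#' @param object an [ExponentialFit].
#' @export
setMethod("coef", "ExponentialFit", function(object, ...) {
  cm <- object@components
  out <- c(offset = object@offset)
  for (i in seq_len(nrow(cm)))
    out <- c(out, stats::setNames(cm[i, ], paste0(c("a", "tau"), i)))
  out
})
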