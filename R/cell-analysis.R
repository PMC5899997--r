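#' @include AllClasses.R trace-analysis.R gating-model.R
NULL

## Window helpers working off the protocol's epoch table for a given sweep.
epochWindow <- function(protocol, sweepIndex, label) {
  et <- epochTimes(protocol, sweepIndex)
  row <- which(et$label == label)
  if (!length(row)) stop("protocol '", protocol@name, "' has no epoch '",
                         label, "'")
  c(et$start_ms[row[1]], et$end_ms[row[1]])
}

#' Activation analysis of one cell
#'
#' Measures the peak current per test voltage from the activation protocol,
#' reports the peak current and current density at the 0 mV step, estimates
#' the reversal potential from the depolarised I-V limb, transforms the I-V
#' into a conductance-voltage curve and fits an increasing Boltzmann to
#' obtain the activation midpoint and slope factor.
#'
#' @param cell a [CellRecording] containing an \code{"activation"}
#'   recording.
#' @param eRevPolicy \code{"per-cell"} (estimate from the I-V limb, fall
#'   back to \code{eRevFallback}) or \code{"fixed"}.
#' @param eRevFallback reversal potential used by the fallback / fixed
#'   policy, mV.
#' @return list with \code{Ipeak_0mV_pA}, \code{Ipeak_density_pA_per_pF},
#'   \code{E_rev_est_mV}, \code{act_V12_mV}, \code{act_Vslope_mV}, the
#'   peak I-V table (\code{iv}), the conductance curve (\code{gv}) and the
#'   [BoltzmannFit] (\code{fit}).
#' @export
analyzeActivation <- function(cell, eRevPolicy = c("per-cell", "fixed"),
                              eRevFallback = 65) {
  eRevPolicy <- match.arg(eRevPolicy)
  if (!"activation" %in% recordingNames(cell))
    stop("cell ", cellId(cell), " has no activation recording")
  rec <- getRecording(cell, "activation")
  prot <- rec$protocol
  tms <- sweepTimes(prot)
  testWin <- epochWindow(prot, 1L, "test")
  baseWin <- epochWindow(prot, 1L, "hold")
  Vs <- sweepValues(prot)
  Ip <- vapply(seq_along(Vs), function(i)
    peakCurrent(rec$sweeps[, i], tms, testWin, baseWin), numeric(1))
  i0 <- which(Vs == 0)
  if (!length(i0)) stop("activation protocol lacks a 0 mV test sweep")
  eRev <- if (eRevPolicy == "fixed") eRevFallback else
    withCallingHandlers(
      estimateReversal(Vs, Ip, fallback = eRevFallback),
      warning = function(w) invokeRestart("muffleWarning"))
  gv <- conductanceCurve(Vs, Ip, eRev)
  fit <- fitBoltzmann(gv$V, gv$G, "increasing")
  list(Ipeak_0mV_pA = Ip[i0],
       Ipeak_density_pA_per_pF = Ip[i0] / capacitance(cell),
       E_rev_est_mV = eRev,
       act_V12_mV = if (fit@converged) fit@V12mV else NA_real_,
       act_Vslope_mV = if (fit@converged) fit@VslopemV else NA_real_,
       iv = data.frame(V = Vs, I = Ip), gv = gv, fit = fit)
}

#' Steady-state fast-inactivation analysis of one cell
#'
#' Measures the peak tail current at the fixed tail voltage (first 5 ms of
#' the tail step) for each conditioning pre-pulse, fits a decreasing
#' Boltzmann against the pre-pulse voltage and reports the
#' fast-inactivation midpoint and slope factor.  The availability curve
#' normalised to the fit's asymptotes is returned for cohort averaging.
#'
#' @param cell a [CellRecording] containing an \code{"inactivation"}
#'   recording.
#' @param tailWindowMs width of the tail-current search window, ms.
#' @return list with \code{inact_V12_mV}, \code{inact_Vslope_mV}, the raw
#'   tail amplitudes (\code{avail}), the normalised curve
#'   (\code{normalized}) and the [BoltzmannFit] (\code{fit}).
#' @export
analyzeInactivation <- function(cell, tailWindowMs = 5) {
  if (!"inactivation" %in% recordingNames(cell))
    stop("cell ", cellId(cell), " has no inactivation recording")
  rec <- getRecording(cell, "inactivation")
  prot <- rec$protocol
  tms <- sweepTimes(prot)
  tailWin <- epochWindow(prot, 1L, "tail")
  tailWin[2] <- min(tailWin[2], tailWin[1] + tailWindowMs)
  baseWin <- epochWindow(prot, 1L, "hold")
  Vs <- sweepValues(prot)
  tail <- vapply(seq_along(Vs), function(i)
    peakCurrent(rec$sweeps[, i], tms, tailWin, baseWin), numeric(1))
  fit <- fitBoltzmann(Vs, abs(tail), "decreasing")
  normd <- if (fit@converged) normalizeToFit(abs(tail), fit) else
    rep(NA_real_, length(tail))
  list(inact_V12_mV = if (fit@converged) fit@V12mV else NA_real_,
       inact_Vslope_mV = if (fit@converged) fit@VslopemV else NA_real_,
       avail = data.frame(V = Vs, tail_pA = tail),
       normalized = data.frame(V = Vs, availability = normd),
       fit = fit)
}

#' Recovery-from-inactivation analysis of one cell
#'
#' Measures the peak current of the conditioning pulse (P1) and of the test
#' pulse (P2) for each recovery interval, forms the P2/P1 ratios and fits
#' \eqn{1 - a e^{-\Delta t/\tau}} to obtain the recovery time constant.
#'
#' @param cell a [CellRecording] containing a \code{"recovery"} recording.
#' @param p2WindowMs width of the P2 peak-search window, ms.
#' @return list with \code{tau_rec_ms}, \code{analyzable} flag, the
#'   [RecoveryCurve] (\code{curve}) and the [ExponentialFit] (\code{fit}).
#' @export
analyzeRecovery <- function(cell, p2WindowMs = 5) {
  if (!"recovery" %in% recordingNames(cell))
    stop("cell ", cellId(cell), " has no recovery recording")
  rec <- getRecording(cell, "recovery")
  prot <- rec$protocol
  tms <- sweepTimes(prot)
  ivals <- sweepValues(prot)
  baseWin <- epochWindow(prot, 1L, "hold")
  p1 <- numeric(length(ivals)); p2 <- numeric(length(ivals))
  for (i in seq_along(ivals)) {
    w1 <- epochWindow(prot, i, "P1")
    w2 <- epochWindow(prot, i, "P2")
    w2[2] <- min(w2[2], w2[1] + p2WindowMs)
    p1[i] <- peakCurrent(rec$sweeps[, i], tms, w1, baseWin)
    p2[i] <- peakCurrent(rec$sweeps[, i], tms, w2, baseWin)
  }
  if (stats::median(abs(p1)) < 50) {    # pA; essentially no P1 current
    return(list(tau_rec_ms = NA_real_, analyzable = FALSE,
                curve = new("RecoveryCurve", intervalsMs = ivals,
                            ratio = rep(NA_real_, length(ivals))),
                fit = NULL))
  }
  ratio <- pmin(pmax(p2 / p1, -0.05), 1.05)
  curve <- new("RecoveryCurve", intervalsMs = ivals, ratio = ratio)
  fit <- fitRecovery(ivals, ratio)
  list(tau_rec_ms = if (fit@converged)
         unname(fit@components[1, "tau_ms"]) else NA_real_,
       analyzable = TRUE, curve = curve, fit = fit)
}

#' Onset-of-inactivation analysis of one cell
#'
#' Fits a double exponential to the decay of the 0 mV activation-protocol
#' sweep from its peak and reports the fast time constant (open-state
#' fast-inactivation time constant at 0 mV) and its amplitude share.
#'
#' @param cell a [CellRecording] containing an \code{"activation"}
#'   recording with a 0 mV sweep.
#' @param fitStartOffsetMs dead time after the peak excluded from the fit
#'   (activation-gate settling), ms.
#' @param fitSpanMs length of the fitted decay segment, ms.
#' @return list with \code{tau_inact_0mV_ms}, \code{fast_fraction} and the
#'   [ExponentialFit] (\code{fit}).
#' @export
analyzeOnset <- function(cell, fitStartOffsetMs = 0.06, fitSpanMs = 8) {
  if (!"activation" %in% recordingNames(cell))
    stop("cell ", cellId(cell), " has no activation recording")
  rec <- getRecording(cell, "activation")
  prot <- rec$protocol
  tms <- sweepTimes(prot)
  i0 <- which(sweepValues(prot) == 0)
  if (!length(i0)) stop("activation protocol lacks a 0 mV test sweep")
  testWin <- epochWindow(prot, 1L, "test")
  tr <- rec$sweeps[, i0]
  sel <- which(tms >= testWin[1] & tms <= testWin[2])
  pk <- sel[which.max(abs(tr[sel]))]
  t0 <- tms[pk] + fitStartOffsetMs
  fsel <- which(tms >= t0 & tms <= min(t0 + fitSpanMs, testWin[2]))
  if (length(fsel) < 10)
    return(list(tau_inact_0mV_ms = NA_real_, fast_fraction = NA_real_,
                fit = NULL))
  fit <- fitExponential(tms[fsel] - tms[fsel][1], tr[fsel], nComponents = 2L)
  if (!fit@converged || abs(fit@components[1, "amplitude"]) <
      .Machine$double.eps)
    return(list(tau_inact_0mV_ms = NA_real_, fast_fraction = NA_real_,
                fit = fit))
  list(tau_inact_0mV_ms = unname(fit@components[1, "tau_ms"]),
       fast_fraction = fit@fastFraction, fit = fit)
}

#' Full biophysical analysis of one cell
#'
#' Runs the activation, steady-state inactivation, recovery and onset
#' analyses and assembles one row of per-cell biophysics: the seven gating
#' parameters, the series-resistance voltage error
#' (\eqn{|I_{peak}| \cdot R_s}) and the two nested quality-control flags
#' (peak current above 0.1 nA for the density tier; above 0.5 nA with a
#' series-resistance error below 5 mV for the biophysics tier).
#'
#' @param cell a [CellRecording] with the three standard recordings.
#' @param eRevPolicy,eRevFallback see [analyzeActivation()].
#' @return one-row data.frame of per-cell biophysics.
#' @export
analyzeCell <- function(cell, eRevPolicy = "per-cell", eRevFallback = 65) {
  act <- analyzeActivation(cell, eRevPolicy, eRevFallback)
  ina <- analyzeInactivation(cell)
  rec <- analyzeRecovery(cell)
  ons <- analyzeOnset(cell)
  ip <- act$Ipeak_0mV_pA
  rsErr <- abs(ip) * seriesResistance(cell) * 1e-3   # pA * MOhm -> mV
  row <- data.frame(
    cell_id = cellId(cell), variant_id = variantId(cell),
    capacitance_pF = capacitance(cell),
    series_resistance_MOhm = seriesResistance(cell),
    Ipeak_0mV_pA = ip,
    Ipeak_density_pA_per_pF = act$Ipeak_density_pA_per_pF,
    act_V12_mV = act$act_V12_mV, act_Vslope_mV = act$act_Vslope_mV,
    inact_V12_mV = ina$inact_V12_mV, inact_Vslope_mV = ina$inact_Vslope_mV,
    tau_inact_0mV_ms = ons$tau_inact_0mV_ms,
    tau_rec_ms = rec$tau_rec_ms,
    E_rev_est_mV = act$E_rev_est_mV,
    Rs_error_mV = rsErr,
    fast_fraction = ons$fast_fraction,
    stringsAsFactors = FALSE)
  qcFilter(row)
}

#' Apply the two-tier quality-control filter
#'
#' Density tier: peak current magnitude above 0.1 nA (cells counted for the
#' current-density column).  Biophysics tier: peak current magnitude above
#' 0.5 nA and series-resistance error below 5 mV (cells counted for the
#' other parameters).  The tiers are nested by construction.
#'
#' @param cells data.frame of per-cell biophysics (from [analyzeCell()]).
#' @return the same data.frame with logical columns \code{qc_density_pass}
#'   and \code{qc_biophysics_pass} (re)computed.
#' @export
qcFilter <- function(cells) {
  cells$qc_density_pass <- is.finite(cells$Ipeak_0mV_pA) &
    abs(cells$Ipeak_0mV_pA) > 100
  cells$qc_biophysics_pass <- cells$qc_density_pass &
    abs(cells$Ipeak_0mV_pA) > 500 & cells$Rs_error_mV < 5
  cells
}

#' Analyse every cell of a cohort
#'
#' @param cells list of [CellRecording].
#' @param ... passed to [analyzeCell()].
#' @return data.frame with one biophysics row per cell.
#' @export
analyzeCohort <- function(cells, ...) {
  if (!length(cells)) return(data.frame())
  do.call(rbind, lapply(cells, analyzeCell, ...))
}

## Which QC tier each reported parameter uses.
biophysicsParameters <- function() {
  c(Ipeak_density_pA_per_pF = "density",
    act_V12_mV = "biophysics", act_Vslope_mV = "biophysics",
    inact_V12_mV = "biophysics", inact_Vslope_mV = "biophysics",
    tau_inact_0mV_ms = "biophysics", tau_rec_ms = "biophysics")
}

#' Per-variant summary (mean, SE, N) of the seven parameters
#'
#' Means and standard errors (sample sd / sqrt(N)) per parameter over the
#' appropriate QC tier: the current density uses the density tier, every
#' other parameter the biophysics tier.  A single-cell parameter reports
#' SE 0 with \code{se_defined = FALSE}.
#'
#' @param cells data.frame of per-cell biophysics rows (one variant or
#'   many; summaries are per \code{variant_id}).
#' @return data.frame with columns \code{variant_id}, \code{parameter},
#'   \code{n}, \code{mean}, \code{se}, \code{se_defined}.
#' @export
summarizeVariant <- function(cells) {
  pars <- biophysicsParameters()
  out <- list()
  for (vid in unique(cells$variant_id)) {
    sub <- cells[cells$variant_id == vid, , drop = FALSE]
    for (p in names(pars)) {
      tier <- if (pars[[p]] == "density") sub$qc_density_pass else
        sub$qc_biophysics_pass
      vals <- sub[[p]][tier & is.finite(sub[[p]])]
      n <- length(vals)
      if (n == 0) next   # empty tier: parameter reported absent
      se <- if (n > 1) stats::sd(vals) / sqrt(n) else 0
      out[[length(out) + 1L]] <- data.frame(
        variant_id = vid, parameter = p, n = n, mean = mean(vals),
        se = se, se_defined = n > 1, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(data.frame())
  do.call(rbind, out)
}
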