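#' @include AllClasses.R gating-model.R protocols.R
NULL

## Deterministic named-stream seed splitter: a small polynomial string hash
## folded into [0, 2^31 - 2] so that each (seed, stream) pair has its own
## reproducible RNG stream and adding a cohort never perturbs another
## cohort's draws.
streamSeed <- function(seed, ...) {
  key <- paste(c(format(seed, scientific = FALSE), ...), collapse = "/")
  h <- 104729
  M <- 2147483647   # 2^31 - 1, keeps derived seeds valid R integers
  # polynomial rolling hash; intermediate products stay below 2^53
  for (cp in utf8ToInt(key)) h <- (h * 131 + cp) %% M
  as.integer(h)
}

## Log-normal draw with the requested mean and coefficient of variation,
## applied to the magnitude of `mean` (sign preserved).
rlnormCV <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  s2 <- log(1 + cv^2)
  sign(mean) * stats::rlnorm(n, log(abs(mean)) - s2 / 2, sqrt(s2))
}

#' Cohort specification constructor
#'
#' @param variantId cohort label.
#' @param nCells number of cells.
#' @param paramMeans a [GatingParams] of central values.
#' @param peakDensityMean target mean peak current density at 0 mV (pA/pF).
#' @param paramCV named per-field coefficients of variation (see
#'   [CohortSpec]); missing fields default to 0.
#' @param capacitancepF,seriesResistanceMOhm length-2 \code{(mean, sd)}.
#' @param noiseSdpA additive current noise sd, pA.
#' @param seed cohort seed.
#' @return a [CohortSpec].
#' @export
cohortSpec <- function(variantId, nCells, paramMeans = wildTypeParams(),
                       peakDensityMean = -127.5,
                       paramCV = numeric(),
                       capacitancepF = c(12, 3),
                       seriesResistanceMOhm = c(2, 0.5),
                       noiseSdpA = 10, seed = 1) {
  cv <- c(peakDensity = 0, actV12 = 0, actSlope = 0, inactV12 = 0,
          inactSlope = 0, tauInact = 0, tauRec = 0)
  if (length(paramCV)) {
    bad <- setdiff(names(paramCV), names(cv))
    if (length(bad)) stop("unknown paramCV fields: ", paste(bad, collapse = ", "))
    cv[names(paramCV)] <- paramCV
  }
  new("CohortSpec", variantId = variantId, nCells = nCells,
      paramMeans = paramMeans, peakDensityMean = peakDensityMean,
      paramCV = cv, capacitancepF = capacitancepF,
      seriesResistanceMOhm = seriesResistanceMOhm,
      noiseSdpA = noiseSdpA, seed = seed)
}

## Draw one cell's ground-truth parameters around the cohort means.
## Voltages are normal (sd = |mean| * cv), positive-by-construction
## quantities log-normal.  Draws violating the physical bounds are redrawn
## (bounded retry), matching the generator contract.
drawCellParams <- function(spec, minTauInact = 0.1) {
  mu <- spec@paramMeans
  cv <- spec@paramCV
  redraws <- 0L
  for (attempt in seq_len(100L)) {
    p <- mu
    p@actV12mV <- stats::rnorm(1, mu@actV12mV, abs(mu@actV12mV) * cv["actV12"])
    p@inactV12mV <- stats::rnorm(1, mu@inactV12mV,
                                 abs(mu@inactV12mV) * cv["inactV12"])
    p@actSlopemV <- rlnormCV(1, mu@actSlopemV, cv["actSlope"])
    p@inactSlopemV <- rlnormCV(1, mu@inactSlopemV, cv["inactSlope"])
    p@tauInact0mVms <- rlnormCV(1, mu@tauInact0mVms, cv["tauInact"])
    p@tauRecM80mVms <- rlnormCV(1, mu@tauRecM80mVms, cv["tauRec"])
    peakDensity <- rlnormCV(1, spec@peakDensityMean, cv["peakDensity"])
    ok <- p@actSlopemV > 0 && p@inactSlopemV > 0 &&
      p@tauInact0mVms >= minTauInact && p@tauRecM80mVms > 0
    if (ok) {
      attr(p, "redraws") <- redraws
      return(list(params = p, peakDensity = peakDensity, redraws = redraws))
    }
    redraws <- redraws + 1L
  }
  stop("cohort ", spec@variantId, ": could not draw physical gating ",
       "parameters after 100 attempts (cv too large?)")
}

#' Simulate a cohort of virtual cells
#'
#' Draws per-cell gating parameters, capacitance and series resistance
#' around the cohort means, calibrates each cell's maximal conductance to
#' its drawn target peak current density, and simulates all three standard
#' protocols per cell.  Ground truth is returned alongside the recordings
#' for parameter-recovery testing.  Fully reproducible: each cell uses a
#' named RNG stream derived from the cohort seed.
#'
#' @param spec a [CohortSpec].
#' @param protocols named protocol list as from [buildStandardProtocols()].
#' @param noise logical; set \code{FALSE} to simulate noiseless traces.
#' @return list with \code{cells} (list of [CellRecording]) and
#'   \code{truth} (data.frame of drawn ground-truth parameters per cell,
#'   plus a \code{redraws} count of bounded redraws).
#' @examples
#' spec <- cohortSpec("WT", 2, seed = 42)
#' coh <- generateCohort(spec)
#' coh$truth$act_V12_mV
#' @export
generateCohort <- function(spec, protocols = buildStandardProtocols(),
                           noise = TRUE) {
  validObject(spec)
  n <- spec@nCells
  cells <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(streamSeed(spec@seed, "cell", spec@variantId, i))
    dr <- drawCellParams(spec)
    cap <- 0; rs <- 0
    while (cap <= 0) cap <- stats::rnorm(1, spec@capacitancepF[1],
                                         spec@capacitancepF[2])
    while (rs <= 0) rs <- stats::rnorm(1, spec@seriesResistanceMOhm[1],
                                       spec@seriesResistanceMOhm[2])
    params <- dr$params
    params@gmaxDensity <- gmaxForPeakDensity(
      params, dr$peakDensity,
      sampleIntervalMs = protocols[[1]]@sampleIntervalMs)
    recs <- lapply(protocols, function(pr)
      simulateProtocol(params, cap, pr,
                       noiseSdpA = if (noise) spec@noiseSdpA else 0))
    cid <- sprintf("%s_c%03d", spec@variantId, i)
    cells[[i]] <- new("CellRecording", cellId = cid,
                      variantId = spec@variantId,
                      capacitancepF = cap, seriesResistanceMOhm = rs,
                      recordings = recs, protocols = protocols)
    rows[[i]] <- data.frame(
      cell_id = cid, variant_id = spec@variantId,
      capacitance_pF = cap, series_resistance_MOhm = rs,
      Ipeak_density_pA_per_pF = dr$peakDensity,
      act_V12_mV = params@actV12mV, act_Vslope_mV = params@actSlopemV,
      inact_V12_mV = params@inactV12mV,
      inact_Vslope_mV = params@inactSlopemV,
      tau_inact_0mV_ms = params@tauInact0mVms,
      tau_rec_ms = params@tauRecM80mVms,
      gmax_density_nS_per_pF = params@gmaxDensity,
      redraws = dr$redraws,
      stringsAsFactors = FALSE)
  }
  truth <- if (n > 0) do.call(rbind, rows) else data.frame()
  list(cells = cells, truth = truth)
}
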