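#' @include AllClasses.R
NULL

boxcar <- function(x, n) {
  if (n <= 1L || length(x) < n) return(x)
  sm <- as.numeric(stats::filter(x, rep(1 / n, n), sides = 2))
  # edges keep the raw samples where the window does not fit
  sm[is.na(sm)] <- x[is.na(sm)]
  sm
}

#' Signed peak current in a time window
#'
#' Subtracts the baseline (mean over \code{baselineWindow}, if given),
#' lightly smooths the trace with a short running mean (as acquisition
#' filtering would), and returns the extremum of largest magnitude within
#' \code{window}, sign preserved (inward current negative).
#'
#' @param trace current samples, pA.
#' @param timesMs sample times, ms (same length).
#' @param window length-2 numeric \code{c(t0, t1)} in ms; the search window.
#' @param baselineWindow optional length-2 numeric; baseline is its mean.
#' @param smoothN running-mean width in samples (1 = no smoothing).
#' @return signed peak current, pA.
#' @examples
#' t <- seq(0.1, 10, by = 0.1)
#' tr <- -1200 * exp(-(t - 3)^2)
#' peakCurrent(tr, t, c(1, 6), smoothN = 1)  # -1200
#' @export
peakCurrent <- function(trace, timesMs, window, baselineWindow = NULL,
                        smoothN = 5L) {
  if (length(trace) != length(timesMs))
    stop("trace and timesMs must have the same length")
  idx <- which(timesMs >= window[1] & timesMs <= window[2])
  if (!length(idx)) stop("empty peak-search window")
  base <- 0
  if (!is.null(baselineWindow)) {
    bidx <- which(timesMs >= baselineWindow[1] & timesMs <= baselineWindow[2])
    if (length(bidx)) base <- mean(trace[bidx])
  }
  y <- boxcar(trace[idx] - base, smoothN)
  y[which.max(abs(y))]
}

#' Estimate the reversal potential from an I-V relation
#'
#' Fits a line to the depolarised limb of the peak I-V curve (test voltages
#' at or above \code{limbMinmV}) and extrapolates to zero current.  If no
#' usable limb exists, or the extrapolated value falls outside (0, 100) mV,
#' the configured fallback is returned with a warning.
#'
#' @param V test voltages, mV.
#' @param I peak currents, pA.
#' @param limbMinmV lower bound of the linear limb (default +20 mV).
#' @param minPoints minimum number of limb points (default 3).
#' @param fallback reversal potential returned when estimation fails, mV.
#' @return estimated reversal potential, mV.
#' @export
estimateReversal <- function(V, I, limbMinmV = 20, minPoints = 3L,
                             fallback = 65) {
  sel <- which(V >= limbMinmV & is.finite(I))
  if (length(sel) >= minPoints && stats::sd(I[sel]) > 0) {
    fit <- stats::lm(I[sel] ~ V[sel])
    b <- stats::coef(fit)
    if (is.finite(b[2]) && b[2] != 0) {
      er <- -b[1] / b[2]
      if (er > 0 && er < 100) return(unname(er))
    }
  }
  warning("could not estimate reversal potential from the I-V limb; ",
          "using fallback ", fallback, " mV")
  fallback
}

#' Peak conductance versus voltage
#'
#' Transforms a peak I-V relation into conductance,
#' \eqn{G = I_{peak} / (V - E_{rev})} (nS for pA and mV).  Points within
#' \code{excludeMarginmV} of the reversal potential are dropped because the
#' driving force vanishes there.
#'
#' @param V test voltages, mV.
#' @param I peak currents, pA.
#' @param eRev reversal potential, mV.
#' @param excludeMarginmV exclusion half-width around \code{eRev}, mV.
#' @return data.frame with columns \code{V} (mV) and \code{G} (nS).
#' @export
conductanceCurve <- function(V, I, eRev, excludeMarginmV = 5) {
  keep <- abs(V - eRev) >= excludeMarginmV
  data.frame(V = V[keep], G = I[keep] / (V[keep] - eRev))
}

#' Fit a Boltzmann curve to amplitude-voltage data
#'
#' Nonlinear least squares of
#' \eqn{y = B + (A - B)/(1 + \exp(\pm(V_{1/2} - V)/V_{slope}))}, with the
#' sign chosen so that \code{direction} gives the sense of the curve in V;
#' \code{A} is the maximum and \code{B} the minimum amplitude, and the
#' fitted value at \code{V12} is \eqn{(A+B)/2}.  Starting values are taken
#' from the data (asymptotes from the extreme-voltage means, midpoint from
#' the half-crossing, slope 6 mV).  Non-convergence is reported honestly
#' through the \code{converged} flag.
#'
#' @param V voltages, mV (at least 5 points spanning the transition).
#' @param y amplitudes (conductance or current, any scale).
#' @param direction \code{"increasing"} (activation) or \code{"decreasing"}
#'   (availability).
#' @return a [BoltzmannFit].
#' @examples
#' V <- seq(-100, 50, 10)
#' y <- 1 / (1 + exp((-19.5 - V) / 6.4))
#' coef(fitBoltzmann(V, y, "increasing"))
#' @export
fitBoltzmann <- function(V, y, direction = c("increasing", "decreasing")) {
  direction <- match.arg(direction)
  ok <- is.finite(V) & is.finite(y)
  V <- V[ok]; y <- y[ok]
  if (length(V) < 5) stop("need at least 5 finite points for a Boltzmann fit")
  o <- order(V); V <- V[o]; y <- y[o]
  sgn <- if (direction == "increasing") 1 else -1
  nEnd <- max(2L, round(length(V) / 5))
  lowEnd <- mean(y[seq_len(nEnd)])
  highEnd <- mean(y[seq(length(y) - nEnd + 1L, length(y))])
  a0 <- if (direction == "increasing") highEnd else lowEnd   # maximum
  b0 <- if (direction == "increasing") lowEnd else highEnd   # minimum
  mid <- (a0 + b0) / 2
  cross <- which.min(abs(y - mid))
  start <- list(A = a0, B = b0, V12 = V[cross], slope = 6)
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      y ~ B + (A - B) / (1 + exp(sgn * (V12 - V) / slope)),
      start = start,
      lower = c(A = -Inf, B = -Inf, V12 = -200, slope = 1e-3),
      upper = c(A = Inf, B = Inf, V12 = 200, slope = 100),
      control = minpack.lm::nls.lm.control(maxiter = 500, maxfev = 5000,
                                           ftol = 1e-10, ptol = 1e-10))),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(new("BoltzmannFit", A = a0, B = b0, V12mV = V[cross],
               VslopemV = 6, direction = direction, rss = NA_real_,
               converged = FALSE))
  }
  cf <- stats::coef(fit)
  new("BoltzmannFit", A = unname(cf["A"]), B = unname(cf["B"]),
      V12mV = unname(cf["V12"]), VslopemV = unname(cf["slope"]),
      direction = direction, rss = sum(stats::resid(fit)^2),
      converged = nlsConverged(fit) && unname(cf["A"]) != unname(cf["B"]))
}

#' Evaluate a fitted Boltzmann curve
#'
#' @param fit a [BoltzmannFit].
#' @param V voltages, mV.
#' @return fitted amplitudes.
#' @export
predictBoltzmann <- function(fit, V) {
  sgn <- if (fit@direction == "increasing") 1 else -1
  fit@B + (fit@A - fit@B) / (1 + exp(sgn * (fit@V12mV - V) / fit@VslopemV))
}

#' Normalise amplitudes to the asymptotes of a Boltzmann fit
#'
#' Returns \eqn{(y - B)/(A - B)}: the fitted minimum maps to 0 and the
#' fitted maximum to 1, so that normalised curves from different cells can
#' be averaged.
#'
#' @param y amplitudes.
#' @param fit a converged [BoltzmannFit].
#' @return normalised amplitudes.
#' @export
normalizeToFit <- function(y, fit) {
  if (!fit@converged) stop("cannot normalise to a non-converged fit")
  if (fit@A == fit@B) stop("degenerate fit: A equals B")
  (y - fit@B) / (fit@A - fit@B)
}

## Levenberg-Marquardt termination codes that mean "no further progress
## possible at the requested tolerances", i.e. practical convergence.
nlsConverged <- function(fit) {
  ci <- fit$convInfo
  isTRUE(ci$isConv) || ci$stopCode %in% c(1L, 2L, 3L, 6L, 7L, 8L)
}

expModel <- function(t, offset, amp, tau) {
  y <- rep(offset, length(t))
  for (i in seq_along(amp)) y <- y + amp[i] * exp(-t / tau[i])
  y
}

#' Fit a single or double exponential to time-course data
#'
#' Least-squares fit of \eqn{y(t) = c_0 + \sum_i a_i \exp(-t/\tau_i)} with
#' one or two components; decays and saturating rises are both covered by
#' the free offset and signed amplitudes.  For two components the fastest
#' is the primary result; its amplitude share (\code{fastFraction}) is
#' recorded, with a note when it falls below 0.95.  Components contributing
#' less than 5\% of the total amplitude are dropped before the fastest
#' component is selected, and a two-component fit that does not improve the
#' residual sum of squares by at least 5\% over the single-exponential fit
#' falls back to the latter (see the methods vignette).
#'
#' @param t times, ms; strictly increasing, at least 6 points.
#' @param y amplitudes.
#' @param nComponents 1 or 2.
#' @return an [ExponentialFit].
#' @examples
#' t <- seq(0, 30, 0.5)
#' f <- fitExponential(t, 3 * exp(-t / 5.63), 1)
#' coef(f)
#' @export
fitExponential <- function(t, y, nComponents = 1L) {
  if (length(t) != length(y)) stop("t and y must have the same length")
  if (length(t) < 6) stop("need at least 6 points for an exponential fit")
  if (is.unsorted(t, strictly = TRUE)) stop("t must be strictly increasing")
  if (!nComponents %in% c(1L, 2L)) stop("nComponents must be 1 or 2")
  span <- diff(range(y))
  if (span < .Machine$double.eps * max(1, abs(mean(y)))) {
    # constant data: zero-amplitude fit, flagged degenerate
    return(new("ExponentialFit",
               components = matrix(c(0, 1), 1, 2,
                                   dimnames = list(NULL, c("amplitude", "tau_ms"))),
               offset = mean(y), fastFraction = 1, rss = 0,
               converged = FALSE, notes = "degenerate: constant input"))
  }
  c0 <- mean(y[t >= stats::quantile(t, 0.9)])
  a0 <- y[1] - c0
  # crude tau from the time at which |y - c0| falls to 1/e of its start
  dy <- abs(y - c0)
  below <- which(dy <= abs(a0) / exp(1))
  tau0 <- if (length(below)) max(t[below[1]] - t[1], diff(range(t)) / 50)
          else diff(range(t)) / 3
  fit1 <- tryCatch(
    suppressWarnings(minpack.lm::nlsLM(y ~ c0 + a1 * exp(-t / tau1),
                      start = list(c0 = c0, a1 = a0, tau1 = tau0),
                      lower = c(c0 = -Inf, a1 = -Inf, tau1 = 1e-6),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, maxfev = 5000, ftol = 1e-10,
                        ptol = 1e-10))),
    error = function(e) NULL)
  makeFit <- function(offset, amp, tau, rss, converged, notes = character()) {
    o <- order(tau)
    amp <- amp[o]; tau <- tau[o]
    keep <- abs(amp) >= 0.05 * sum(abs(amp))
    if (!any(keep)) keep[1] <- TRUE
    amp <- amp[keep]; tau <- tau[keep]
    ff <- abs(amp[1]) / sum(abs(amp))
    if (length(amp) > 1 && ff < 0.95)
      notes <- c(notes, sprintf("fast component carries only %.1f%% of the amplitude",
                                100 * ff))
    new("ExponentialFit",
        components = matrix(c(amp, tau), ncol = 2,
                            dimnames = list(NULL, c("amplitude", "tau_ms"))),
        offset = offset, fastFraction = ff, rss = rss,
        converged = converged, notes = notes)
  }
  res1 <- if (!is.null(fit1)) {
    cf <- stats::coef(fit1)
    makeFit(unname(cf["c0"]), unname(cf["a1"]), unname(cf["tau1"]),
            sum(stats::resid(fit1)^2), nlsConverged(fit1))
  } else {
    new("ExponentialFit",
        components = matrix(c(a0, tau0), 1, 2,
                            dimnames = list(NULL, c("amplitude", "tau_ms"))),
        offset = c0, fastFraction = 1, rss = NA_real_, converged = FALSE,
        notes = "single-exponential fit failed")
  }
  if (nComponents == 1L) return(res1)
  tau1s <- if (!is.null(fit1)) unname(stats::coef(fit1)["tau1"]) else tau0
  a1s <- if (!is.null(fit1)) unname(stats::coef(fit1)["a1"]) else a0
  fit2 <- tryCatch(
    suppressWarnings(minpack.lm::nlsLM(y ~ c0 + a1 * exp(-t / tau1) + a2 * exp(-t / tau2),
                      start = list(c0 = if (!is.null(fit1))
                                     unname(stats::coef(fit1)["c0"]) else c0,
                                   a1 = a1s * 0.8, tau1 = tau1s / 2,
                                   a2 = a1s * 0.2, tau2 = tau1s * 3),
                      lower = c(c0 = -Inf, a1 = -Inf, tau1 = 1e-6,
                                a2 = -Inf, tau2 = 1e-6),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, maxfev = 5000, ftol = 1e-10,
                        ptol = 1e-10))),
    error = function(e) NULL)
  if (is.null(fit2)) return(res1)
  rss2 <- sum(stats::resid(fit2)^2)
  # fall back to the single component when the second does not earn its
  # keep or the two-component optimisation degenerates
  if (!nlsConverged(fit2) ||
      (!is.na(res1@rss) && res1@converged && rss2 > 0.95 * res1@rss))
    return(res1)
  cf <- stats::coef(fit2)
  makeFit(unname(cf["c0"]), unname(cf[c("a1", "a2")]),
          unname(cf[c("tau1", "tau2")]), rss2, nlsConverged(fit2))
}

#' Fit the two-pulse recovery time course
#'
#' Fits \eqn{P2/P1(\Delta t) = 1 - a\,e^{-\Delta t/\tau}} with the
#' asymptote fixed at 1 and the amplitude \code{a} free, and returns the
#' recovery time constant.
#'
#' @param intervalsMs recovery intervals, ms.
#' @param ratio P2/P1 peak-current ratios.
#' @return an [ExponentialFit] with offset 1 and one component
#'   (amplitude \code{-a}, tau = recovery time constant).
#' @export
fitRecovery <- function(intervalsMs, ratio) {
  ok <- is.finite(ratio)
  t <- intervalsMs[ok]; r <- ratio[ok]
  if (length(t) < 3) stop("need at least 3 recovery points")
  defic <- pmax(1 - r, 1e-6)
  a0 <- max(min(defic[which.min(t)], 1), 0.2)
  pos <- defic > 1e-5 & t > 0
  tau0 <- if (sum(pos) >= 2)
    unname(-1 / stats::coef(stats::lm(log(defic[pos]) ~ t[pos]))[2]) else 5
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- 5
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nlsLM(r ~ 1 - a * exp(-t / tau),
                      start = list(a = a0, tau = tau0),
                      lower = c(a = 0, tau = 1e-3),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, maxfev = 5000, ftol = 1e-10,
                        ptol = 1e-10))),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(new("ExponentialFit",
               components = matrix(c(-a0, tau0), 1, 2,
                                   dimnames = list(NULL, c("amplitude", "tau_ms"))),
               offset = 1, fastFraction = 1, rss = NA_real_,
               converged = FALSE, notes = "recovery fit failed"))
  }
  cf <- stats::coef(fit)
  new("ExponentialFit",
      components = matrix(c(-unname(cf["a"]), unname(cf["tau"])), 1, 2,
                          dimnames = list(NULL, c("amplitude", "tau_ms"))),
      offset = 1, fastFraction = 1, rss = sum(stats::resid(fit)^2),
      converged = nlsConverged(fit))
}
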