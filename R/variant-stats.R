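#' @include cell-analysis.R
NULL

#' Kruskal-Wallis rank-sum test across cohorts
#'
#' Tie-corrected H statistic with a chi-square reference distribution on
#' k - 1 degrees of freedom (delegates to [stats::kruskal.test()]).  If all
#' observations are identical the test is degenerate and p = 1 is returned
#' with a flag.
#'
#' @param values numeric observations.
#' @param groups group labels, same length.
#' @return list with \code{H}, \code{df}, \code{p} and \code{degenerate}.
#' @export
kruskalWallis <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("each group needs at least 2 observations")
  if (length(unique(values)) == 1L)
    return(list(H = 0, df = nlevels(groups) - 1L, p = 1, degenerate = TRUE))
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value, degenerate = FALSE)
}

#' Dunn's rank comparisons of each group against a control
#'
#' Ranks are pooled once across all groups; each non-control group is then
#' compared with the control by
#' \deqn{z = \frac{\bar R_i - \bar R_c}{\sqrt{\left(\frac{N(N+1)}{12} -
#'   \frac{\sum (t^3 - t)}{12 (N-1)}\right)\left(\frac{1}{n_i} +
#'   \frac{1}{n_c}\right)}}}
#' with the tie correction over tied groups of size \eqn{t}, and a
#' two-sided normal p-value.  Groups with fewer than 2 observations are
#' skipped with a flag.
#'
#' @param values numeric observations.
#' @param groups group labels, same length.
#' @param control the control group's label.
#' @return data.frame with \code{group}, \code{z}, \code{p},
#'   \code{skipped}.
#' @export
dunnVsControl <- function(values, groups, control) {
  groups <- as.character(groups)
  if (!control %in% groups) stop("control group '", control, "' not found")
  ok <- is.finite(values)
  values <- values[ok]; groups <- groups[ok]
  N <- length(values)
  r <- rank(values)
  ties <- table(r)
  tieTerm <- sum(ties^3 - ties) / (12 * (N - 1))
  base <- N * (N + 1) / 12 - tieTerm
  meanRank <- tapply(r, groups, mean)
  nPer <- tapply(r, groups, length)
  others <- setdiff(names(meanRank), control)
  out <- lapply(others, function(g) {
    if (nPer[[g]] < 2 || nPer[[control]] < 2)
      return(data.frame(group = g, z = NA_real_, p = NA_real_,
                        skipped = TRUE))
    se <- sqrt(base * (1 / nPer[[g]] + 1 / nPer[[control]]))
    z <- if (se > 0) (meanRank[[g]] - meanRank[[control]]) / se else 0
    data.frame(group = g, z = z, p = 2 * stats::pnorm(-abs(z)),
               skipped = FALSE)
  })
  do.call(rbind, out)
}

#' Games-Howell comparisons of each group against a control
#'
#' Welch-type contrast for unequal variances:
#' \eqn{t = (\bar x_i - \bar x_c)/\sqrt{s_i^2/n_i + s_c^2/n_c}} with
#' Welch-Satterthwaite degrees of freedom; the p-value is taken from the
#' studentized-range distribution with \code{k} groups at
#' \eqn{q = |t|\sqrt{2}}.  With two groups this reduces exactly to the
#' two-sided Welch t-test.  Identical degenerate groups give p = 1.
#'
#' @param values numeric observations.
#' @param groups group labels, same length.
#' @param control the control group's label.
#' @return data.frame with \code{group}, \code{t}, \code{q}, \code{df},
#'   \code{p}, \code{skipped}.
#' @export
gamesHowellVsControl <- function(values, groups, control) {
  groups <- as.character(groups)
  if (!control %in% groups) stop("control group '", control, "' not found")
  ok <- is.finite(values)
  values <- values[ok]; groups <- groups[ok]
  k <- length(unique(groups))
  st <- do.call(rbind, lapply(split(values, groups), function(v)
    data.frame(n = length(v), m = mean(v), v = stats::var(v))))
  others <- setdiff(rownames(st), control)
  ctl <- st[control, ]
  out <- lapply(others, function(g) {
    gi <- st[g, ]
    if (gi$n < 3 || ctl$n < 3)
      return(data.frame(group = g, t = NA_real_, q = NA_real_,
                        df = NA_real_, p = NA_real_, skipped = TRUE))
    sem2 <- gi$v / gi$n + ctl$v / ctl$n
    if (sem2 == 0) {
      equal <- gi$m == ctl$m
      return(data.frame(group = g, t = if (equal) 0 else Inf,
                        q = if (equal) 0 else Inf, df = Inf,
                        p = if (equal) 1 else 0, skipped = FALSE))
    }
    t <- (gi$m - ctl$m) / sqrt(sem2)
    df <- sem2^2 / ((gi$v / gi$n)^2 / (gi$n - 1) +
                    (ctl$v / ctl$n)^2 / (ctl$n - 1))
    q <- abs(t) * sqrt(2)
    p <- stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
    data.frame(group = g, t = t, q = q, df = df, p = p, skipped = FALSE)
  })
  do.call(rbind, out)
}

#' Fixed Bonferroni significance threshold for the comparison family
#'
#' \code{alpha / (nVariants * nParameters)}; with 14 variants and the seven
#' gating parameters at alpha 0.05 this is the 98-test threshold 0.00051
#' (displayed at two significant figures, full precision internally).
#'
#' @param nVariants number of variants compared with wild type.
#' @param nParameters number of parameters tested per variant.
#' @param alpha family-wise error target, in (0, 1).
#' @return list with \code{threshold} (full precision) and \code{display}
#'   (two significant figures).
#' @examples
#' bonferroniThreshold(14, 7)$display   # 0.00051
#' @export
bonferroniThreshold <- function(nVariants, nParameters, alpha = 0.05) {
  stopifnot(nVariants >= 1, nParameters >= 1,
            nVariants == round(nVariants), nParameters == round(nParameters),
            alpha > 0, alpha < 1)
  th <- alpha / (nVariants * nParameters)
  list(threshold = th, display = signif(th, 2))
}

#' The seven tested gating parameters
#'
#' Column names of the per-cell biophysics table entering the
#' variant-versus-wild-type comparisons: peak current density at 0 mV, the
#' activation and fast-inactivation Boltzmann midpoints and slope factors,
#' the open-state inactivation time constant at 0 mV and the recovery time
#' constant.
#'
#' @return character vector of length 7.
#' @export
testedParameters <- function() names(biophysicsParameters())

#' Compare every variant against wild type over the seven parameters
#'
#' For each parameter, observations are pooled over all cohorts in the
#' parameter's QC tier and each variant is compared with the wild-type
#' cohort by the chosen post-hoc scheme.  Significance is declared at the
#' fixed Bonferroni threshold
#' \code{alpha / (number of variants * number of parameters)}; the
#' direction of a significant difference is the sign of
#' (variant mean - wild-type mean).
#'
#' @param cells data.frame of per-cell biophysics rows with QC flags (from
#'   [analyzeCohort()] / [qcFilter()] or [simulateParameterTable()]).
#' @param wildType the wild-type \code{variant_id}.
#' @param method \code{"kw_dunn"} (Kruskal-Wallis family with Dunn's
#'   control comparisons; package default, see the methods vignette) or
#'   \code{"anova_games_howell"}.
#' @param alpha family-wise error target.
#' @param parameters parameter columns to test (default the seven).
#' @return data.frame with one row per variant x parameter:
#'   \code{variant_id}, \code{parameter}, \code{method}, \code{statistic},
#'   \code{p_raw}, \code{threshold}, \code{significant}, \code{direction}
#'   (\code{higher}/\code{lower}/\code{none}), \code{mean_variant},
#'   \code{mean_wt}.
#' @export
compareVariants <- function(cells, wildType = "WT",
                            method = c("kw_dunn", "anova_games_howell"),
                            alpha = 0.05,
                            parameters = testedParameters()) {
  method <- match.arg(method)
  tiers <- biophysicsParameters()
  variants <- setdiff(unique(cells$variant_id), wildType)
  if (!wildType %in% cells$variant_id)
    stop("wild-type cohort '", wildType, "' not present")
  if (!length(variants)) stop("no variant cohorts to compare")
  th <- bonferroniThreshold(length(variants), length(parameters),
                            alpha)$threshold
  out <- list()
  for (p in parameters) {
    tier <- if (identical(tiers[[p]], "density")) cells$qc_density_pass else
      cells$qc_biophysics_pass
    keep <- tier & is.finite(cells[[p]])
    vals <- cells[[p]][keep]
    grp <- cells$variant_id[keep]
    counts <- table(grp)
    usable <- names(counts)[counts >= 2]
    if (!wildType %in% usable) next
    sel <- grp %in% usable
    vals <- vals[sel]; grp <- grp[sel]
    cmp <- if (method == "kw_dunn") {
      d <- dunnVsControl(vals, grp, wildType)
      data.frame(group = d$group, statistic = d$z, p_raw = d$p,
                 skipped = d$skipped)
    } else {
      g <- gamesHowellVsControl(vals, grp, wildType)
      data.frame(group = g$group, statistic = g$t, p_raw = g$p,
                 skipped = g$skipped)
    }
    mWT <- mean(vals[grp == wildType])
    for (i in seq_len(nrow(cmp))) {
      if (cmp$skipped[i] || is.na(cmp$p_raw[i])) next
      mV <- mean(vals[grp == cmp$group[i]])
      sig <- cmp$p_raw[i] < th
      out[[length(out) + 1L]] <- data.frame(
        variant_id = cmp$group[i], parameter = p, method = method,
        statistic = cmp$statistic[i], p_raw = cmp$p_raw[i], threshold = th,
        significant = sig,
        direction = if (!sig) "none" else if (mV > mWT) "higher" else
          "lower",
        mean_variant = mV, mean_wt = mWT, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(data.frame())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Draw per-cell fitted-parameter tables directly (no trace simulation)
#'
#' Fast cohort emulation for statistical properties: per-cell values of the
#' seven parameters are drawn around the cohort means with the cohort's
#' per-parameter spread and per-parameter N (cells beyond a parameter's N
#' get \code{NA}, reproducing designs in which not every quantity was
#' measured in every cell).  Voltages are drawn normal, positive-magnitude
#' quantities log-normal.  QC flags are set to pass, since the spread is
#' that of cells that already passed QC.
#'
#' @param cohorts data.frame with one row per cohort and columns
#'   \code{variant_id}, per-parameter means \code{mean_<p>}, spreads
#'   \code{sd_<p>} and counts \code{n_density}, \code{n_biophys},
#'   \code{n_rec} (see [nav14ReferenceCohorts()]).
#' @param seed integer seed.
#' @return data.frame shaped like the [analyzeCohort()] output.
#' @export
simulateParameterTable <- function(cohorts, seed = 1) {
  rows <- list()
  lognormalPars <- c("act_Vslope_mV", "inact_Vslope_mV", "tau_inact_0mV_ms",
                     "tau_rec_ms", "Ipeak_density_pA_per_pF")
  for (i in seq_len(nrow(cohorts))) {
    co <- cohorts[i, ]
    set.seed(streamSeed(seed, "ptable", co$variant_id))
    n <- max(co$n_density, co$n_biophys, co$n_rec)
    draw <- function(p, nobs) {
      mu <- co[[paste0("mean_", p)]]
      sdv <- co[[paste0("sd_", p)]]
      v <- if (p %in% lognormalPars) rlnormCV(nobs, mu, sdv / abs(mu))
           else stats::rnorm(nobs, mu, sdv)
      c(v, rep(NA_real_, n - nobs))
    }
    d <- data.frame(
      cell_id = sprintf("%s_p%03d", co$variant_id, seq_len(n)),
      variant_id = co$variant_id,
      Ipeak_0mV_pA = NA_real_,
      Ipeak_density_pA_per_pF = draw("Ipeak_density_pA_per_pF",
                                     co$n_density),
      act_V12_mV = draw("act_V12_mV", co$n_biophys),
      act_Vslope_mV = draw("act_Vslope_mV", co$n_biophys),
      inact_V12_mV = draw("inact_V12_mV", co$n_biophys),
      inact_Vslope_mV = draw("inact_Vslope_mV", co$n_biophys),
      tau_inact_0mV_ms = draw("tau_inact_0mV_ms", co$n_biophys),
      tau_rec_ms = draw("tau_rec_ms", co$n_rec),
      qc_density_pass = TRUE, qc_biophysics_pass = TRUE,
      stringsAsFactors = FALSE)
    rows[[i]] <- d
  }
  do.call(rbind, rows)
}
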