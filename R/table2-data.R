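#' @include cohort.R
NULL

#' Reference biophysics of wild-type NaV1.4 and 14 rare variants
#'
#' Summary gating parameters (mean, SE, N) for the wild-type channel, six
#' case-cohort variants and eight control-cohort coding variants, used as
#' the default simulation targets.  Columns per parameter: \code{mean_<p>},
#' \code{se_<p>} and the derived per-cell spread \code{sd_<p> = SE *
#' sqrt(N)}; \code{n_density}, \code{n_biophys} and \code{n_rec} give the
#' number of cells behind the current-density, gating and recovery
#' measurements.  \code{star_<p>} flags the parameters reported as
#' significantly different from wild type at the 98-test Bonferroni
#' threshold.  Two wild-type SEs printed as zero at the table's precision
#' are replaced by half of one least-significant printed digit (0.005 ms,
#' 0.05 mV) so that per-cell spreads are non-degenerate.
#'
#' @return data.frame with 15 rows.
#' @export
nav14ReferenceCohorts <- function() {
  d <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
variant_id group nd mdens sedens nb mav12 seav12 mavsl seavsl miv12 seiv12 mivsl seivsl mti seti nr mtr setr
WT         wt      149 -127.5  6.4 146 -19.5 0.2 6.4 0.1 -65.3 0.3 5.4 0.05 0.30 0.005 105 5.63 0.14
Ser682Trp  case     19  -94.2  9.9  17 -21.2 0.7 7.2 0.2 -67.0 0.6 5.9 0.2  0.40 0.02   17 6.15 0.33
Gly859Arg  case     18 -138.5 16.4  17 -20.2 0.8 5.7 0.2 -64.2 0.6 5.1 0.1  0.31 0.01   17 5.20 0.30
Val1442Met case     14 -145.5 21.7  14 -21.7 0.8 6.3 0.2 -71.9 1.0 5.2 0.1  0.27 0.01   13 8.51 0.46
Arg1463Ser case     27  -71.3  8.3  25 -17.4 0.5 6.7 0.2 -61.7 0.6 6.3 0.1  0.31 0.01   19 1.95 0.09
Met1493Val case     17  -78.2  8.3  17 -19.2 0.5 6.7 0.3 -65.3 0.8 5.5 0.2  0.29 0.01    7 5.76 0.47
Glu1520Lys case     39  -49.8  9.7  28 -20.3 0.4 6.3 0.1 -66.3 0.5 5.4 0.2  0.33 0.01   20 5.63 0.29
Arg179Gln  control  11 -117.6 11.0  11 -19.3 0.6 6.5 0.2 -65.1 0.7 5.1 0.1  0.25 0.01   11 4.73 0.30
Arg190Trp  control  14 -153.4 21.8  14 -20.7 0.5 6.4 0.2 -64.9 0.5 5.3 0.1  0.29 0.01   13 5.09 0.20
Leu227Phe  control  12 -107.7 16.1  12 -17.6 0.4 6.5 0.2 -67.8 0.8 5.6 0.1  0.33 0.02   10 5.33 0.30
Asp334Asn  control  10 -141.0 26.6  10 -21.0 0.9 6.4 0.2 -66.4 0.8 5.3 0.1  0.27 0.01    9 5.07 0.30
Gly863Arg  control  12 -124.6 15.8  12 -20.3 0.8 6.3 0.1 -66.1 0.7 5.2 0.2  0.29 0.01   10 5.71 0.21
Ala870Thr  control  16 -132.6 20.0  15 -20.0 0.6 6.4 0.1 -65.7 0.6 5.0 0.1  0.29 0.01   14 6.29 0.55
Met897Lys  control  10 -102.8 23.3   9 -20.4 0.7 6.8 0.3 -67.7 1.3 5.5 0.2  0.31 0.02    7 6.21 0.54
Val1590Ile control   8  -92.8 13.2   8 -20.7 0.6 6.8 0.2 -65.8 0.9 5.4 0.2  0.30 0.02    7 5.73 0.61
")
  short <- c(Ipeak_density_pA_per_pF = "dens", act_V12_mV = "av12",
             act_Vslope_mV = "avsl", inact_V12_mV = "iv12",
             inact_Vslope_mV = "ivsl", tau_inact_0mV_ms = "ti",
             tau_rec_ms = "tr")
  nFor <- c(dens = "nd", av12 = "nb", avsl = "nb", iv12 = "nb",
            ivsl = "nb", ti = "nb", tr = "nr")
  out <- data.frame(variant_id = d$variant_id, group = d$group,
                    n_density = d$nd, n_biophys = d$nb, n_rec = d$nr,
                    stringsAsFactors = FALSE)
  for (p in names(short)) {
    s <- short[[p]]
    out[[paste0("mean_", p)]] <- d[[paste0("m", s)]]
    out[[paste0("se_", p)]] <- d[[paste0("se", s)]]
    out[[paste0("sd_", p)]] <- d[[paste0("se", s)]] * sqrt(d[[nFor[[s]]]])
  }
  stars <- list(
    Ser682Trp = c("act_Vslope_mV", "tau_inact_0mV_ms"),
    Val1442Met = c("inact_V12_mV", "tau_rec_ms"),
    Arg1463Ser = c("Ipeak_density_pA_per_pF", "inact_V12_mV",
                   "inact_Vslope_mV", "tau_rec_ms"),
    Glu1520Lys = "Ipeak_density_pA_per_pF")
  for (p in names(short))
    out[[paste0("star_", p)]] <- vapply(out$variant_id, function(v)
      p %in% stars[[v]], logical(1), USE.NAMES = FALSE)
  out
}

#' Build a trace-level cohort specification from the reference table
#'
#' Converts one row of [nav14ReferenceCohorts()] into a [CohortSpec]: the
#' parameter means become the central [GatingParams], the per-cell spreads
#' become coefficients of variation, and the cohort size is the
#' current-density N (the largest tier; QC then thins the other tiers as
#' in real recordings).
#'
#' @param variantId row to use.
#' @param seed cohort seed.
#' @param nCells override the cohort size (default: the reference
#'   \code{n_density}).
#' @param noiseSdpA current noise sd, pA.
#' @param ref the reference table (defaults to [nav14ReferenceCohorts()]).
#' @return a [CohortSpec].
#' @export
cohortSpecFromReference <- function(variantId, seed = 1, nCells = NULL,
                                    noiseSdpA = 10,
                                    ref = nav14ReferenceCohorts()) {
  row <- ref[ref$variant_id == variantId, ]
  if (nrow(row) != 1L) stop("unknown reference cohort '", variantId, "'")
  pm <- new("GatingParams",
            gmaxDensity = 1, eRevmV = 65,
            actV12mV = row$mean_act_V12_mV,
            actSlopemV = row$mean_act_Vslope_mV,
            inactV12mV = row$mean_inact_V12_mV,
            inactSlopemV = row$mean_inact_Vslope_mV,
            tauInact0mVms = row$mean_tau_inact_0mV_ms,
            tauRecM80mVms = row$mean_tau_rec_ms,
            tauActms = 0.03, gateExponent = 3)
  cv <- c(peakDensity = row$sd_Ipeak_density_pA_per_pF /
            abs(row$mean_Ipeak_density_pA_per_pF),
          actV12 = row$sd_act_V12_mV / abs(row$mean_act_V12_mV),
          actSlope = row$sd_act_Vslope_mV / row$mean_act_Vslope_mV,
          inactV12 = row$sd_inact_V12_mV / abs(row$mean_inact_V12_mV),
          inactSlope = row$sd_inact_Vslope_mV / row$mean_inact_Vslope_mV,
          tauInact = row$sd_tau_inact_0mV_ms / row$mean_tau_inact_0mV_ms,
          tauRec = row$sd_tau_rec_ms / row$mean_tau_rec_ms)
  cohortSpec(variantId, if (is.null(nCells)) row$n_density else nCells,
             paramMeans = pm,
             peakDensityMean = row$mean_Ipeak_density_pA_per_pF,
             paramCV = cv, noiseSdpA = noiseSdpA, seed = seed)
}

#' Rare SCN4A variant records of the case-control cohorts
#'
#' The shipped variant table: six case-cohort and nine control-cohort rare
#' variants with their population allele frequencies (or NOVEL),
#' consequence, carrier counts, functional classification from the
#' expression studies and (for the functionally disruptive case variants)
#' the sub-cohort of origin.
#'
#' @return data.frame of variant records.
#' @examples
#' v <- scn4aVariants()
#' nrow(mafFilter(v))   # the 14 protein-altering rare variants
#' @export
scn4aVariants <- function() {
  readVariantTable(system.file("extdata", "scn4a_rare_variants.tsv",
                               package = "navclamp", mustWork = TRUE))
}
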