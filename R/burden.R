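#' @include classify.R
NULL

#' Read a rare-variant table
#'
#' Tab-separated table with one row per observed variant and columns
#' \code{variant_id}, \code{cdna_change}, \code{cohort}
#' (\code{case}/\code{control}), \code{exac_af} (population allele
#' frequency, or the string \code{NOVEL}), \code{consequence}
#' (\code{missense}/\code{intronic}/\code{other}), \code{carrier_count}
#' and optional \code{functional_class} and \code{region} columns.
#'
#' @param path TSV file path.
#' @return data.frame of variant records.
#' @export
readVariantTable <- function(path) {
  v <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(exac_af = "character"))
  need <- c("variant_id", "cohort", "exac_af", "consequence",
            "carrier_count")
  miss <- setdiff(need, names(v))
  if (length(miss)) stop("variant table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (any(!v$cohort %in% c("case", "control")))
    stop("cohort must be 'case' or 'control'")
  if (any(v$carrier_count < 1)) stop("carrier_count must be >= 1")
  v
}

isNovel <- function(af) toupper(trimws(as.character(af))) == "NOVEL" |
  is.na(af)

#' Filter variants by population allele frequency
#'
#' Retains variants that are novel (absent from the population database) or
#' whose allele frequency is strictly below the threshold (default
#' 0.00005).  With \code{proteinAlteringOnly = TRUE} (the default) intronic
#' records are dropped as well.
#'
#' @param records variant data.frame (see [readVariantTable()]).
#' @param threshold allele-frequency cutoff in (0, 1); strict less-than.
#' @param proteinAlteringOnly drop non-protein-altering (intronic) records.
#' @return the retained records.
#' @export
mafFilter <- function(records, threshold = 5e-5,
                      proteinAlteringOnly = TRUE) {
  stopifnot(threshold > 0, threshold < 1)
  novel <- isNovel(records$exac_af)
  af <- suppressWarnings(as.numeric(records$exac_af))
  keep <- novel | (!is.na(af) & af < threshold)
  if (proteinAlteringOnly) keep <- keep & records$consequence != "intronic"
  records[keep, , drop = FALSE]
}

#' One-tailed Fisher's exact test for carrier enrichment in cases
#'
#' Exact hypergeometric upper tail \eqn{P(X \ge a)} for the 2 x 2 table of
#' carriers versus non-carriers in cases and controls, with the enrichment
#' direction towards cases.  Full precision is returned; display rounding
#' is left to the caller.
#'
#' @param a carriers among cases.
#' @param nCases number of cases.
#' @param b carriers among controls.
#' @param nControls number of controls.
#' @return the one-tailed p-value.
#' @examples
#' fisherOneTailed(4, 278, 0, 729)   # 0.0057
#' @export
fisherOneTailed <- function(a, nCases, b, nControls) {
  stopifnot(a >= 0, b >= 0, a <= nCases, b <= nControls)
  stats::phyper(a - 1, nCases, nControls, a + b, lower.tail = FALSE)
}

selectRecords <- function(records, selector) {
  disruptive <- !is.na(records$functional_class) &
    records$functional_class %in% c("gain_of_function", "loss_of_function")
  switch(selector,
    all = rep(TRUE, nrow(records)),
    functional = disruptive,
    sensitivity = disruptive | records$consequence == "intronic",
    stop("unknown selector '", selector, "'"))
}

#' Carrier-level rare-variant burden test
#'
#' Counts carriers of qualifying variants per cohort (one carrier per
#' record; multi-variant carriers would be collapsed to one) and applies
#' the one-tailed Fisher exact test for enrichment in cases.  The selector
#' chooses which records qualify: all retained rare variants
#' (\code{"all"}), only functionally disruptive ones
#' (\code{"functional"}), or functionally disruptive plus intronic records
#' treated as deleterious (\code{"sensitivity"}).
#'
#' @param records variant data.frame (after [mafFilter()] as appropriate).
#' @param nCases,nControls cohort sizes.
#' @param selector \code{"all"}, \code{"functional"} or
#'   \code{"sensitivity"}.
#' @return data.frame row with the carrier counts, the one-tailed p, the
#'   case-carrier percentage (one decimal) and a note when no record
#'   qualifies.
#' @examples
#' v <- scn4aVariants()
#' carrierBurden(v, 278, 729, "functional")   # 4 vs 0, p = 0.0057
#' @export
carrierBurden <- function(records, nCases, nControls,
                          selector = c("all", "functional", "sensitivity")) {
  selector <- match.arg(selector)
  sel <- selectRecords(records, selector)
  a <- sum(records$carrier_count[sel & records$cohort == "case"])
  b <- sum(records$carrier_count[sel & records$cohort == "control"])
  note <- if (!any(sel)) "selector matched no records" else ""
  p <- if (!any(sel)) 1 else fisherOneTailed(a, nCases, b, nControls)
  data.frame(selector = selector, case_carriers = a, n_cases = nCases,
             control_carriers = b, n_controls = nControls, p = p,
             case_percent = round(100 * a / nCases, 1), note = note,
             stringsAsFactors = FALSE)
}

#' Variant-level burden of functional disruption
#'
#' Rows of the 2 x 2 table are the distinct variants (not their carriers):
#' functionally disruptive versus not, in the case versus the control
#' cohort, tested with the one-tailed Fisher exact test.  The control
#' denominator includes every retained control variant, the intronic one
#' included (the reading under which the variant-level table reproduces
#' the carrier data; see the methods vignette).
#'
#' @param records variant data.frame with \code{functional_class} labels
#'   for the coding variants.
#' @return data.frame row with variant counts per cohort, disruptive
#'   counts and the one-tailed p.
#' @examples
#' variantLevelBurden(scn4aVariants())   # 4 of 6 vs 0 of 9, p = 0.011
#' @export
variantLevelBurden <- function(records) {
  disruptive <- !is.na(records$functional_class) &
    records$functional_class %in% c("gain_of_function", "loss_of_function")
  caseIdx <- records$cohort == "case"
  nCaseVar <- sum(caseIdx)
  nCtlVar <- sum(!caseIdx)
  a <- sum(disruptive & caseIdx)
  b <- sum(disruptive & !caseIdx)
  p <- if (a + b == 0) 1 else fisherOneTailed(a, nCaseVar, b, nCtlVar)
  data.frame(case_variants = nCaseVar, case_disruptive = a,
             control_variants = nCtlVar, control_disruptive = b, p = p,
             stringsAsFactors = FALSE)
}
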