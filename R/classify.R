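#' @include variant-stats.R
NULL

## Rule tables mapping significant parameter shifts to functional evidence.
## "higher"/"lower" refer to the sign of (variant mean - wild-type mean) on
## the raw scale; for the (negative, inward) current density "higher" means
## a smaller-magnitude current, i.e. reduced functional expression.
gofRules <- function() data.frame(
  parameter = c("inact_V12_mV", "tau_rec_ms", "tau_inact_0mV_ms",
                "inact_Vslope_mV"),
  direction = c("higher", "lower", "higher", "higher"),
  meaning = c("depolarised shift of fast-inactivation midpoint",
              "faster recovery from inactivation",
              "slower onset of open-state inactivation",
              "shallower voltage dependence of inactivation"),
  stringsAsFactors = FALSE)

lofRules <- function() data.frame(
  parameter = c("Ipeak_density_pA_per_pF", "inact_V12_mV", "tau_rec_ms"),
  direction = c("higher", "lower", "higher"),
  meaning = c("reduced peak current density",
              "hyperpolarised shift of fast-inactivation midpoint",
              "slower recovery from inactivation"),
  stringsAsFactors = FALSE)

matchRules <- function(results, rules) {
  hits <- merge(results[results$significant, , drop = FALSE], rules,
                by = c("parameter", "direction"))
  if ("Ipeak_density_pA_per_pF" %in% hits$parameter) {
    # "reduced density" additionally requires a genuine magnitude drop
    i <- hits$parameter == "Ipeak_density_pA_per_pF"
    keep <- abs(hits$mean_variant[i]) < abs(hits$mean_wt[i])
    hits <- rbind(hits[!i, , drop = FALSE], hits[i, , drop = FALSE][keep, ,
                                                                   drop = FALSE])
  }
  hits
}

#' Classify one variant as gain of function, loss of function or wild-type
#' like
#'
#' Applies the precedence rules used for functional annotation of NaV1.4
#' variants: (1) no parameter significantly different from wild type gives
#' \code{wild_type_like}; (2) any significant inactivation-impairing change
#' (depolarised fast-inactivation midpoint, faster recovery, slower onset
#' of open-state inactivation, increased inactivation slope factor) gives
#' \code{gain_of_function}; (3) otherwise a significant reduction in
#' current density, a hyperpolarised inactivation midpoint or slower
#' recovery gives \code{loss_of_function}.  When both kinds of evidence are
#' present, gain of function takes precedence and the conflict is recorded
#' in the evidence table.  Significant shifts matching neither rule set
#' (for example an isolated change in the activation slope factor)
#' contribute no evidence.
#'
#' @param results comparison rows for one variant (from
#'   [compareVariants()]).
#' @return list with \code{variant_id}, \code{label}, \code{evidence}
#'   (data.frame of contributing comparisons with their reading) and
#'   \code{conflict} flag.
#' @export
classifyVariant <- function(results) {
  vid <- unique(results$variant_id)
  if (length(vid) != 1L)
    stop("classifyVariant() expects results for exactly one variant")
  gof <- matchRules(results, gofRules())
  lof <- matchRules(results, lofRules())
  # a parameter shift cannot count for both readings at once
  lof <- lof[!paste(lof$parameter, lof$direction) %in%
               paste(gof$parameter, gof$direction), , drop = FALSE]
  if (nrow(gof) == 0 && nrow(lof) == 0)
    return(list(variant_id = vid, label = "wild_type_like",
                evidence = data.frame(), conflict = FALSE))
  conflict <- nrow(gof) > 0 && nrow(lof) > 0
  if (nrow(gof) > 0) {
    ev <- rbind(cbind(gof, reading = "gain_of_function"),
                if (nrow(lof)) cbind(lof, reading = "loss_of_function"))
    return(list(variant_id = vid, label = "gain_of_function",
                evidence = ev, conflict = conflict))
  }
  list(variant_id = vid, label = "loss_of_function",
       evidence = cbind(lof, reading = "loss_of_function"),
       conflict = FALSE)
}

#' Classify all variants in a comparison table
#'
#' @param results output of [compareVariants()].
#' @return data.frame with \code{variant_id}, \code{label},
#'   \code{n_evidence}, \code{conflict} and a compact \code{evidence}
#'   string; the full per-variant evidence is attached as the
#'   \code{"details"} attribute.
#' @export
classifyVariants <- function(results) {
  vids <- unique(results$variant_id)
  det <- lapply(vids, function(v)
    classifyVariant(results[results$variant_id == v, , drop = FALSE]))
  names(det) <- vids
  out <- do.call(rbind, lapply(det, function(cl) data.frame(
    variant_id = cl$variant_id, label = cl$label,
    n_evidence = if (is.null(nrow(cl$evidence))) 0L else nrow(cl$evidence),
    conflict = cl$conflict,
    evidence = if (!NROW(cl$evidence)) "" else
      paste(sprintf("%s:%s", cl$evidence$parameter, cl$evidence$direction),
            collapse = ";"),
    stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  attr(out, "details") <- det
  out
}
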