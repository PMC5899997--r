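#' @include table2-data.R burden.R io.R
NULL

#' End-to-end run configuration
#'
#' Bundles everything one reproducible run needs: the cohort definitions
#' (reference-table shaped), simulation settings, analysis and statistics
#' settings, the burden inputs and the global seed.  Build with
#' [defaultRunConfig()] or [readRunConfig()].
#'
#' @slot cohorts data.frame shaped like [nav14ReferenceCohorts()].
#' @slot wildType wild-type cohort id.
#' @slot simMode \code{"params"} (draw fitted-parameter tables directly)
#'   or \code{"trace"} (simulate and re-fit full sweep data).
#' @slot sampleIntervalMs trace sampling interval, ms.
#' @slot noiseSdpA trace noise, pA.
#' @slot eRevPolicy,eRevFallback reversal-potential policy for the
#'   analysis.
#' @slot method post-hoc scheme, \code{"kw_dunn"} or
#'   \code{"anova_games_howell"}.
#' @slot alpha family-wise error target.
#' @slot variants burden variant records (see [readVariantTable()]).
#' @slot nCases,nControls burden cohort sizes.
#' @slot seed global seed; every stage derives named streams from it.
#' @export
setClass("RunConfig",
  representation(
    cohorts = "data.frame", wildType = "character",
    simMode = "character", sampleIntervalMs = "numeric",
    noiseSdpA = "numeric", eRevPolicy = "character",
    eRevFallback = "numeric", method = "character", alpha = "numeric",
    variants = "data.frame", nCases = "numeric", nControls = "numeric",
    seed = "numeric"
  )
)

## Validity is implemented as a standalone function (rather than
## setValidity) so that constructors and the pipeline can both reuse it and
## report configuration errors with a uniform "config error:" prefix.
validateRunConfig <- function(cfg) {
  if (!cfg@simMode %in% c("params", "trace"))
    stop("config error: simMode must be 'params' or 'trace'")
  if (!cfg@method %in% c("kw_dunn", "anova_games_howell"))
    stop("config error: unknown method '", cfg@method, "'")
  if (length(cfg@seed) != 1L || !is.finite(cfg@seed))
    stop("config error: a single numeric seed is required")
  if (cfg@alpha <= 0 || cfg@alpha >= 1)
    stop("config error: alpha must be in (0, 1)")
  if (nrow(cfg@cohorts) > 0) {
    if (!cfg@wildType %in% cfg@cohorts$variant_id)
      stop("config error: wild-type cohort '", cfg@wildType,
           "' not among the cohorts")
    need <- c("variant_id", "n_density", "n_biophys", "n_rec",
              paste0("mean_", testedParameters()),
              paste0("sd_", testedParameters()))
    miss <- setdiff(need, names(cfg@cohorts))
    if (length(miss))
      stop("config error: cohort table lacks columns: ",
           paste(miss, collapse = ", "))
  }
  if (nrow(cfg@variants) > 0) {
    known <- c(cfg@cohorts$variant_id, NA_character_)
    stats <- setdiff(cfg@variants$variant_id[
      cfg@variants$consequence != "intronic"], known)
    if (nrow(cfg@cohorts) > 0 && length(stats))
      stop("config error: burden variants without a cohort: ",
           paste(stats, collapse = ", "))
  }
  invisible(cfg)
}

#' Default shipped run configuration
#'
#' The 15 reference cohorts at their printed cell counts, the shipped
#' rare-variant table, 278 cases versus 729 controls, rank-based
#' statistics and parameter-level simulation.
#'
#' @param seed global seed.
#' @param simMode \code{"params"} or \code{"trace"}.
#' @param method post-hoc scheme.
#' @return a [RunConfig].
#' @export
defaultRunConfig <- function(seed = 1, simMode = "params",
                             method = "kw_dunn") {
  cfg <- new("RunConfig",
             cohorts = nav14ReferenceCohorts(), wildType = "WT",
             simMode = simMode, sampleIntervalMs = 0.005, noiseSdpA = 10,
             eRevPolicy = "per-cell", eRevFallback = 65,
             method = method, alpha = 0.05,
             variants = scn4aVariants(), nCases = 278, nControls = 729,
             seed = seed)
  validateRunConfig(cfg)
}

#' Read a run configuration from YAML
#'
#' Recognised keys: \code{seed}, \code{sim_mode}, \code{method},
#' \code{alpha}, \code{wild_type}, \code{sample_interval_ms},
#' \code{noise_sd_pA}, \code{erev_policy}, \code{erev_fallback},
#' \code{n_cases}, \code{n_controls}, \code{cohorts_tsv} and
#' \code{variants_tsv} (paths relative to the YAML file; omitted entries
#' fall back to the shipped defaults).  An explicit
#' \code{cohorts_tsv: none} runs with zero cohorts.
#'
#' @param path YAML file.
#' @return a validated [RunConfig].
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  cohorts <- nav14ReferenceCohorts()
  if (!is.null(y$cohorts_tsv)) {
    cohorts <- if (identical(y$cohorts_tsv, "none"))
      nav14ReferenceCohorts()[0, ] else
      utils::read.delim(resolve(y$cohorts_tsv), stringsAsFactors = FALSE)
  }
  variants <- if (!is.null(y$variants_tsv)) {
    if (identical(y$variants_tsv, "none"))
      scn4aVariants()[0, ] else readVariantTable(resolve(y$variants_tsv))
  } else scn4aVariants()
  pick <- function(key, default) if (is.null(y[[key]])) default else y[[key]]
  cfg <- new("RunConfig",
             cohorts = cohorts,
             wildType = pick("wild_type", "WT"),
             simMode = pick("sim_mode", "params"),
             sampleIntervalMs = pick("sample_interval_ms", 0.005),
             noiseSdpA = pick("noise_sd_pA", 10),
             eRevPolicy = pick("erev_policy", "per-cell"),
             eRevFallback = pick("erev_fallback", 65),
             method = pick("method", "kw_dunn"),
             alpha = pick("alpha", 0.05),
             variants = variants,
             nCases = pick("n_cases", 278),
             nControls = pick("n_controls", 729),
             seed = pick("seed", 1))
  validateRunConfig(cfg)
}

## FNV-1a hash of the canonical JSON serialisation, for the run manifest.
configHash <- function(cfg) {
  s <- jsonlite::toJSON(list(
    cohorts = cfg@cohorts, wildType = cfg@wildType, simMode = cfg@simMode,
    sampleIntervalMs = cfg@sampleIntervalMs, noiseSdpA = cfg@noiseSdpA,
    eRevPolicy = cfg@eRevPolicy, eRevFallback = cfg@eRevFallback,
    method = cfg@method, alpha = cfg@alpha, variants = cfg@variants,
    nCases = cfg@nCases, nControls = cfg@nControls, seed = cfg@seed),
    digits = NA)
  h <- 2166136261
  for (b in as.integer(charToRaw(as.character(s)))) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

simulateCellsTable <- function(cfg) {
  if (nrow(cfg@cohorts) == 0) return(data.frame())
  if (cfg@simMode == "params")
    return(simulateParameterTable(cfg@cohorts, seed = cfg@seed))
  protocols <- buildStandardProtocols(cfg@sampleIntervalMs)
  rows <- lapply(seq_len(nrow(cfg@cohorts)), function(i) {
    co <- cfg@cohorts[i, ]
    spec <- cohortSpecFromReference(co$variant_id,
                                    seed = streamSeed(cfg@seed, "cohort",
                                                      co$variant_id),
                                    noiseSdpA = cfg@noiseSdpA,
                                    ref = cfg@cohorts)
    coh <- generateCohort(spec, protocols, noise = cfg@noiseSdpA > 0)
    analyzeCohort(coh$cells, eRevPolicy = cfg@eRevPolicy,
                  eRevFallback = cfg@eRevFallback)
  })
  do.call(rbind, rows)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full pipeline: simulate, analyse, test, classify, burden
#'
#' Executes all stages in order and writes \code{cells.tsv},
#' \code{variants_summary.tsv}, \code{comparisons.tsv},
#' \code{classification.tsv}, \code{burden.tsv} and a \code{manifest.json}
#' (configuration hash, seed, package version) to the output directory.
#' Identical configuration and seed give byte-identical outputs.  The
#' burden stage uses the pipeline's own functional classification for
#' every variant that was simulated; records without a cohort (the
#' intronic control variant) keep their shipped annotation.
#'
#' @param config a [RunConfig].
#' @param outDir output directory (created if needed).
#' @return invisibly, a list with the in-memory results
#'   (\code{cells}, \code{summary}, \code{comparisons},
#'   \code{classification}, \code{burden}, \code{manifest}).
#' @export
runPipeline <- function(config, outDir) {
  validateRunConfig(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  cells <- stage("simulate", simulateCellsTable(config))
  summary <- stage("summarize",
                   if (nrow(cells)) summarizeVariant(cells) else
                     data.frame())
  haveVariants <- nrow(config@cohorts) > 1 && nrow(cells) > 0
  comparisons <- stage("stats",
    if (haveVariants)
      compareVariants(cells, config@wildType, config@method,
                      config@alpha) else data.frame())
  classification <- stage("classify",
    if (nrow(comparisons)) classifyVariants(comparisons) else
      data.frame())
  burden <- stage("burden", {
    v <- config@variants
    if (nrow(v) && nrow(classification)) {
      hit <- match(v$variant_id, classification$variant_id)
      v$functional_class[!is.na(hit)] <-
        classification$label[hit[!is.na(hit)]]
    }
    if (nrow(v)) {
      rare <- mafFilter(v, proteinAlteringOnly = FALSE)
      coding <- rare[rare$consequence != "intronic", , drop = FALSE]
      carr <- do.call(rbind, lapply(
        c("all", "functional", "sensitivity"), function(s)
          carrierBurden(rare, config@nCases, config@nControls, s)))
      vl <- variantLevelBurden(rare)
      rbind(
        data.frame(test = "carrier", selector = carr$selector,
                   case_count = carr$case_carriers,
                   case_total = carr$n_cases,
                   control_count = carr$control_carriers,
                   control_total = carr$n_controls, p = carr$p,
                   case_percent = carr$case_percent,
                   stringsAsFactors = FALSE),
        data.frame(test = "variant_level", selector = "functional",
                   case_count = vl$case_disruptive,
                   case_total = vl$case_variants,
                   control_count = vl$control_disruptive,
                   control_total = vl$control_variants, p = vl$p,
                   case_percent = NA_real_, stringsAsFactors = FALSE))
    } else data.frame()
  })
  manifest <- list(config_hash = configHash(config), seed = config@seed,
                   sim_mode = config@simMode,
                   package_version =
                     as.character(utils::packageVersion("navclamp")),
                   config = list(
                     wild_type = config@wildType, method = config@method,
                     alpha = config@alpha,
                     sample_interval_ms = config@sampleIntervalMs,
                     noise_sd_pA = config@noiseSdpA,
                     erev_policy = config@eRevPolicy,
                     erev_fallback = config@eRevFallback,
                     n_cases = config@nCases,
                     n_controls = config@nControls,
                     cohorts = config@cohorts$variant_id))
  stage("write", {
    writeTsvWithSchema(cells, file.path(outDir, "cells.tsv"))
    writeTsvWithSchema(summary, file.path(outDir, "variants_summary.tsv"))
    writeTsvWithSchema(comparisons, file.path(outDir, "comparisons.tsv"))
    writeTsvWithSchema(classification, file.path(outDir, "classification.tsv"))
    writeTsvWithSchema(burden, file.path(outDir, "burden.tsv"))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  })
  invisible(list(cells = cells, summary = summary,
                 comparisons = comparisons,
                 classification = classification, burden = burden,
                 manifest = manifest))
}

#' Miniature three-cohort fixture set for fast end-to-end checks
#'
#' Three cohorts of five cells: wild type, a variant drawn from identical
#' parameters, and a variant with ten-fold reduced current density.  Full
#' trace simulation with modest cell-to-cell variability; ground truth
#' included.
#'
#' @param seed integer seed.
#' @return list with \code{specs}, \code{cells} (all [CellRecording]s) and
#'   \code{truth}.
#' @export
makeFixtures <- function(seed = 1) {
  protocols <- buildStandardProtocols()
  cv <- c(peakDensity = 0.1, actV12 = 0.05, actSlope = 0.05,
          inactV12 = 0.02, inactSlope = 0.05, tauInact = 0.05,
          tauRec = 0.05)
  specs <- list(
    cohortSpec("WT", 5, paramCV = cv, seed = streamSeed(seed, "fx", "WT")),
    cohortSpec("IDENT", 5, paramCV = cv,
               seed = streamSeed(seed, "fx", "IDENT")),
    cohortSpec("LOWDENS", 5, peakDensityMean = -12.75, paramCV = cv,
               seed = streamSeed(seed, "fx", "LOWDENS")))
  out <- lapply(specs, generateCohort, protocols = protocols)
  list(specs = specs,
       cells = do.call(c, lapply(out, `[[`, "cells")),
       truth = do.call(rbind, lapply(out, `[[`, "truth")))
}
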