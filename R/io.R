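#' @include cohort.R
NULL

protocolToList <- function(p) {
  list(name = p@name, holding_mV = p@holdingmV,
       epochs = lapply(seq_len(nrow(p@epochs)), function(i) list(
         label = p@epochs$label[i],
         voltage_mV = p@epochs$voltage_mV[i],
         duration_ms = p@epochs$duration_ms[i])),
       sweep_values = p@sweepValues, sweep_dim = p@sweepDim,
       sample_interval_ms = p@sampleIntervalMs)
}

protocolFromList <- function(l) {
  ep <- do.call(rbind, lapply(l$epochs, function(e) data.frame(
    label = e$label,
    voltage_mV = if (is.null(e$voltage_mV)) NA_real_ else e$voltage_mV,
    duration_ms = if (is.null(e$duration_ms)) NA_real_ else e$duration_ms,
    stringsAsFactors = FALSE)))
  voltageProtocol(l$name, l$holding_mV, ep, unlist(l$sweep_values),
                  l$sweep_dim, l$sample_interval_ms)
}

#' Write one cell's recordings as TSV sweep tables with a JSON sidecar
#'
#' Per protocol a tab-separated table (first column \code{time_ms}, one
#' column per sweep, currents in pA) named
#' \code{<cell>_<protocol>.tsv}, plus \code{<cell>.json} holding the cell
#' metadata and the full protocol definitions.
#'
#' @param cell a [CellRecording].
#' @param dir output directory (created if needed).
#' @return invisibly, the sidecar path.
#' @export
writeCellRecording <- function(cell, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in recordingNames(cell)) {
    rec <- getRecording(cell, nm)
    tab <- data.frame(time_ms = sweepTimes(rec$protocol),
                      rec$sweeps, check.names = FALSE)
    names(tab) <- c("time_ms",
                    paste0("sweep_", seq_len(ncol(rec$sweeps))))
    utils::write.table(
      format(tab, digits = 9, trim = TRUE, scientific = FALSE),
      file.path(dir, paste0(cellId(cell), "_", nm, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  sidecar <- file.path(dir, paste0(cellId(cell), ".json"))
  meta <- list(cell_id = cellId(cell), variant_id = variantId(cell),
               capacitance_pF = capacitance(cell),
               series_resistance_MOhm = seriesResistance(cell),
               protocols = lapply(cell@protocols, protocolToList))
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(sidecar)
}

#' Write a whole cohort of cells
#'
#' @param cells list of [CellRecording].
#' @param dir output directory.
#' @return invisibly, \code{dir}.
#' @export
writeCohort <- function(cells, dir) {
  for (cell in cells) writeCellRecording(cell, dir)
  invisible(dir)
}

#' Read one cell back from its TSV + JSON sidecar representation
#'
#' @param dir directory holding the files.
#' @param cellId the cell identifier.
#' @return a [CellRecording].
#' @export
readCellRecording <- function(dir, cellId) {
  meta <- jsonlite::read_json(file.path(dir, paste0(cellId, ".json")),
                              simplifyVector = FALSE)
  protocols <- lapply(meta$protocols, protocolFromList)
  names(protocols) <- vapply(protocols, function(p) p@name, character(1))
  recordings <- lapply(names(protocols), function(nm) {
    tab <- utils::read.delim(file.path(dir, paste0(cellId, "_", nm,
                                                   ".tsv")))
    as.matrix(tab[, -1, drop = FALSE])
  })
  names(recordings) <- names(protocols)
  new("CellRecording", cellId = meta$cell_id,
      variantId = meta$variant_id,
      capacitancepF = meta$capacitance_pF,
      seriesResistanceMOhm = meta$series_resistance_MOhm,
      recordings = recordings, protocols = protocols)
}

#' List the cell identifiers stored in a trace directory
#'
#' @param dir directory written by [writeCohort()].
#' @return character vector of cell ids.
#' @export
listCellIds <- function(dir) {
  sub("\\.json$", "", basename(Sys.glob(file.path(dir, "*.json"))))
}

writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## TSV plus a JSON schema sidecar (column names and types), so every
## pipeline output is self-describing and machine-checkable.
writeTsvWithSchema <- function(x, path) {
  writeTsv(x, path)
  schema <- lapply(seq_along(x), function(i) list(
    name = names(x)[i], type = class(x[[i]])[1]))
  jsonlite::write_json(list(columns = schema),
                       paste0(path, ".schema.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
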