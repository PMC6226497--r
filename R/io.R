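# Plain-text interchange: photon streams as two-column TSV with a JSON
# metadata sidecar; surfaces and histograms as CSV.

#' Write a photon trace to TSV (+ JSON sidecar)
#'
#' Columns `time_s` and `channel` (`donor`/`acceptor`); the trace id,
#' duration and metadata go into `<path>.json`.
#'
#' @param trace a [PhotonTrace-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writePhotonTrace <- function(trace, path) {
  df <- data.frame(time_s = trace@arrivalTimes,
                   channel = c("donor", "acceptor")[trace@channels + 1L])
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  side <- list(traceId = trace@traceId, duration = trace@duration,
               metadata = trace@metadata)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a photon trace from TSV (+ JSON sidecar)
#'
#' @param path TSV path written by [writePhotonTrace()] (or any two-column
#'   `time_s`/`channel` table; a `<path>.json` sidecar is used if present).
#' @return a [PhotonTrace-class].
#' @export
readPhotonTrace <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c("numeric", "character"))
  side <- if (file.exists(paste0(path, ".json")))
    jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  else list()
  photonTrace(df$time_s, df$channel,
              traceId = side$traceId %||% basename(path),
              duration = side$duration %||% NULL,
              metadata = as.list(side$metadata %||% list()))
}

#' Export a likelihood surface as long-format CSV
#'
#' Columns `tau_s`, `E`, `deltaLnL`.
#'
#' @param surface a [LikelihoodSurface-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeSurfaceCSV <- function(surface, path) {
  df <- expand.grid(tau_s = surface@tauGrid, E = surface@eGrid)
  df$deltaLnL <- as.numeric(surface@deltaLnL)
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a lifetime histogram as CSV
#'
#' Columns `edge_lo_s`, `edge_hi_s`, `count`.
#'
#' @param hist a [TauHistogram-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeHistogramCSV <- function(hist, path) {
  k <- length(hist@counts)
  df <- data.frame(edge_lo_s = hist@edges[seq_len(k)],
                   edge_hi_s = hist@edges[seq_len(k) + 1],
                   count = hist@counts)
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
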