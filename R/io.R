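#' Read an LFP recording from disk
#'
#' Supports two on-disk dialects: EDF (European Data Format, 16-bit integer
#' samples rescaled to physical units per header) and a raw fixture format
#' (little-endian 32-bit float samples in a `.f32` file plus a JSON sidecar
#' holding `fs`, `channel_id`, `n_samples` and `units`).
#'
#' Samples are returned in microvolts. The only rescaling ever applied is
#' the declared EDF physical-unit conversion (e.g. a `mV` physical dimension
#' is multiplied by 1000); the loader never resamples.
#'
#' @param path Path to the `.edf` or `.f32` file.
#' @param format `"auto"` (by extension), `"edf"` or `"fixture"`.
#' @param channel For EDF files with several signals, the 1-based signal
#'   index to load.
#' @return An [lfp_recording].
#' @seealso [write_recording()]
#' @export
read_recording <- function(path, format = c("auto", "fixture", "edf"),
                           channel = 1L) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, edf = "edf", f32 = "fixture",
                     stop_srseize("cannot infer format from extension '.",
                                  ext, "'; pass format="))
  }
  if (!file.exists(path)) stop_srseize("file not found: ", path)
  if (format == "fixture") read_fixture(path) else read_edf(path, channel)
}

#' Write an LFP recording to disk
#'
#' @param rec An [lfp_recording].
#' @param path Output path (`.f32` or `.edf`).
#' @param format `"auto"`, `"fixture"` or `"edf"`. The fixture format stores
#'   samples as little-endian 32-bit floats with a JSON sidecar
#'   (`<path minus extension>.json`); EDF stores 16-bit integers scaled over
#'   the recording's amplitude range.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("auto", "fixture", "edf")) {
  stopifnot(inherits(rec, "lfp_recording"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, edf = "edf", f32 = "fixture",
                     stop_srseize("cannot infer format from extension '.",
                                  ext, "'; pass format="))
  }
  if (format == "fixture") write_fixture(rec, path) else write_edf(rec, path)
  invisible(path)
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

read_fixture <- function(path) {
  n_bytes <- file.info(path)$size
  if (is.na(n_bytes) || n_bytes == 0)
    stop_srseize("empty or unreadable fixture file: ", path)
  if (n_bytes %% 4L != 0L)
    stop_srseize("fixture size ", n_bytes, " bytes is not a multiple of 4")
  sc <- sidecar_path(path)
  if (!file.exists(sc)) stop_srseize("missing JSON sidecar: ", sc)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  for (f in c("fs", "n_samples")) if (is.null(meta[[f]]))
    stop_srseize("sidecar lacks required field '", f, "'")
  n <- n_bytes / 4L
  if (n != meta$n_samples)
    stop_srseize("sidecar n_samples (", meta$n_samples,
                 ") disagrees with file size (", n, " samples)")
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = n, size = 4L, endian = "little")
  bad <- which(!is.finite(x))
  if (length(bad))
    stop_srseize("non-finite sample at index ", bad[1L], " in ", path)
  lfp_recording(x, fs = meta$fs,
                channel_id = if (!is.null(meta$channel_id)) meta$channel_id else "ch1",
                provenance = paste0("fixture:", basename(path)))
}

write_fixture <- function(rec, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  # float32 is lossless for simulated data generated at that precision
  writeBin(rec$samples, con, size = 4L, endian = "little")
  close(con); on.exit()
  meta <- list(fs = rec$fs, channel_id = rec$channel_id,
               n_samples = length(rec$samples), units = "uV")
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write detected or ground-truth events to CSV
#'
#' Columns are `onset_s`, `offset_s`, `duration_s` (derived) plus any
#' further attribute columns present. Times are seconds from recording
#' start, 0-based, half-open intervals `[onset, offset)`.
#'
#' @param events Data frame with at least `onset_s` and `offset_s`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  events <- validate_events(events)
  extra <- setdiff(names(events), c("onset_s", "offset_s", "duration_s"))
  out <- data.frame(onset_s = events$onset_s, offset_s = events$offset_s,
                    duration_s = events$offset_s - events$onset_s)
  for (cl in extra) out[[cl]] <- events[[cl]]
  write.csv(format(out, digits = 15, scientific = FALSE, trim = TRUE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an events CSV
#'
#' @param path CSV written by [write_events()] (or any CSV with `onset_s`
#'   and `offset_s` columns).
#' @return Data frame of events; rows with `offset_s <= onset_s` raise an
#'   error naming the offending row.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop_srseize("file not found: ", path)
  ev <- read.csv(path, stringsAsFactors = FALSE)
  validate_events(ev)
}

validate_events <- function(ev) {
  if (!is.data.frame(ev))
    stop_srseize("events must be a data frame")
  need <- c("onset_s", "offset_s")
  miss <- setdiff(need, names(ev))
  if (length(miss)) stop_srseize("events lack column(s): ",
                                 paste(miss, collapse = ", "))
  if (nrow(ev)) {
    bad <- which(ev$offset_s <= ev$onset_s)
    if (length(bad))
      stop_srseize("offset_s <= onset_s at row ", bad[1L])
  }
  if (!"duration_s" %in% names(ev))
    ev$duration_s <- ev$offset_s - ev$onset_s
  ev[order(ev$onset_s), , drop = FALSE]
}
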