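#' Construct an LFP recording
#'
#' A single-channel local field potential (LFP) time series in microvolts
#' with its sampling metadata. This is the raw input to seizure detection.
#'
#' @param samples Numeric vector of samples in microvolts. Must be finite.
#' @param fs Sampling rate in Hz (scalar, > 0). Recordings in this package
#'   are nominally sampled at 2 kHz with content below 500 Hz.
#' @param channel_id Channel label.
#' @param start_time Optional `POSIXct` start timestamp.
#' @param provenance Free-text provenance note (file of origin, simulation
#'   settings, unit conversions applied).
#'
#' @return An object of class `lfp_recording`: a list with elements
#'   `samples`, `fs`, `channel_id`, `start_time`, `provenance`.
#' @examples
#' rec <- lfp_recording(rnorm(2000, sd = 10), fs = 2000)
#' duration_s(rec)
#' @export
lfp_recording <- function(samples, fs, channel_id = "ch1",
                          start_time = NULL, provenance = "") {
  if (!is.numeric(samples) || length(samples) < 1L)
    stop_srseize("'samples' must be a non-empty numeric vector")
  bad <- which(!is.finite(samples))
  if (length(bad))
    stop_srseize("non-finite sample(s) at index ", bad[1L],
                 " (", length(bad), " total)")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop_srseize("'fs' must be a positive scalar (Hz)")
  structure(
    list(samples = as.numeric(samples), fs = as.numeric(fs),
         channel_id = as.character(channel_id), start_time = start_time,
         provenance = as.character(provenance)),
    class = "lfp_recording")
}

#' Recording duration in seconds
#' @param rec An `lfp_recording`.
#' @return Duration in seconds (`n_samples / fs`).
#' @export
duration_s <- function(rec) {
  stopifnot(inherits(rec, "lfp_recording"))
  length(rec$samples) / rec$fs
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("LFP recording '%s': %d samples @ %g Hz (%.1f s)\n",
              x$channel_id, length(x$samples), x$fs, duration_s(x)))
  cat(sprintf("  amplitude range [%.2f, %.2f] uV, SD %.2f uV\n",
              min(x$samples), max(x$samples), sd(x$samples)))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}
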