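# Minimal EDF (European Data Format) I/O.
#
# EDF: a 256-byte ASCII main header, then 256 ASCII bytes per signal
# (16-byte label, 80 transducer, 8 physical dimension, 8 physical min,
# 8 physical max, 8 digital min, 8 digital max, 80 prefiltering,
# 8 samples-per-record, 32 reserved, each field stored contiguously for
# all signals), then data records of little-endian 16-bit integers.
# Physical value = physmin + (digital - digmin) * (physmax - physmin)
#                                              / (digmax - digmin).

edf_pad <- function(s, width) {
  s <- as.character(s)
  if (nchar(s, type = "bytes") > width) s <- substr(s, 1L, width)
  sprintf(paste0("%-", width, "s"), s)
}

edf_num <- function(x, width) {
  for (d in 7:1) {
    s <- formatC(x, format = "g", digits = d)
    if (nchar(s) <= width) return(edf_pad(s, width))
  }
  stop_srseize("cannot encode ", x, " in ", width, " header chars")
}

read_edf <- function(path, channel = 1L) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 256)
    stop_srseize("not a valid EDF file (", sz, " bytes): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256L, useBytes = TRUE)
  field <- function(str, from, len) substr(str, from + 1L, from + len)
  num <- function(str, from, len) {
    v <- suppressWarnings(as.numeric(trimws(field(str, from, len))))
    if (is.na(v)) stop_srseize("corrupt EDF header field at byte ", from)
    v
  }
  header_bytes <- num(hdr, 184, 8)
  n_records   <- num(hdr, 236, 8)
  record_dur  <- num(hdr, 244, 8)
  ns          <- as.integer(num(hdr, 252, 4))
  if (ns < 1L || header_bytes != 256L * (1L + ns))
    stop_srseize("corrupt EDF header: ns=", ns,
                 ", header bytes=", header_bytes)
  if (channel < 1L || channel > ns)
    stop_srseize("channel ", channel, " out of range (file has ", ns, ")")
  sig_hdr <- readChar(con, 256L * ns, useBytes = TRUE)
  sfield <- function(from_block, len, i)
    trimws(substr(sig_hdr, from_block * ns + (i - 1L) * len + 1L,
                  from_block * ns + i * len))
  # byte offsets of the per-signal blocks within the signal header
  off <- cumsum(c(0L, 16L, 80L, 8L, 8L, 8L, 8L, 8L, 80L, 8L))
  labels   <- vapply(seq_len(ns), function(i) sfield(off[1], 16, i), "")
  physdim  <- vapply(seq_len(ns), function(i) sfield(off[3], 8, i), "")
  physmin  <- as.numeric(vapply(seq_len(ns), function(i) sfield(off[4], 8, i), ""))
  physmax  <- as.numeric(vapply(seq_len(ns), function(i) sfield(off[5], 8, i), ""))
  digmin   <- as.numeric(vapply(seq_len(ns), function(i) sfield(off[6], 8, i), ""))
  digmax   <- as.numeric(vapply(seq_len(ns), function(i) sfield(off[7], 8, i), ""))
  spr      <- as.integer(vapply(seq_len(ns), function(i) sfield(off[9], 8, i), ""))
  if (anyNA(c(physmin, physmax, digmin, digmax, spr)))
    stop_srseize("corrupt EDF signal header in ", path)
  rec_len <- sum(spr)
  raw_all <- readBin(con, "integer", n = rec_len * n_records, size = 2L,
                     signed = TRUE, endian = "little")
  if (length(raw_all) < rec_len * n_records)
    stop_srseize("EDF data truncated: expected ", rec_len * n_records,
                 " samples, found ", length(raw_all))
  # gather this channel's slice from every record
  start_in_rec <- sum(spr[seq_len(channel - 1L)])
  idx <- as.vector(outer(seq_len(spr[channel]) + start_in_rec,
                         (seq_len(n_records) - 1L) * rec_len, `+`))
  dig <- raw_all[idx]
  scale <- (physmax[channel] - physmin[channel]) /
           (digmax[channel] - digmin[channel])
  phys <- physmin[channel] + (dig - digmin[channel]) * scale
  unit <- physdim[channel]
  mult <- switch(tolower(unit), "uv" = 1, "µv" = 1, "mv" = 1e3,
                 "v" = 1e6, 1)
  fs <- spr[channel] / record_dur
  lfp_recording(phys * mult, fs = fs, channel_id = labels[channel],
                provenance = sprintf("edf:%s unit=%s x%g", basename(path),
                                     unit, mult))
}

write_edf <- function(rec, path) {
  x <- rec$samples
  n <- length(x)
  pm <- max(abs(x))
  if (pm == 0) pm <- 1
  digmin <- -32768L; digmax <- 32767L
  physmin <- -pm; physmax <- pm
  dig <- as.integer(round((x - physmin) / (physmax - physmin) *
                            (digmax - digmin) + digmin))
  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(s) writeChar(s, con, eos = NULL, useBytes = TRUE)
  # main header: one data record holding the whole recording
  put(edf_pad("0", 8))                        # version
  put(edf_pad("X X X X", 80))                 # patient id
  put(edf_pad(paste0("Startdate X srseize ", rec$channel_id), 80))
  put(edf_pad("01.01.26", 8))                 # start date
  put(edf_pad("00.00.00", 8))                 # start time
  put(edf_pad("512", 8))                      # header bytes, 1 signal
  put(edf_pad("", 44))                        # reserved
  put(edf_pad("1", 8))                        # number of data records
  put(edf_num(n / rec$fs, 8))                 # record duration (s)
  put(edf_pad("1", 4))                        # number of signals
  # signal header
  put(edf_pad(rec$channel_id, 16))
  put(edf_pad("", 80))                        # transducer
  put(edf_pad("uV", 8))
  put(edf_num(physmin, 8))
  put(edf_num(physmax, 8))
  put(edf_pad(digmin, 8))
  put(edf_pad(digmax, 8))
  put(edf_pad("HP:0Hz LP:500Hz", 80))
  put(edf_pad(n, 8))                          # samples per record
  put(edf_pad("", 32))
  writeBin(dig, con, size = 2L, endian = "little")
  invisible(path)
}
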