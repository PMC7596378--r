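# EDF (European Data Format) input/output. The format: a 256-byte ASCII
# global header, 256 ASCII bytes per signal, then data records of 16-bit
# little-endian integers mapped linearly from [dig_min, dig_max] to
# [phys_min, phys_max]. One-second records are used, so fs must be a whole
# number of samples per second.

pad_field <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  substr(s, 1, width)
}

num_field <- function(raw, off, width, what) {
  s <- trimws(rawToChar(raw[(off + 1):(off + width)]))
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v)) {
    stop(sprintf("malformed EDF header: non-numeric %s at byte offset %d",
                 what, off), call. = FALSE)
  }
  v
}

#' Write an EEG recording as EDF
#'
#' 16-bit EDF with physical dimension microvolts, one-second data records
#' and a symmetric physical range covering the signal.
#'
#' @param rec an `eeg_recording` with integer `fs`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (fs != round(fs)) stop("EDF export needs an integer sampling rate",
                            call. = FALSE)
  ns <- nrow(rec$data)
  n_rec <- floor(ncol(rec$data) / fs)
  data <- rec$data[, seq_len(n_rec * fs), drop = FALSE]
  phys_max <- max(1, ceiling(max(abs(data))))
  phys_min <- -phys_max
  dig_max <- 32767L; dig_min <- -32768L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field(paste0("X X X ", rec$subject_id), 80),
    pad_field("Startdate X X X X synthetic neonatal EEG", 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256 * (1 + ns), 8),
    pad_field("", 44),
    pad_field(n_rec, 8),
    pad_field(1, 8),
    pad_field(ns, 4),
    paste(pad_field(rec$channel_labels, 16), collapse = ""),
    paste(rep(pad_field("synthetic", 80), ns), collapse = ""),
    paste(rep(pad_field("uV", 8), ns), collapse = ""),
    paste(rep(pad_field(phys_min, 8), ns), collapse = ""),
    paste(rep(pad_field(phys_max, 8), ns), collapse = ""),
    paste(rep(pad_field(dig_min, 8), ns), collapse = ""),
    paste(rep(pad_field(dig_max, 8), ns), collapse = ""),
    paste(rep(pad_field("HP:0.5Hz LP:30Hz", 80), ns), collapse = ""),
    paste(rep(pad_field(fs, 8), ns), collapse = ""),
    paste(rep(pad_field("", 32), ns), collapse = "")
  )
  writeChar(hdr, con, eos = NULL)
  scale <- (dig_max - dig_min) / (phys_max - phys_min)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    for (s in seq_len(ns)) {
      dig <- round((data[s, cols] - phys_min) * scale) + dig_min
      dig <- pmin(pmax(dig, dig_min), dig_max)
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file into an EEG recording
#'
#' Parses the header, validates the declared sizes against the file length
#' (a truncated file is an error, never a partial recording) and converts
#' the 16-bit samples back to physical units. A physical dimension of mV
#' or V triggers a warning and conversion to microvolts.
#'
#' @param path EDF file path.
#' @return an `eeg_recording`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 256) {
    stop("malformed EDF header: file shorter than 256 bytes (offset 0)",
         call. = FALSE)
  }
  get_str <- function(off, width) trimws(rawToChar(raw[(off + 1):(off + width)]))
  subject <- get_str(8, 80)
  n_rec <- num_field(raw, 236, 8, "record count")
  rec_dur <- num_field(raw, 244, 8, "record duration")
  ns <- as.integer(num_field(raw, 252, 4, "signal count"))
  hdr_len <- 256 * (1 + ns)
  if (length(raw) < hdr_len) {
    stop(sprintf("malformed EDF header: file ends inside signal headers (offset %d)",
                 length(raw)), call. = FALSE)
  }
  sig_field <- function(width, off0, numeric = FALSE) {
    vapply(seq_len(ns), function(i) {
      off <- 256 + off0 * ns + (i - 1) * width
      if (numeric) num_field(raw, off, width, "signal header field")
      else get_str(off, width)
    }, if (numeric) numeric(1) else character(1))
  }
  labels <- sig_field(16, 0)
  dims <- sig_field(8, 96)   # after 16-byte label + 80-byte transducer
  phys_min <- sig_field(8, 104, TRUE)
  phys_max <- sig_field(8, 112, TRUE)
  dig_min <- sig_field(8, 120, TRUE)
  dig_max <- sig_field(8, 128, TRUE)
  spr <- as.integer(sig_field(8, 216, TRUE))

  expected <- hdr_len + 2 * n_rec * sum(spr)
  if (length(raw) < expected) {
    stop(sprintf("truncated EDF file: expected %d bytes, found %d",
                 expected, length(raw)), call. = FALSE)
  }
  vals <- readBin(raw[(hdr_len + 1):expected], "integer",
                  n = n_rec * sum(spr), size = 2, endian = "little",
                  signed = TRUE)
  data <- matrix(0, nrow = ns, ncol = n_rec * spr[1],
                 dimnames = list(labels, NULL))
  pos <- 0L
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      seg <- vals[(pos + 1):(pos + spr[s])]
      pos <- pos + spr[s]
      phys <- phys_min[s] +
        (seg - dig_min[s]) * (phys_max[s] - phys_min[s]) /
          (dig_max[s] - dig_min[s])
      data[s, ((r - 1) * spr[s] + 1):(r * spr[s])] <- phys
    }
  }
  for (s in seq_len(ns)) {
    unit <- tolower(dims[s])
    if (unit %in% c("mv", "v")) {
      warning("EDF signal '", labels[s], "' stored in ", dims[s],
              "; converting to uV", call. = FALSE)
      data[s, ] <- data[s, ] * if (unit == "mv") 1e3 else 1e6
    }
  }
  structure(
    list(data = data, fs = spr[1] / rec_dur, channel_labels = labels,
         subject_id = sub("^X X X ", "", subject), ga_weeks = NA_real_,
         state = NULL, burst_onsets = NULL),
    class = "eeg_recording"
  )
}
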