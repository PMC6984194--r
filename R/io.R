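# File I/O: EDF recordings, TSV/JSON event and command logs, JSON configs.
#
# The EDF writer/reader below implements the plain 16-bit EDF layout (one
# data record per second, all channels at the recording rate). It covers
# exactly what the simulator and pipeline need; it is not a general-purpose
# EDF+ library.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' @param recording An [eeg_recording()].
#' @param path Output file path.
#' @param patient,recording_id Free-text EDF header fields.
#' @return `path`, invisibly. Trailing samples that do not fill a whole
#'   1 s data record are dropped.
#' @export
write_edf <- function(recording, path, patient = "X", recording_id = "smrbci") {
  fs <- recording$fs
  if (abs(fs - round(fs)) > 1e-9) {
    abort_validation("EDF export requires an integer sampling rate")
  }
  fs <- as.integer(round(fs))
  x <- recording$data
  ns <- ncol(x)
  n_rec <- floor(nrow(x) / fs)
  if (n_rec < 1L) abort_validation("recording shorter than one EDF record (1 s)")
  x <- x[seq_len(n_rec * fs), , drop = FALSE]

  phys_min <- apply(x, 2, min)
  phys_max <- apply(x, 2, max)
  flat <- phys_max - phys_min < 1e-12
  phys_min[flat] <- phys_min[flat] - 1
  phys_max[flat] <- phys_max[flat] + 1
  dig_min <- -32768
  dig_max <- 32767

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeChar(paste0(
    edf_pad("0", 8), edf_pad(patient, 80), edf_pad(recording_id, 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 + ns * 256, 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(1, 8), edf_pad(ns, 4),
    paste(edf_pad(paste("EEG", recording$channels), 16), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad("uV", 8), ns), collapse = ""),
    paste(edf_pad(signif(phys_min, 7), 8), collapse = ""),
    paste(edf_pad(signif(phys_max, 7), 8), collapse = ""),
    paste(rep(edf_pad(dig_min, 8), ns), collapse = ""),
    paste(rep(edf_pad(dig_max, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad(fs, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 32), ns), collapse = "")
  ), con, eos = NULL)

  scale <- (dig_max - dig_min) / (phys_max - phys_min)
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1L) * fs + 1L):(r * fs)
    for (ch in seq_len(ns)) {
      dig <- round((x[rows, ch] - phys_min[ch]) * scale[ch] + dig_min)
      writeBin(as.integer(pmin(pmax(dig, dig_min), dig_max)), con,
               size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' @param path EDF file path.
#' @return An [eeg_recording()]. Quantization to the 16-bit EDF grid means
#'   values round-trip only to the per-channel amplitude resolution.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  version <- hdr(8)
  if (version != "0") abort_validation("not an EDF file (bad version field)")
  invisible(hdr(80)); invisible(hdr(80)); invisible(hdr(8)); invisible(hdr(8))
  invisible(hdr(8)); invisible(hdr(44))
  n_rec <- as.integer(hdr(8))
  rec_dur <- as.numeric(hdr(8))
  ns <- as.integer(hdr(4))
  field <- function(w) vapply(seq_len(ns), function(i) hdr(w), character(1))
  labels <- sub("^EEG ", "", field(16))
  invisible(field(80)); invisible(field(8))
  phys_min <- as.numeric(field(8))
  phys_max <- as.numeric(field(8))
  dig_min <- as.numeric(field(8))
  dig_max <- as.numeric(field(8))
  invisible(field(80))
  spr <- as.integer(field(8))
  invisible(field(32))
  if (length(unique(spr)) != 1L) {
    abort_validation("mixed per-signal sampling rates are not supported")
  }
  fs <- spr[1] / rec_dur
  out <- matrix(0, nrow = n_rec * spr[1], ncol = ns)
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2L,
                     endian = "little", signed = TRUE)
      rows <- ((r - 1L) * spr[ch] + 1L):(r * spr[ch])
      out[rows, ch] <- (dig - dig_min[ch]) * scale[ch] + phys_min[ch]
    }
  }
  eeg_recording(out, fs = fs, channels = labels)
}

#' Write / read event tables
#'
#' Event and command logs are stored as tab-separated text with columns
#' `time_s` and `label`, or as JSON arrays of `{time_s, label}` records.
#'
#' @param events A tibble with columns `time`, `label` (see [event_table()]).
#' @param path File path; format chosen by extension (`.tsv` or `.json`).
#' @return `path` invisibly (write) or an event tibble (read).
#' @export
write_events <- function(events, path) {
  out <- tibble(time_s = events$time, label = events$label)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, dataframe = "rows", digits = NA)
  } else {
    readr::write_tsv(out, path, progress = FALSE)
  }
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    out <- jsonlite::fromJSON(path)
  } else {
    out <- readr::read_tsv(path, col_types = readr::cols(
      time_s = readr::col_double(), label = readr::col_character()))
  }
  event_table(time = out$time_s, label = out$label)
}

#' Write / read a simulation configuration as JSON
#'
#' @param config A [sim_config()].
#' @param path JSON file path.
#' @return `path` invisibly (write) or a [sim_config()] (read).
#' @export
write_sim_config <- function(config, path) {
  raw <- unclass(config)
  # named numeric vectors serialize as bare arrays; keep channel names
  raw$topographies <- lapply(raw$topographies, as.list)
  jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- jsonlite::fromJSON(path)
  raw$topographies <- lapply(raw$topographies, function(v) unlist(v))
  do.call(sim_config, raw)
}
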