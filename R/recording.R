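#' Standard 24-channel montage
#'
#' Channel labels of the 24-channel 10-20 subset used throughout the package:
#' frontal, central, temporal, centro-parietal, parietal and occipital sites
#' as recorded by a mobile 24-channel EEG amplifier.
#'
#' @return Character vector of 24 channel labels.
#' @export
montage_24 <- function() {
  c("FP1", "FP2", "F7", "F8", "FZ", "FC1", "FC2", "T7", "C3", "CZ",
    "C4", "T8", "TP9", "CP5", "CP1", "CPz", "CP2", "CP6", "TP10",
    "P3", "PZ", "P4", "O1", "O2")
}

#' Sensorimotor channel set
#'
#' Channels over sensorimotor cortex used for plausibility checks of spatial
#' patterns and filters.
#'
#' @return Character vector of channel labels.
#' @export
sensorimotor_channels <- function() {
  c("C3", "CZ", "C4", "FC1", "FC2", "CP1", "CPz", "CP2", "CP5", "CP6")
}

#' Construct a continuous EEG recording
#'
#' @param data Numeric matrix, samples in rows and channels in columns.
#' @param fs Sampling rate in Hz.
#' @param channels Character vector of channel labels (defaults to the
#'   column names of `data`).
#'
#' @return An object of class `eeg_recording`: a list with elements `data`,
#'   `fs` and `channels`.
#' @export
eeg_recording <- function(data, fs, channels = colnames(data)) {
  if (!is.matrix(data) || !is.numeric(data)) {
    abort_validation("`data` must be a numeric matrix (samples x channels)")
  }
  check_scalar(fs, "fs", lower = 1)
  if (is.null(channels)) channels <- paste0("ch", seq_len(ncol(data)))
  if (length(channels) != ncol(data)) {
    abort_validation("`channels` length must equal ncol(data)")
  }
  colnames(data) <- channels
  structure(list(data = data, fs = fs, channels = channels),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              length(x$channels), nrow(x$data), x$fs,
              nrow(x$data) / x$fs))
  invisible(x)
}

n_samples <- function(recording) nrow(recording$data)

#' Duration of a recording in seconds
#'
#' @param recording An `eeg_recording`.
#' @return Length of the recording in seconds.
#' @export
recording_duration <- function(recording) {
  n_samples(recording) / recording$fs
}

#' Construct an event table
#'
#' Events are plain tibbles with columns `time` (seconds from recording
#' start) and `label`. Times must be non-decreasing.
#'
#' @param time Numeric vector of event times in seconds.
#' @param label Character vector of event labels.
#' @return A tibble with columns `time`, `label`.
#' @export
event_table <- function(time = numeric(), label = character()) {
  if (length(time) != length(label)) {
    abort_validation("`time` and `label` must have equal length")
  }
  if (is.unsorted(time, strictly = FALSE)) {
    abort_validation("event times must be non-decreasing")
  }
  tibble(time = as.numeric(time), label = as.character(label))
}

event_labels <- function() {
  c("rest_onset", "led_onset", "flexion_onset", "extension_onset",
    "command_open", "command_close", "command_grasp",
    "movement_flexion", "movement_extension", "phase_move", "phase_rest")
}
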