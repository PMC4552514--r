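#' Multichannel EEG recording container
#'
#' A lightweight S3 container for a continuous multichannel recording:
#' a channels-by-time numeric matrix plus sampling rate, channel labels,
#' unit-sphere electrode positions and a processing-stage tag. Amplitudes
#' are in microvolts until current source density referencing, after which
#' they are in microvolts per square metre.
#'
#' @param data Numeric matrix, channels x time.
#' @param fs Sampling rate in Hz.
#' @param positions data.frame with columns `label`, `x`, `y`, `z`
#'   (unit sphere), one row per channel, in channel order.
#' @param stage Processing stage tag, one of `"raw"`, `"filtered"`,
#'   `"ocular_corrected"`, `"csd"`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, positions, stage = "raw") {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("`data` must be a numeric channels-by-time matrix", call. = FALSE)
  }
  stopifnot_scalar(fs, "fs", min = 1e-9)
  stage <- match.arg(stage, c("raw", "filtered", "ocular_corrected", "csd"))
  if (!is.data.frame(positions) ||
      !all(c("label", "x", "y", "z") %in% names(positions))) {
    stop("`positions` must have columns label, x, y, z", call. = FALSE)
  }
  if (nrow(positions) != nrow(data)) {
    stop("`positions` must have one row per channel", call. = FALSE)
  }
  rownames(data) <- positions$label
  structure(list(data = data, fs = fs, labels = positions$label,
                 positions = positions, stage = stage),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), stage: %s\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs, x$stage))
  cat("  channels:", paste(x$labels, collapse = " "), "\n")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec An `eeg_recording`.
#' @return Duration in seconds.
#' @export
recording_duration <- function(rec) ncol(rec$data) / rec$fs

check_stage <- function(rec, expected, op) {
  if (!identical(rec$stage, expected)) {
    stop(sprintf("%s expects a recording at stage '%s' (got '%s')",
                 op, expected, rec$stage), call. = FALSE)
  }
  invisible(TRUE)
}

set_stage <- function(rec, stage) {
  rec$stage <- stage
  rec
}

#' Fixed-length epoch set
#'
#' Holds fixed-length, contiguous, non-overlapping segments of a recording
#' together with per-epoch accept/reject status. Built by [segment_epochs()]
#' and annotated by [reject_epochs()].
#'
#' @param epochs 3-d numeric array, epoch x channel x time.
#' @param fs Sampling rate in Hz.
#' @param labels Channel labels (length = dim 2).
#' @param epoch_length Epoch length in seconds.
#' @param stage Stage tag inherited from the source recording.
#' @return An object of class `eeg_epochs` with `accepted` and
#'   `rejection_reason` fields (all accepted, reason `"none"` initially).
#' @export
eeg_epochs <- function(epochs, fs, labels, epoch_length, stage = "raw") {
  stopifnot(length(dim(epochs)) == 3L, dim(epochs)[2] == length(labels))
  if (dim(epochs)[3] != round(epoch_length * fs)) {
    stop("epoch sample count must equal epoch_length * fs", call. = FALSE)
  }
  n <- dim(epochs)[1]
  structure(list(epochs = epochs, fs = fs, labels = labels,
                 epoch_length = epoch_length, stage = stage,
                 accepted = rep(TRUE, n),
                 rejection_reason = rep("none", n)),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs> %d epochs x %d channels x %d samples (%g s @ %g Hz), %d accepted\n",
              dim(x$epochs)[1], dim(x$epochs)[2], dim(x$epochs)[3],
              x$epoch_length, x$fs, sum(x$accepted)))
  invisible(x)
}

#' Number of epochs in an epoch set
#' @param eps An `eeg_epochs` object.
#' @param accepted_only Count only accepted epochs?
#' @return Integer count.
#' @export
n_epochs <- function(eps, accepted_only = FALSE) {
  if (accepted_only) sum(eps$accepted) else dim(eps$epochs)[1]
}
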