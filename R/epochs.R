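#' Segment a recording into fixed-length epochs
#'
#' Cuts a recording into contiguous, non-overlapping epochs of
#' `epoch_length` seconds (default 5 s), discarding any trailing partial
#' epoch. Epoching is not locked to task events.
#'
#' @param rec An `eeg_recording`.
#' @param epoch_length Epoch length in seconds.
#' @param span Optional numeric `c(start, end)` in seconds restricting the
#'   segmented span (e.g. from first card to last feedback); the whole
#'   recording is used when omitted.
#' @return An `eeg_epochs` object (all epochs initially accepted).
#' @export
segment_epochs <- function(rec, epoch_length = 5, span = NULL) {
  stopifnot_scalar(epoch_length, "epoch_length", min = 1e-9)
  data <- rec$data
  if (!is.null(span)) {
    if (length(span) != 2L || span[1] < 0 ||
        span[2] > recording_duration(rec) || span[1] >= span[2]) {
      stop("`span` must be c(start, end) seconds within the recording",
           call. = FALSE)
    }
    idx <- (floor(span[1] * rec$fs) + 1L):floor(span[2] * rec$fs)
    data <- data[, idx, drop = FALSE]
  }
  nsamp <- round(epoch_length * rec$fs)
  n_ep <- floor(ncol(data) / nsamp)
  if (n_ep < 1L) {
    stop(sprintf("recording span (%.2f s) is shorter than one %g s epoch",
                 ncol(data) / rec$fs, epoch_length), call. = FALSE)
  }
  arr <- array(NA_real_, dim = c(n_ep, nrow(data), nsamp))
  for (e in seq_len(n_ep)) {
    arr[e, , ] <- data[, ((e - 1L) * nsamp + 1L):(e * nsamp)]
  }
  eeg_epochs(arr, fs = rec$fs, labels = rec$labels,
             epoch_length = epoch_length, stage = rec$stage)
}

#' Reject artifact-contaminated epochs
#'
#' Flags an epoch as rejected when, on any of the inspected channels, the
#' absolute amplitude exceeds `amp_thresh` or the peak-to-peak range
#' exceeds `ptp_thresh`. Intended for CSD-referenced data, where the
#' default thresholds are 500 uV/m^2 (amplitude) and 800 uV/m^2
#' (peak-to-peak). When both rules fire, the amplitude reason is recorded.
#'
#' @param eps An `eeg_epochs` object at stage `"csd"` (override with
#'   `require_csd = FALSE` to threshold other stages).
#' @param amp_thresh Absolute amplitude threshold.
#' @param ptp_thresh Peak-to-peak threshold.
#' @param channels Channels inspected (default: all channels present).
#' @param require_csd Insist on CSD-stage input?
#' @return The epoch set with updated `accepted` and `rejection_reason`.
#' @export
reject_epochs <- function(eps, amp_thresh = 500, ptp_thresh = 800,
                          channels = NULL, require_csd = TRUE) {
  if (require_csd && !identical(eps$stage, "csd")) {
    stop("reject_epochs expects CSD-referenced epochs", call. = FALSE)
  }
  stopifnot_scalar(amp_thresh, "amp_thresh", min = 0)
  stopifnot_scalar(ptp_thresh, "ptp_thresh", min = 0)
  ci <- if (is.null(channels)) seq_along(eps$labels) else
    match(channels, eps$labels)
  if (anyNA(ci)) stop("unknown channel in `channels`", call. = FALSE)
  n <- n_epochs(eps)
  reason <- rep("none", n)
  for (e in seq_len(n)) {
    x <- eps$epochs[e, ci, , drop = FALSE]
    mx <- apply(x, 2, max)
    mn <- apply(x, 2, min)
    if (any(pmax(abs(mx), abs(mn)) > amp_thresh)) {
      reason[e] <- "amplitude"
    } else if (any(mx - mn > ptp_thresh)) {
      reason[e] <- "peak_to_peak"
    }
  }
  eps$rejection_reason <- reason
  eps$accepted <- reason == "none"
  eps
}

#' Per-epoch rejection report
#'
#' @param eps An `eeg_epochs` object after [reject_epochs()].
#' @return data.frame with `epoch`, `accepted`, `reason`.
#' @export
rejection_report <- function(eps) {
  data.frame(epoch = seq_len(n_epochs(eps)),
             accepted = eps$accepted,
             reason = eps$rejection_reason,
             stringsAsFactors = FALSE)
}
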