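# Minimal EDF (European Data Format) writer/reader for continuous
# recordings: standard 256-byte header plus 256 bytes per signal, 16-bit
# little-endian samples in 1 s data records, per-channel physical scaling.

pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

#' Write a recording to an EDF file
#'
#' Samples are scaled per channel to the 16-bit digital range; the
#' recording is truncated to whole 1 s data records.
#'
#' @param rec An `eeg_recording` (any stage; the stage tag is stored in the
#'   EDF recording-id field and restored on read).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  fs <- round(rec$fs)
  n_rec <- floor(ncol(rec$data) / fs)
  if (n_rec < 1) stop("recording shorter than one 1 s EDF record",
                      call. = FALSE)
  ns <- nrow(rec$data)
  data <- rec$data[, seq_len(n_rec * fs), drop = FALSE]
  pmax_ <- apply(abs(data), 1, max)
  pmax_[pmax_ == 0] <- 1
  dig_max <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8), pad("synthetic subject", 80),
    pad(paste("stage:", rec$stage), 80),
    pad("01.01.00", 8), pad("00.00.00", 8),
    pad(256 * (ns + 1), 8), pad("", 44),
    pad(n_rec, 8), pad(1, 8), pad(ns, 4),
    paste(vapply(rec$labels, pad, "", width = 16), collapse = ""),
    paste(rep(pad("", 80), ns), collapse = ""),
    paste(rep(pad("uV", 8), ns), collapse = ""),
    paste(vapply(sprintf("%.6g", -pmax_), pad, "", width = 8),
          collapse = ""),
    paste(vapply(sprintf("%.6g", pmax_), pad, "", width = 8),
          collapse = ""),
    paste(rep(pad(-dig_max, 8), ns), collapse = ""),
    paste(rep(pad(dig_max, 8), ns), collapse = ""),
    paste(rep(pad("", 80), ns), collapse = ""),
    paste(rep(pad(fs, 8), ns), collapse = ""),
    paste(rep(pad("", 32), ns), collapse = ""))
  writeChar(hdr, con, eos = NULL)
  scale <- dig_max / pmax_
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    block <- round(data[, idx, drop = FALSE] * scale)
    writeBin(as.integer(t(block)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' @param path EDF file path.
#' @param positions Optional positions data.frame; electrode positions are
#'   looked up from the standard montage by label when omitted.
#' @return An `eeg_recording`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)
  rd(80)
  stage <- sub("^stage: *", "", rd(80))
  if (!stage %in% c("raw", "filtered", "ocular_corrected", "csd")) {
    stage <- "raw"
  }
  rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1L) {
    stop("mixed sampling rates are not supported", call. = FALSE)
  }
  fs <- spr[1] / rec_dur
  data <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = ns * spr[1], size = 2,
                   endian = "little")
    data[, ((r - 1) * spr[1] + 1):(r * spr[1])] <-
      matrix(raw, nrow = ns, byrow = TRUE)
  }
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  data <- data * scale + (pmax_ - scale * dmax)
  positions <- montage_1020(labels)
  eeg_recording(data, fs = fs, positions = positions, stage = stage)
}
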