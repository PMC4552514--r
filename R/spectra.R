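# Epoch-averaged spectra, individualized bands, band power and coherence.

#' Estimate epoch-averaged auto- and cross-spectra
#'
#' Computes Hann-tapered periodograms and cross-periodograms for each
#' accepted epoch and averages them across epochs. The taper is power
#' normalized so that the one-sided PSD integrates (trapezoid rule) to the
#' signal variance. With 5 s epochs the frequency resolution is 0.2 Hz.
#'
#' @param eps An `eeg_epochs` object with at least 2 accepted epochs
#'   (coherence is undefined from a single epoch: its magnitude-squared
#'   value is identically 1).
#' @param channels Channels to analyze (default: the 12 pooled channels if
#'   all present, otherwise all channels).
#' @return A `spectrum_set`: list with `freqs` (Hz), `psd`
#'   (channels x freqs), `cross` (channels x channels x freqs, complex,
#'   conjugate-symmetric in the channel pair), `channels`,
#'   `n_epochs_used`, `df`.
#' @export
estimate_spectra <- function(eps, channels = NULL) {
  if (is.null(channels)) {
    channels <- if (all(pool_channels() %in% eps$labels)) pool_channels()
                else eps$labels
  }
  ci <- match(channels, eps$labels)
  if (anyNA(ci)) {
    stop("unknown channel(s): ",
         paste(channels[is.na(ci)], collapse = ", "), call. = FALSE)
  }
  keep <- which(eps$accepted)
  if (length(keep) < 2L) {
    stop(sprintf("need >= 2 accepted epochs to estimate spectra (have %d)",
                 length(keep)), call. = FALSE)
  }
  nsamp <- dim(eps$epochs)[3]
  nfreq <- floor(nsamp / 2) + 1L
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nsamp) / nsamp)  # Hann
  U <- sum(w^2)
  scale <- 2 / (eps$fs * U)            # one-sided density scaling
  nc <- length(ci)
  cross <- array(0 + 0i, dim = c(nc, nc, nfreq))
  for (e in keep) {
    Fm <- matrix(0 + 0i, nc, nfreq)
    for (j in seq_len(nc)) {
      x <- eps$epochs[e, ci[j], ]
      Fm[j, ] <- stats::fft((x - mean(x)) * w)[seq_len(nfreq)]
    }
    for (a in seq_len(nc)) {
      for (b in a:nc) {
        s <- Fm[a, ] * Conj(Fm[b, ])
        cross[a, b, ] <- cross[a, b, ] + s
        if (b > a) cross[b, a, ] <- cross[b, a, ] + Conj(s)
      }
    }
  }
  cross <- cross * (scale / length(keep))
  # one-sided doubling does not apply at DC / Nyquist
  cross[, , 1] <- cross[, , 1] / 2
  if (nsamp %% 2 == 0) cross[, , nfreq] <- cross[, , nfreq] / 2
  psd <- matrix(NA_real_, nc, nfreq, dimnames = list(channels, NULL))
  for (j in seq_len(nc)) psd[j, ] <- pmax(Re(cross[j, j, ]), 0)
  structure(list(freqs = (seq_len(nfreq) - 1L) * eps$fs / nsamp,
                 psd = psd, cross = cross, channels = channels,
                 n_epochs_used = length(keep), df = eps$fs / nsamp),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d channels, %d frequency bins (0-%.1f Hz, df = %g Hz), %d epochs averaged\n",
              length(x$channels), length(x$freqs), max(x$freqs), x$df,
              x$n_epochs_used))
  invisible(x)
}

band_bins <- function(freqs, band) {
  which(freqs >= band[1] - 1e-9 & freqs <= band[2] + 1e-9)
}

#' Detect the individual alpha peak frequency of an electrode pool
#'
#' The alpha peak frequency (APF) is the frequency of maximal pool-averaged
#' power on the 8-13 Hz grid (edges inclusive). Ties break toward the lower
#' frequency. When the peak is not prominent (less than 5% above the
#' in-window median, e.g. on a monotone 1/f spectrum) the estimate is
#' returned with a low-confidence flag.
#'
#' @param spec A `spectrum_set`.
#' @param pool Character vector of the pool's channels.
#' @param window APF search window in Hz.
#' @return List with `apf` (Hz) and `low_confidence` (logical).
#' @export
detect_apf <- function(spec, pool, window = c(8, 13)) {
  ci <- match(pool, spec$channels)
  if (anyNA(ci)) stop("pool channel(s) missing from the spectrum set",
                      call. = FALSE)
  bins <- band_bins(spec$freqs, window)
  if (length(bins) < 2L) {
    stop("frequency grid does not cover the APF search window", call. = FALSE)
  }
  pavg <- colMeans(spec$psd[ci, bins, drop = FALSE])
  imax <- which.max(pavg)   # which.max takes the first (lowest-f) maximum
  # low confidence when there is no interior peak structure: the maximum
  # sits on a window edge (monotone spectrum) or barely rises above the
  # in-window median
  list(apf = spec$freqs[bins[imax]],
       low_confidence = imax == 1L || imax == length(bins) ||
         pavg[imax] < 1.05 * stats::median(pavg))
}

#' Individualized band limits anchored at the alpha peak
#'
#' Alpha spans APF +/- 2 Hz; theta spans APF - 7 Hz to APF - 3 Hz.
#'
#' @param apf Alpha peak frequency in Hz, within 8-13.
#' @return List with `alpha` and `theta`, each `c(lo, hi)` in Hz.
#' @export
band_limits <- function(apf) {
  stopifnot_scalar(apf, "apf")
  if (apf < 8 || apf > 13) {
    stop(sprintf("APF %.2f Hz outside the 8-13 Hz alpha window", apf),
         call. = FALSE)
  }
  list(alpha = c(apf - 2, apf + 2), theta = c(apf - 7, apf - 3))
}

#' Band power of an electrode pool
#'
#' Integrates the PSD over the band (trapezoid rule on the discrete grid,
#' both edge bins inclusive) per channel, then averages over the pool's
#' channels.
#'
#' @param spec A `spectrum_set`.
#' @param pool Character vector of channels (a single channel works too).
#' @param band `c(lo, hi)` in Hz.
#' @return Band power (units: signal units squared).
#' @export
band_power <- function(spec, pool, band) {
  ci <- match(pool, spec$channels)
  if (anyNA(ci)) stop("pool channel(s) missing from the spectrum set",
                      call. = FALSE)
  bins <- band_bins(spec$freqs, band)
  if (length(bins) < 2L ||
      band[1] < min(spec$freqs) - 1e-9 || band[2] > max(spec$freqs) + 1e-9) {
    stop("band outside the frequency grid", call. = FALSE)
  }
  wts <- rep(1, length(bins))
  wts[c(1L, length(bins))] <- 0.5
  mean(spec$psd[ci, bins, drop = FALSE] %*% wts) * spec$df
}

#' Magnitude-squared coherence between two electrode pools
#'
#' For each of the cross-pool channel pairs, the magnitude-squared
#' coherence msc(w) = |C_ij(w)|^2 / (C_ii(w) C_jj(w)) is formed from the
#' epoch-averaged cross- and auto-spectra, averaged over the band bins
#' (edges inclusive), and finally averaged over the 9 pairs.
#'
#' @param spec A `spectrum_set` with `n_epochs_used >= 2`.
#' @param poolA,poolB Character vectors of channels (disjoint).
#' @param band `c(lo, hi)` in Hz.
#' @param squared Return magnitude-squared coherence (default); `FALSE`
#'   returns its square root (magnitude coherence).
#' @return Coherence in \[0, 1\].
#' @export
pool_coherence <- function(spec, poolA, poolB, band, squared = TRUE) {
  if (length(intersect(poolA, poolB))) {
    stop("pools must be disjoint", call. = FALSE)
  }
  ia <- match(poolA, spec$channels)
  ib <- match(poolB, spec$channels)
  if (anyNA(ia) || anyNA(ib)) {
    stop("pool channel(s) missing from the spectrum set", call. = FALSE)
  }
  if (spec$n_epochs_used < 2L) {
    stop("coherence from a single epoch is identically 1; need >= 2 epochs",
         call. = FALSE)
  }
  bins <- band_bins(spec$freqs, band)
  if (!length(bins)) stop("band outside the frequency grid", call. = FALSE)
  vals <- numeric(0)
  for (a in ia) {
    for (b in ib) {
      saa <- Re(spec$cross[a, a, bins])
      sbb <- Re(spec$cross[b, b, bins])
      if (any(saa <= 0) || any(sbb <= 0)) {
        stop("zero auto-spectrum in band (degenerate channel)", call. = FALSE)
      }
      msc <- Mod(spec$cross[a, b, bins])^2 / (saa * sbb)
      vals <- c(vals, mean(msc))
    }
  }
  out <- mean(vals)
  if (!squared) out <- sqrt(out)
  out
}

#' Baseline-correct a task-period feature
#'
#' @param task_value Feature value during the task.
#' @param baseline_value Feature value during the pre-task baseline.
#' @param mode `"subtract"` (task - baseline) or `"log_ratio"`
#'   (10 log10(task / baseline), power-type features only).
#' @return Corrected value, with the mode recorded as an attribute.
#' @export
baseline_correct <- function(task_value, baseline_value,
                             mode = c("subtract", "log_ratio")) {
  mode <- match.arg(mode)
  out <- if (mode == "subtract") {
    task_value - baseline_value
  } else {
    if (any(task_value <= 0) || any(baseline_value <= 0)) {
      stop("log-ratio baseline correction needs positive values",
           call. = FALSE)
    }
    10 * log10(task_value / baseline_value)
  }
  attr(out, "correction") <- mode
  out
}

#' Lateral asymmetry of the alpha peak frequency
#'
#' Signed left-minus-right difference of the alpha peak frequencies of two
#' homologous pools (frontal FL-FR or parietal PL-PR).
#'
#' @param apf_left,apf_right APF estimates in Hz, either bare numbers or the
#'   lists returned by [detect_apf()].
#' @return Difference in Hz; carries a `low_confidence` attribute when
#'   either input was flagged.
#' @export
apf_asymmetry <- function(apf_left, apf_right) {
  lc <- (is.list(apf_left) && isTRUE(apf_left$low_confidence)) ||
    (is.list(apf_right) && isTRUE(apf_right$low_confidence))
  l <- if (is.list(apf_left)) apf_left$apf else apf_left
  r <- if (is.list(apf_right)) apf_right$apf else apf_right
  out <- l - r
  if (lc) attr(out, "low_confidence") <- TRUE
  out
}
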