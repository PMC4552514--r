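# Synthetic multichannel EEG with known spectral ground truth.
#
# Signals are built in the frequency domain as random-phase surrogates: a
# prescribed one-sided PSD with uniformly random phases, inverted to a real
# time series. The amplitude spectrum is deterministic, so band powers of
# the generated components equal their targets exactly and only phases are
# random. Inter-regional coherence is planted with shared band-limited
# sources added to both pools of a pair; for a shared source of in-band SNR
# gamma on two channels with independent equal-power noise the
# magnitude-squared coherence is (gamma / (1 + gamma))^2, which gives the
# generator a closed-form oracle.

#' Random-phase surrogate with a prescribed one-sided PSD
#'
#' @param n Number of samples.
#' @param fs Sampling rate (Hz).
#' @param psd One-sided PSD (units^2/Hz) on the grid `(0:(n/2)) * fs / n`.
#' @param seed RNG seed.
#' @return Numeric time series of length `n` whose periodogram follows
#'   `psd` exactly (random phases only).
#' @export
spectral_noise <- function(n, fs, psd, seed) {
  nf <- floor(n / 2) + 1L
  stopifnot(length(psd) == nf)
  df <- fs / n
  amp <- n * sqrt(psd * df / 2)
  amp[1] <- 0                                # no DC
  if (n %% 2 == 0) amp[nf] <- 0              # drop Nyquist bin
  phases <- with_seed(seed, stats::runif(nf, 0, 2 * pi))
  Xh <- amp * exp(1i * phases)
  Xfull <- c(Xh, Conj(Xh[seq(nf - 1 + n %% 2, 2)]))
  Re(stats::fft(Xfull, inverse = TRUE)) / n
}

freq_grid <- function(n, fs) (0:(floor(n / 2))) * fs / n

psd_one_over_f <- function(freqs, total_power, band = c(0.3, 100),
                           alpha = 1, white_frac = 0.1) {
  s <- numeric(length(freqs))
  sel <- freqs >= band[1] & freqs <= band[2]
  s[sel] <- 1 / pmax(freqs[sel], band[1])^alpha
  w <- numeric(length(freqs))
  w[sel] <- 1
  df <- freqs[2] - freqs[1]
  s <- s / sum(s * df) * (1 - white_frac) + w / sum(w * df) * white_frac
  s * total_power
}

psd_bump <- function(freqs, center, sigma, band, total_power) {
  s <- exp(-(freqs - center)^2 / (2 * sigma^2))
  s[freqs < band[1] | freqs > band[2]] <- 0
  df <- freqs[2] - freqs[1]
  tot <- sum(s * df)
  if (tot <= 0) stop("empty spectral bump", call. = FALSE)
  s / tot * total_power
}

psd_flat <- function(freqs, band, total_power) {
  s <- as.numeric(freqs >= band[1] & freqs <= band[2])
  df <- freqs[2] - freqs[1]
  tot <- sum(s * df)
  if (tot <= 0) stop("empty flat band", call. = FALSE)
  s / tot * total_power
}

psd_band_power <- function(freqs, psd, band) {
  sel <- freqs >= band[1] - 1e-9 & freqs <= band[2] + 1e-9
  sum(psd[sel]) * (freqs[2] - freqs[1])
}

#' Synthesize a coherent channel pair with known coherence
#'
#' Two channels sharing a band-limited source of in-band SNR `gamma` over
#' independent white noise. The analytic magnitude-squared coherence inside
#' `band` is `(gamma / (1 + gamma))^2`.
#'
#' @param gamma In-band SNR of the shared source (>= 0).
#' @param duration Length in seconds.
#' @param fs Sampling rate (Hz).
#' @param band Shared-source band `c(lo, hi)` in Hz.
#' @param seed RNG seed.
#' @param noise_density One-sided noise PSD level.
#' @param guard Widening (Hz) of the shared-source band beyond `band`, so
#'   that taper leakage does not dilute the source at the analysis band's
#'   edge bins.
#' @return List with `data` (2 x n matrix), `fs`, `band`, `msc_expected`.
#' @export
coherent_pair <- function(gamma, duration, fs, band = c(8, 12), seed = 1L,
                          noise_density = 1, guard = 0.5) {
  stopifnot_scalar(gamma, "gamma", min = 0)
  n <- round(duration * fs)
  freqs <- freq_grid(n, fs)
  noise_psd <- rep(noise_density, length(freqs))
  src_psd <- numeric(length(freqs))
  src_psd[freqs >= band[1] - guard & freqs <= band[2] + guard] <-
    gamma * noise_density
  seeds <- derive_seeds(seed, 3L)
  s <- spectral_noise(n, fs, src_psd, seeds[1])
  x <- s + spectral_noise(n, fs, noise_psd, seeds[2])
  y <- s + spectral_noise(n, fs, noise_psd, seeds[3])
  list(data = rbind(x, y), fs = fs, band = band,
       msc_expected = (gamma / (1 + gamma))^2)
}

blink_template <- function(fs, amplitude, width = 0.3, lowpass = 6) {
  # 300 ms raised-cosine transient, band-limited below ~6 Hz: a real
  # blink carries essentially no alpha-band energy, and the sharp pulse's
  # spectral sidelobes would otherwise contaminate the alpha band
  blink_len <- round(width * fs)
  pad <- round(0.2 * fs)
  x <- c(numeric(pad),
         0.5 - 0.5 * cos(2 * pi * seq_len(blink_len) / (blink_len + 1)),
         numeric(pad))
  n <- length(x)
  freqs <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) * fs / n
  g <- butter_lowpass_mag2(abs(freqs), lowpass, 4L)
  y <- Re(stats::fft(stats::fft(x) * g, inverse = TRUE)) / n
  amplitude * y / max(y)
}

blink_weight_map <- function(positions) {
  # frontally dominant, spatially smooth (dipole-like) pattern: ~1 at the
  # fronto-polar sites decaying to a small parietal floor; kept smooth so
  # the surface Laplacian of the blink topography stays moderate
  0.01 + 0.99 * ((positions$y + 1) / 2)^5
}

pool_weight_map <- function(montage, members) {
  # compact regional pattern: unit weight on the pool members only, so
  # cross-pool coherence comes solely from the planted shared sources
  as.numeric(montage$label %in% members)
}

#' Synthesize a subject's multichannel EEG recording
#'
#' Builds a recording realizing a subject's spectral ground truth: per
#' channel a 1/f background with white floor, a near-uniform low-frequency
#' global field, per-pool alpha oscillators centred at the subject's alpha
#' peak frequency plus flat theta components, and per-pool-pair shared
#' band-limited sources whose gains are solved from the coherence targets
#' (`g^2 = sqrt(c * P_i * P_j)`), so pool band powers and pairwise
#' coherences approach the planted targets as epochs accumulate.
#'
#' @param truth A `subject_truth` from [cohort_truths()].
#' @param duration Recording length in seconds (>= one 5 s epoch).
#' @param fs Sampling rate in Hz.
#' @param montage Electrode positions (data.frame `label`, `x`, `y`, `z`)
#'   containing at least the 12 pooled channels.
#' @param seed RNG seed.
#' @param span `"task"` or `"baseline"`; selects which target table of the
#'   subject truth is realized.
#' @return An `eeg_recording` at stage `"raw"` (units uV).
#' @export
synthesize_eeg <- function(truth, duration, fs = 1024, montage = NULL,
                           seed = 1L, span = c("task", "baseline")) {
  span <- match.arg(span)
  if (is.null(montage)) montage <- montage_1020()
  check_pools_in_montage(montage$label)
  if (duration < 5) {
    stop("duration shorter than one 5 s epoch", call. = FALSE)
  }
  n <- round(duration * fs)
  freqs <- freq_grid(n, fs)
  nf <- length(freqs)
  df <- fs / n
  nchan <- nrow(montage)
  pools <- pool_spec()
  pairs <- pool_couplings()
  n_pairs <- nrow(pairs)

  seeds <- derive_seeds(seed, nchan + 1L + 2L * length(pools) +
                          2L * n_pairs)
  si <- 0L
  next_seed <- function() {
    si <<- si + 1L
    seeds[si]
  }

  # accumulate component amplitude spectra (random phases, deterministic
  # amplitudes) per channel; one inverse FFT per channel at the end
  spec_acc <- matrix(0 + 0i, nchan, nf)
  component_spectrum <- function(psd, sd) {
    amp <- n * sqrt(psd * df / 2)
    amp[1] <- 0
    if (n %% 2 == 0) amp[nf] <- 0
    idx <- which(amp > 0)
    ph <- with_seed(sd, stats::runif(length(idx), 0, 2 * pi))
    list(idx = idx, x = amp[idx] * exp(1i * ph))
  }
  add_component <- function(psd, weights, sd) {
    cs <- component_spectrum(psd, sd)
    if (length(cs$idx)) {
      spec_acc[, cs$idx] <<- spec_acc[, cs$idx] + weights %o% cs$x
    }
  }

  # channel-specific 1/f + white-floor background
  noise_psd <- psd_one_over_f(freqs, truth$channel_noise_power)
  for (c in seq_len(nchan)) {
    w <- numeric(nchan)
    w[c] <- 1
    add_component(noise_psd, w, next_seed())
  }

  # near-uniform slow global field (suppressed by the surface Laplacian)
  add_component(psd_flat(freqs, c(0.3, 0.9), truth$global_power),
                1 + 0.01 * montage$y, next_seed())

  powt <- truth$band_power[truth$band_power$span == span, ]
  coht <- truth$coherence[truth$coherence$span == span, ]
  target <- function(pool, band) {
    powt$power[powt$pool == pool & powt$band == band]
  }

  # shared-source gains from the coherence targets
  gains <- numeric(n_pairs)
  names(gains) <- paste(pairs[, 1], pairs[, 2], sep = "-")
  band_of <- function(pool, band) {
    bl <- band_limits(truth$apf[[pool]])
    bl[[band]]
  }
  pair_sources <- list()
  for (b in c("alpha", "theta")) {
    for (q in seq_len(n_pairs)) {
      pa <- pairs[q, 1]; pb <- pairs[q, 2]
      cq <- coht$coherence[coht$pair == names(gains)[q] & coht$band == b]
      lo <- pmax(band_of(pa, b)[1], band_of(pb, b)[1])
      hi <- pmin(band_of(pa, b)[2], band_of(pb, b)[2])
      g2 <- sqrt(cq * target(pa, b) * target(pb, b))
      pair_sources[[paste(b, q)]] <-
        list(pools = c(pa, pb), band = b, g2 = g2, lo = lo, hi = hi)
    }
  }
  used <- list()
  for (p in names(pools)) {
    for (b in c("alpha", "theta")) {
      used[[paste(p, b)]] <-
        sum(vapply(pair_sources,
                   function(s) if (p %in% s$pools && s$band == b) s$g2 else 0,
                   0))
    }
  }

  pool_w <- lapply(pools, function(chs) pool_weight_map(montage, chs))

  # per-pool oscillators fill the band-power budget left by noise and
  # shared sources
  for (p in names(pools)) {
    apf <- truth$apf[[p]]
    bl <- band_limits(apf)
    for (b in c("alpha", "theta")) {
      tgt <- target(p, b)
      resid <- tgt - psd_band_power(freqs, noise_psd, bl[[b]]) -
        used[[paste(p, b)]]
      resid <- max(resid, 0.02 * tgt)
      osc_psd <- if (b == "alpha") {
        # broad alpha hump plus a sharp dominant-frequency line: real
        # alpha spectra peak at an identifiable frequency, and the line
        # keeps the planted peak recoverable at grid resolution
        0.65 * psd_bump(freqs, apf, 0.6, bl$alpha, resid) +
          0.35 * psd_bump(freqs, apf, 0.06, bl$alpha, resid)
      } else {
        psd_flat(freqs, bl$theta, resid)
      }
      add_component(osc_psd, pool_w[[p]], next_seed())
    }
  }

  # shared pair sources: alpha sources are bump-shaped (centred between the
  # two pools' alpha peaks), theta sources flat, both confined to the
  # intersection of the two pools' individualized bands
  for (s in pair_sources) {
    if (s$g2 <= 0) { si <- si + 1L; next }
    ctr <- mean(c(truth$apf[[s$pools[1]]], truth$apf[[s$pools[2]]]))
    src_psd <- if (s$band == "alpha") {
      0.65 * psd_bump(freqs, ctr, 0.6, c(s$lo, s$hi), s$g2) +
        0.35 * psd_bump(freqs, ctr, 0.06, c(s$lo, s$hi), s$g2)
    } else {
      psd_flat(freqs, c(s$lo, s$hi), s$g2)
    }
    w <- pmax(pool_w[[s$pools[1]]], pool_w[[s$pools[2]]])
    add_component(src_psd, w, next_seed())
  }

  data <- matrix(0, nchan, n)
  tail_idx <- seq(nf - 1L + n %% 2L, 2L)
  for (c in seq_len(nchan)) {
    Xfull <- c(spec_acc[c, ], Conj(spec_acc[c, tail_idx]))
    data[c, ] <- Re(stats::fft(Xfull, inverse = TRUE)) / n
  }

  eeg_recording(data, fs = fs, positions = montage, stage = "raw")
}

#' Plant ocular and high-amplitude artifacts into a recording
#'
#' Blinks are stereotyped 300 ms raised-cosine transients with a frontally
#' dominant spatial pattern (fronto-polar weight 1, parietal floor 0.1).
#' Amplitude artifacts are brief focal bursts on one pooled channel, sized
#' through the montage's CSD operator so that the post-CSD amplitude
#' exceeds the 500 uV/m^2 rejection threshold in exactly the listed epochs.
#'
#' @param rec A raw `eeg_recording`.
#' @param blink_epochs,amplitude_epochs Integer epoch indices (5 s grid,
#'   1-based); must not overlap.
#' @param seed RNG seed (artifact timing, polarity, target channel).
#' @param epoch_length Epoch length in seconds defining the index grid.
#' @param blink_amplitude Peak blink amplitude (uV) at the fronto-polar
#'   sites.
#' @param csd_peak Post-CSD peak amplitude (uV/m^2) that amplitude
#'   artifacts are scaled to reach.
#' @return List with `recording` and `ledger` (data.frame `epoch`, `kind`).
#' @export
plant_artifacts <- function(rec, blink_epochs = integer(),
                            amplitude_epochs = integer(), seed = 1L,
                            epoch_length = 5, blink_amplitude = 600,
                            csd_peak = 1500) {
  blink_epochs <- as.integer(blink_epochs)
  amplitude_epochs <- as.integer(amplitude_epochs)
  if (length(intersect(blink_epochs, amplitude_epochs))) {
    stop("blink and amplitude epochs must not overlap", call. = FALSE)
  }
  n_ep <- floor(recording_duration(rec) / epoch_length)
  all_idx <- c(blink_epochs, amplitude_epochs)
  if (length(all_idx) && (anyDuplicated(all_idx) ||
                          any(all_idx < 1L) || any(all_idx > n_ep))) {
    stop(sprintf("artifact epoch indices must be distinct and within 1..%d",
                 n_ep), call. = FALSE)
  }
  fs <- rec$fs
  ep_samp <- round(epoch_length * fs)
  ledger <- data.frame(epoch = integer(), kind = character(),
                       stringsAsFactors = FALSE)
  if (!length(all_idx)) {
    return(list(recording = rec, ledger = ledger))
  }

  with_seed(seed, {
    if (length(blink_epochs)) {
      w <- blink_weight_map(rec$positions)
      template <- blink_template(fs, blink_amplitude)
      blink_len <- length(template)
      for (e in sort(blink_epochs)) {
        start <- (e - 1L) * ep_samp +
          sample.int(ep_samp - blink_len - round(0.5 * fs), 1L) +
          round(0.25 * fs)
        idx <- start:(start + blink_len - 1L)
        rec$data[, idx] <- rec$data[, idx] + w %o% template
      }
      ledger <- rbind(ledger,
                      data.frame(epoch = sort(blink_epochs), kind = "blink",
                                 stringsAsFactors = FALSE))
    }
    if (length(amplitude_epochs)) {
      M <- csd_matrix(rec$positions)
      pooled <- match(pool_channels(), rec$labels)
      burst_len <- round(0.15 * fs)
      burst <- 0.5 - 0.5 * cos(2 * pi * seq_len(burst_len) / (burst_len + 1))
      for (e in sort(amplitude_epochs)) {
        ch <- sample(pooled, 1L)
        amp <- csd_peak / max(abs(M[, ch])) * sample(c(-1, 1), 1L)
        start <- (e - 1L) * ep_samp +
          sample.int(ep_samp - burst_len - round(0.5 * fs), 1L) +
          round(0.25 * fs)
        idx <- start:(start + burst_len - 1L)
        rec$data[ch, idx] <- rec$data[ch, idx] + amp * burst
      }
      ledger <- rbind(ledger,
                      data.frame(epoch = sort(amplitude_epochs),
                                 kind = "amplitude",
                                 stringsAsFactors = FALSE))
    }
  })
  ledger <- ledger[order(ledger$epoch), , drop = FALSE]
  rownames(ledger) <- NULL
  list(recording = rec, ledger = ledger)
}
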