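# Spectral estimation, individualized bands, band power, coherence,
# baseline correction and APF metrics.

make_epochs <- function(data_fun, n_ep, fs, len_s, labels = c("F3", "P3")) {
  nsamp <- len_s * fs
  arr <- array(NA_real_, dim = c(n_ep, length(labels), nsamp))
  for (e in seq_len(n_ep)) {
    d <- data_fun(e)
    arr[e, , ] <- d
  }
  eeg_epochs(arr, fs, labels, len_s, stage = "csd")
}

test_that("integrated PSD of unit-variance white noise satisfies Parseval", {
  set.seed(31)
  eps <- make_epochs(function(e) matrix(rnorm(2 * 5 * 256), 2), 60, 256, 5)
  sp <- estimate_spectra(eps)
  w <- rep(1, length(sp$freqs))
  w[c(1, length(w))] <- 0.5
  for (ch in 1:2) {
    integral <- sum(sp$psd[ch, ] * w) * sp$df
    expect_lt(abs(integral - 1), 0.02)
  }
})

test_that("a pure sinusoid concentrates its A^2/2 power at its frequency", {
  fs <- 256
  t <- seq(0, 5 - 1 / fs, by = 1 / fs)
  A <- 3
  eps <- make_epochs(function(e) rbind(A * sin(2 * pi * 10 * t),
                                       rnorm(length(t), sd = 1e-4)),
                     10, fs, 5)
  sp <- estimate_spectra(eps)
  expect_equal(sp$freqs[which.max(sp$psd[1, ])], 10)
  total <- band_power(sp, "F3", c(8, 12))
  expect_lt(abs(total - A^2 / 2) / (A^2 / 2), 0.02)
})

test_that("degenerate spectral inputs are handled", {
  eps <- make_epochs(function(e) matrix(0, 2, 5 * 64), 4, 64, 5)
  sp <- estimate_spectra(eps)
  expect_true(all(sp$psd == 0))
  one <- make_epochs(function(e) matrix(rnorm(2 * 5 * 64), 2), 2, 64, 5)
  one$accepted <- c(TRUE, FALSE)
  expect_error(estimate_spectra(one), ">= 2 accepted")
  expect_error(pool_coherence(sp, "F3", "P3", c(8, 12)), "zero auto")
})

test_that("alpha peak detection follows the argmax with low-frequency ties", {
  # hand-built spectrum set: grid at 0.2 Hz
  freqs <- seq(0, 30, by = 0.2)
  mk <- function(psd) {
    structure(list(freqs = freqs, psd = matrix(psd, 1,
                                               dimnames = list("F3", NULL)),
                   channels = "F3", n_epochs_used = 10, df = 0.2),
              class = "spectrum_set")
  }
  two <- rep(1, length(freqs))
  two[freqs %in% c(9, 11)] <- 5
  res <- detect_apf(mk(two), "F3")
  expect_equal(res$apf, 9)
  expect_false(res$low_confidence)
  mono <- 1 / pmax(freqs, 0.5)
  res2 <- detect_apf(mk(mono), "F3")
  expect_equal(res2$apf, 8)
  expect_true(res2$low_confidence)
})

test_that("individualized band limits are anchored at the alpha peak", {
  expect_equal(band_limits(10), list(alpha = c(8, 12), theta = c(3, 7)))
  expect_equal(band_limits(8), list(alpha = c(6, 10), theta = c(1, 5)))
  expect_equal(band_limits(13), list(alpha = c(11, 15), theta = c(6, 10)))
  expect_error(band_limits(7.5), "8-13")
  expect_error(band_limits(13.2), "8-13")
})

test_that("band power integrates the PSD with trapezoid additivity", {
  set.seed(7)
  eps <- make_epochs(function(e) matrix(rnorm(2 * 5 * 256), 2), 40, 256, 5)
  sp <- estimate_spectra(eps)
  # white noise: flat PSD at 1/128 per Hz, 4 Hz band -> 4/128
  expect_lt(abs(band_power(sp, "F3", c(20, 24)) - 4 / 128) / (4 / 128),
            0.03)
  # additivity over adjacent bands
  total <- band_power(sp, "F3", c(6, 18))
  parts <- band_power(sp, "F3", c(6, 11)) + band_power(sp, "F3", c(11, 18))
  expect_lt(abs(total - parts), 1e-9)
  # quadratic in amplitude
  eps2 <- eps
  eps2$epochs <- eps$epochs * 2
  sp2 <- estimate_spectra(eps2)
  expect_lt(abs(band_power(sp2, "F3", c(6, 10)) /
                  band_power(sp, "F3", c(6, 10)) - 4), 1e-6)
  expect_error(band_power(sp, "F3", c(120, 140)), "grid")
})

test_that("coherence is bounded, symmetric and 1 against a copy", {
  set.seed(11)
  fs <- 128
  eps <- make_epochs(function(e) {
    x <- rnorm(5 * fs)
    rbind(x, x)                         # exact copy
  }, 10, fs, 5)
  sp <- estimate_spectra(eps)
  expect_lt(abs(pool_coherence(sp, "F3", "P3", c(4, 30)) - 1), 1e-10)
  eps2 <- make_epochs(function(e) matrix(rnorm(2 * 5 * fs), 2), 200, fs, 5)
  sp2 <- estimate_spectra(eps2)
  msc <- pool_coherence(sp2, "F3", "P3", c(8, 12))
  expect_lte(msc, 0.05)
  expect_gte(msc, 0)
  expect_equal(msc, pool_coherence(sp2, "P3", "F3", c(8, 12)))
  expect_error(pool_coherence(sp2, "F3", "F3", c(8, 12)), "disjoint")
  sp1 <- sp2
  sp1$n_epochs_used <- 1L
  expect_error(pool_coherence(sp1, "F3", "P3", c(8, 12)), "single epoch")
})

test_that("baseline correction subtracts or forms the dB log ratio", {
  expect_equal(as.numeric(baseline_correct(5, 3)), 2)
  expect_equal(as.numeric(baseline_correct(4, 4)), 0)
  lr <- baseline_correct(8, 4, mode = "log_ratio")
  expect_equal(as.numeric(lr), 10 * log10(2), tolerance = 1e-10)
  expect_identical(attr(lr, "correction"), "log_ratio")
  expect_error(baseline_correct(-1, 4, mode = "log_ratio"), "positive")
})

test_that("APF asymmetry is the signed left-right difference", {
  expect_equal(apf_asymmetry(10.2, 10.2), 0)
  expect_equal(apf_asymmetry(9.8, 10.4), -0.6)
  l <- list(apf = 9, low_confidence = TRUE)
  r <- list(apf = 10, low_confidence = FALSE)
  out <- apf_asymmetry(l, r)
  expect_equal(as.numeric(out), -1)
  expect_true(attr(out, "low_confidence"))
})

test_that("planted lateralized alpha peaks are recovered through the pipeline", {
  cfg <- test_cohort_config(n = 3, seed = 29, fs = 256)
  truth <- cohort_truths(cfg)[[1]]
  truth$apf <- c(FL = 9.0, FR = 10.0, PL = 9.0, PR = 10.0)
  # isolate the oscillator peaks: shared inter-regional sources sit at the
  # mean of the two coupled pools' peaks and would blur a 1 Hz split
  truth$coherence$coherence <- 0
  rec <- synthesize_eeg(truth, 100, cfg$fs, cfg$montage, seed = 3)
  eps <- preprocess_recording(rec,
                              preprocess_params(ocular_correction = FALSE))
  sp <- estimate_spectra(eps, pool_channels())
  fl <- detect_apf(sp, pool_spec()$FL)
  fr <- detect_apf(sp, pool_spec()$FR)
  asym <- apf_asymmetry(fl, fr)
  expect_lte(abs(as.numeric(asym) - (-1)), 0.41)
})
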