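# Filtering, ocular correction, current source density, epoching and
# artifact rejection.

test_that("band-pass filter attenuates drift and passes the alpha range", {
  fs <- 1024
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  slow <- sin(2 * pi * 0.05 * t)
  alpha <- sin(2 * pi * 10 * t)
  rec <- signal_recording(slow + alpha, fs)
  out <- bandpass_filter(rec)
  expect_identical(out$stage, "filtered")
  # project onto the two sinusoids to measure their residual amplitudes
  amp <- function(y, f) 2 * abs(mean(y * exp(-2i * pi * f * t)))
  expect_lt(amp(out$data[1, ], 0.05), 10^(-40 / 20))     # >= 40 dB down
  expect_lt(abs(amp(out$data[1, ], 10) - 1), 0.01)       # within 1%
})

test_that("band-pass filter is zero phase and linear", {
  fs <- 512
  imp <- numeric(fs * 4)
  imp[fs] <- 1
  out <- bandpass_filter(signal_recording(imp, fs))
  expect_equal(which.max(out$data[1, ]), fs)             # no group delay
  x1 <- rnorm(fs * 4)
  x2 <- rnorm(fs * 4)
  f <- function(x) bandpass_filter(signal_recording(x, fs))$data[1, ]
  expect_lt(max(abs(f(x1 + x2) - f(x1) - f(x2))) / max(abs(f(x1))), 1e-8)
  expect_error(bandpass_filter(signal_recording(rnorm(1000), 128)),
               "256")
})

test_that("notch filter suppresses mains and spares the neighbourhood", {
  fs <- 1024
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  amp <- function(y, f) 2 * abs(mean(y * exp(-2i * pi * f * t)))
  rec <- signal_recording(sin(2 * pi * 50 * t), fs)
  out <- notch_filter(rec)
  expect_lt(amp(out$data[1, ], 50), 0.03)
  for (f0 in c(10, 45, 55)) {
    rec2 <- signal_recording(sin(2 * pi * f0 * t), fs)
    res <- notch_filter(rec2)
    tol <- if (f0 == 10) 0.01 else 0.05
    expect_lt(abs(amp(res$data[1, ], f0) - 1), tol)
  }
  dc <- notch_filter(signal_recording(rep(2, fs), fs))
  expect_equal(max(abs(dc$data[1, ] - 2)), 0, tolerance = 1e-9)
  expect_error(notch_filter(signal_recording(rnorm(fs), fs), mains = 600),
               "Nyquist")
})

test_that("surface Laplacian annihilates uniform fields and is linear", {
  mon <- montage_1020()
  n <- 256
  rec <- function(d) eeg_recording(d, 256, mon, stage = "ocular_corrected")
  u <- apply_csd(rec(matrix(5, nrow(mon), n)))
  expect_lt(max(abs(u$data)), 1e-6)
  expect_identical(u$stage, "csd")
  d <- matrix(rnorm(nrow(mon) * n), nrow(mon))
  one <- apply_csd(rec(d))$data
  two <- apply_csd(rec(2 * d))$data
  expect_lt(max(abs(two - 2 * one)) / max(abs(one)), 1e-10)
})

test_that("a focal source maps to a peak with an inverted surround", {
  mon <- montage_1020()
  M <- csd_matrix(mon)
  src <- match("Cz", mon$label)
  out <- M[, src]                      # CSD of a unit source at Cz
  expect_identical(which.max(out), src)
  # nearest neighbours lie in the sign-inverted ring
  d2 <- (mon$x - mon$x[src])^2 + (mon$y - mon$y[src])^2 +
    (mon$z - mon$z[src])^2
  ring <- order(d2)[2:5]
  expect_true(all(out[ring] < 0))
})

test_that("segmentation floors to whole epochs and validates spans", {
  mon <- tiny_montage()
  rec <- eeg_recording(matrix(rnorm(3 * 30 * 1024), 3), 1024, mon)
  eps <- segment_epochs(rec, 5)
  expect_identical(dim(eps$epochs), c(6L, 3L, 5120L))
  rec12 <- eeg_recording(matrix(rnorm(3 * 12 * 64), 3), 64, mon)
  expect_identical(n_epochs(segment_epochs(rec12, 5)), 2L)
  rec4 <- eeg_recording(matrix(rnorm(3 * 4 * 64), 3), 64, mon)
  expect_error(segment_epochs(rec4, 5), "shorter")
  expect_error(segment_epochs(rec12, 5, span = c(0, 99)), "span")
  sp <- segment_epochs(rec12, 5, span = c(1, 11.5))
  expect_identical(n_epochs(sp), 2L)
})

test_that("epoch rejection applies amplitude and peak-to-peak rules", {
  mon <- tiny_montage()
  arr <- array(0, dim = c(3, 3, 64 * 5))
  arr[2, 1, 100] <- 600                      # single-sample excursion
  arr[3, 2, ] <- rep(c(-450, 420), 160)      # range 870 within +-500
  eps <- eeg_epochs(arr, 64, mon$label, 5, stage = "csd")
  out <- reject_epochs(eps)
  expect_identical(out$rejection_reason, c("none", "amplitude",
                                           "peak_to_peak"))
  expect_identical(out$accepted, c(TRUE, FALSE, FALSE))
  # monotone in the thresholds: raising them never rejects more
  harsher <- reject_epochs(eps, amp_thresh = 300, ptp_thresh = 500)
  expect_true(all(out$accepted >= harsher$accepted))
  lax <- reject_epochs(eps, amp_thresh = 1000, ptp_thresh = 1000)
  expect_true(all(lax$accepted >= out$accepted))
})

test_that("stage ordering of the preprocessing chain is enforced", {
  rec <- signal_recording(rnorm(2048), 512)
  expect_error(apply_csd(rec), "stage")
  expect_error(remove_ocular(rec), "stage")
  filt <- bandpass_filter(rec)
  expect_error(bandpass_filter(filt), "stage")
  expect_error(remove_ocular(filt), "8 channels")
})

test_that("ocular correction removes planted blinks and nothing else", {
  cfg <- test_cohort_config(n = 3, seed = 17, fs = 256)
  truth <- cohort_truths(cfg)[[1]]
  rec <- synthesize_eeg(truth, 60, cfg$fs, cfg$montage, seed = 4)
  planted <- plant_artifacts(rec, blink_epochs = c(2, 7), seed = 6)
  dirty <- notch_filter(bandpass_filter(planted$recording))
  clean <- notch_filter(bandpass_filter(rec))
  oc <- remove_ocular(dirty, seed = 2)
  expect_true(any(oc$report$flagged))
  fp <- match(c("Fp1", "Fp2"), rec$labels)
  for (e in c(2, 7)) {
    idx <- ((e - 1) * 5 * cfg$fs + 1):(e * 5 * cfg$fs)
    red <- 1 - mean(oc$recording$data[fp, idx]^2) /
      mean(dirty$data[fp, idx]^2)
    expect_gte(red, 0.9)
  }
  # blink-free input passes through untouched
  oc0 <- remove_ocular(clean, seed = 2)
  expect_false(any(oc0$report$flagged))
  expect_equal(oc0$recording$data, clean$data)
})

test_that("clean synthetic recordings lose no epochs in the full chain", {
  cfg <- test_cohort_config(n = 3, seed = 23, fs = 256)
  truth <- cohort_truths(cfg)[[1]]
  rec <- synthesize_eeg(truth, 60, cfg$fs, cfg$montage,
                        seed = truth$seeds$eeg_task)
  eps <- preprocess_recording(rec, preprocess_params(ocular_correction = FALSE))
  expect_true(all(eps$accepted))
  expect_identical(eps$stage, "csd")
})
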