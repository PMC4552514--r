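# Synthetic cohort generator: determinism, planted age/skill structure,
# coherence realizability, spectral peaks, artifact planting.

test_that("generators are pure functions of config and seed", {
  cfg <- test_cohort_config(n = 4, seed = 11)
  t1 <- cohort_truths(cfg)
  t2 <- cohort_truths(cfg)
  expect_identical(t1, t2)
  r1 <- synthesize_eeg(t1[[1]], 20, cfg$fs, cfg$montage, seed = 3)
  r2 <- synthesize_eeg(t1[[1]], 20, cfg$fs, cfg$montage, seed = 3)
  expect_identical(r1$data, r2$data)
})

test_that("sample age-skill correlation hits the configured target", {
  cfg <- cohort_config(n_subjects = 60, seed = 7)
  tr <- cohort_truths(cfg)
  r <- age_skill_correlation(tr)
  expect_gte(r, -0.72)
  expect_lte(r, -0.52)
  # the orthogonalized construction is exact
  expect_equal(r, -0.62, tolerance = 1e-10)
})

test_that("zero age variance leaves the correlation undefined", {
  ag <- data.frame(group = "only", lo = 30, hi = 30, prop = 1)
  cfg <- cohort_config(n_subjects = 3, seed = 1, age_groups = ag)
  expect_true(is.na(age_skill_correlation(cohort_truths(cfg))))
})

test_that("invalid configurations are refused", {
  expect_error(cohort_config(n_subjects = 2), "n_subjects")
  expect_error(cohort_config(skill_age_correlation = 0.3),
               "skill_age_correlation")
  expect_error(cohort_config(task_duration = -10), "task_duration")
  ag <- data.frame(group = "g", lo = 40, hi = 20, prop = 1)
  expect_error(cohort_config(age_groups = ag), "age_groups")
})

test_that("independent pools show vanishing coherence", {
  cp <- coherent_pair(0, duration = 1000, fs = 128, band = c(8, 12),
                      seed = 2)
  rec <- eeg_recording(cp$data, 128, montage_1020(c("F3", "P3")),
                      stage = "csd")
  sp <- estimate_spectra(segment_epochs(rec, 5), c("F3", "P3"))
  expect_lte(pool_coherence(sp, "F3", "P3", c(8, 12)), 0.05)
})

test_that("shared-source pair realizes the closed-form coherence", {
  cp <- coherent_pair(1, duration = 1000, fs = 128, band = c(8, 12),
                      seed = 8)
  rec <- eeg_recording(cp$data, 128, montage_1020(c("F3", "P3")),
                      stage = "csd")
  sp <- estimate_spectra(segment_epochs(rec, 5), c("F3", "P3"))
  msc <- pool_coherence(sp, "F3", "P3", c(8, 12))
  expect_lt(abs(msc - 0.25), 0.03)
})

test_that("planted alpha oscillator peaks at the configured frequency", {
  cfg <- test_cohort_config(n = 3, seed = 21)
  tr <- cohort_truths(cfg)
  truth <- tr[[1]]
  truth$apf[] <- 9.4
  rec <- synthesize_eeg(truth, 60, cfg$fs, cfg$montage, seed = 13)
  # periodogram argmax oracle, independent of the spectral module
  fl <- match(pool_spec()$FL, rec$labels)
  x <- colMeans(rec$data[fl, , drop = FALSE])
  pg <- Mod(stats::fft(x))^2
  freqs <- seq(0, length(x) - 1) / (length(x) / cfg$fs)
  win <- freqs >= 8 & freqs <= 13
  peak <- freqs[win][which.max(pg[win])]
  expect_lt(abs(peak - 9.4), 0.2)
})

test_that("band-power targets are realized within ten percent", {
  cfg <- cohort_config(n_subjects = 3, seed = 9, fs = 256,
                       task_duration = 300)
  truth <- cohort_truths(cfg)[[1]]
  rec <- synthesize_eeg(truth, 300, cfg$fs, cfg$montage,
                        seed = truth$seeds$eeg_task, span = "task")
  sp <- estimate_spectra(segment_epochs(rec, 5), pool_channels())
  pools <- pool_spec()
  for (b in c("alpha", "theta")) {
    ratio <- vapply(names(pools), function(p) {
      bl <- band_limits(truth$apf[[p]])
      tgt <- truth$band_power$power[truth$band_power$pool == p &
                                      truth$band_power$band == b &
                                      truth$band_power$span == "task"]
      band_power(sp, pools[[p]], bl[[b]]) / tgt
    }, 0)
    expect_lt(abs(mean(ratio) - 1), 0.1)
  }
})

test_that("artifact planting validates indices and is the identity when empty", {
  cfg <- test_cohort_config(n = 3, seed = 31)
  truth <- cohort_truths(cfg)[[1]]
  rec <- synthesize_eeg(truth, 30, cfg$fs, cfg$montage, seed = 2)
  out <- plant_artifacts(rec)
  expect_identical(out$recording$data, rec$data)
  expect_identical(nrow(out$ledger), 0L)
  expect_error(plant_artifacts(rec, blink_epochs = 2, amplitude_epochs = 2),
               "overlap")
  expect_error(plant_artifacts(rec, blink_epochs = 99), "within")
  expect_error(plant_artifacts(rec, amplitude_epochs = 0), "within")
})

test_that("planted blinks raise frontal low-band variance, sparing parietal", {
  cfg <- test_cohort_config(n = 3, seed = 31, fs = 512)
  truth <- cohort_truths(cfg)[[1]]
  rec <- synthesize_eeg(truth, 30, cfg$fs, cfg$montage, seed = 2)
  out <- plant_artifacts(rec, blink_epochs = 3, seed = 5)
  idx <- (2 * 5 * cfg$fs + 1):(3 * 5 * cfg$fs)
  fp <- match(c("Fp1", "Fp2"), rec$labels)
  pl <- match(pool_spec()$PL, rec$labels)
  v_f <- mean(out$recording$data[fp, idx]^2) / mean(rec$data[fp, idx]^2)
  v_p <- mean(out$recording$data[pl, idx]^2) / mean(rec$data[pl, idx]^2)
  expect_gt(v_f, 2)
  expect_lt(abs(v_p - 1), 0.05)
  expect_identical(out$ledger$kind, "blink")
})

test_that("trial logs survive a CSV round trip", {
  log <- simulate_wcst_agent(0.8, 0.1, 0.05, seed = 3)
  path <- tempfile(fileext = ".csv")
  write_trial_log(log, path)
  back <- read_trial_log(path)
  expect_equal(back, log)
  expect_identical(score_trial_log(back), score_trial_log(log))
})
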