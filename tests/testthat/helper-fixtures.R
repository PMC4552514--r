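# Shared fixtures: tiny recordings and scripted WCST logs built in code.

tiny_montage <- function(labels = c("Fp1", "Fp2", "Cz")) montage_1020(labels)

# single-channel recording from a bare signal vector
signal_recording <- function(x, fs, label = "Cz", stage = "raw") {
  eeg_recording(matrix(x, nrow = 1), fs = fs,
                positions = montage_1020(label), stage = stage)
}

# scripted trial log: 10 correct under color, shift to shape, 3
# perseverative choices (matching color), 10 correct, shift, 2 correct
scripted_log_25 <- function() {
  rows <- list()
  add <- function(rule, choice_matches, feedback) {
    rows[[length(rows) + 1L]] <<- data.frame(
      trial = length(rows) + 1L, rule = rule, choice = 1L,
      matched_categories = choice_matches, feedback = feedback,
      stringsAsFactors = FALSE)
  }
  for (i in 1:10) add("color", "color", "correct")
  for (i in 1:3) add("shape", "color", "incorrect")   # perseverative
  for (i in 1:10) add("shape", "shape", "correct")
  for (i in 1:2) add("number", "number", "correct")
  do.call(rbind, rows)
}

# small clean cohort configuration used across tests (short recordings,
# reduced sampling rate keeps the suite fast; spectral resolution and all
# band definitions are unchanged)
test_cohort_config <- function(n = 6, seed = 5, fs = 256,
                               task_duration = 60, n_blink = 0,
                               n_amplitude = 0) {
  cohort_config(n_subjects = n, seed = seed, fs = fs,
                task_duration = task_duration, baseline_duration = 30,
                n_blink = n_blink, n_amplitude = n_amplitude)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
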