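# Synthetic cohort generation: age structure, latent skill, spectral
# ground truth and WCST behaviour with a known answer key.

default_age_groups <- function() {
  data.frame(group = c("young", "mid", "elder"),
             lo = c(20, 51, 67), hi = c(34, 64, 82),
             prop = c(19, 28, 15) / 62,
             stringsAsFactors = FALSE)
}

default_effects <- function() {
  list(
    # band power (uV^2, raw scale chosen so post-CSD amplitudes sit well
    # below the 500/800 uV/m^2 rejection thresholds); age slopes are per
    # year on the log scale
    alpha_power_base = 0.0025, alpha_power_age_slope = 0.012,
    theta_power_base = 0.0018, theta_power_age_slope = 0.010,
    power_jitter_sd = 0.15,
    baseline_alpha_factor = 1.35, baseline_theta_factor = 0.72,
    # alpha peak frequency (Hz)
    apf_left_base = 10.6, apf_left_age_slope = 0.022, apf_left_sd = 0.25,
    apf_right_base = 10.5, apf_right_age_slope = 0.006,
    apf_right_skill_slope = 0.10, apf_right_sd = 0.20,
    # coherence targets (msc)
    coh_base = c(`FL-FR` = 0.060, `FL-PL` = 0.050, `FL-PR` = 0.070,
                 `FR-PL` = 0.050, `FR-PR` = 0.055, `PL-PR` = 0.050),
    coh_age_slope = c(`FL-FR` = 8e-4, `FL-PL` = 0, `FL-PR` = 0,
                      `FR-PL` = 7e-4, `FR-PR` = 8e-4, `PL-PR` = 0),
    coh_skill_slope = c(`FL-FR` = 0, `FL-PL` = 0, `FL-PR` = 0.030,
                        `FR-PL` = 0, `FR-PR` = 0, `PL-PR` = 0.015),
    coh_baseline = c(alpha = 0.085, theta = 0.070),
    coh_range = c(0.015, 0.16),
    # amplitude scales (uV^2)
    channel_noise_power = 0.0009, global_power = 324,
    # WCST agent links (latent skill -> agent parameters)
    wcst_know = c(2.2, 1.8), wcst_persev = c(-2.6, -1.2),
    wcst_distract = c(-3.2, -0.8)
  )
}

#' Configuration for a synthetic cohort
#'
#' Bundles and validates all knobs of the synthetic study: cohort size and
#' age-group structure, the target age-skill correlation, recording
#' durations, planted effect sizes and artifact counts.
#'
#' @param n_subjects Number of subjects (>= 3).
#' @param seed Master seed; every random quantity in the cohort derives
#'   from it.
#' @param age_groups data.frame with `group`, `lo`, `hi`, `prop` rows.
#' @param skill_age_correlation Target Pearson correlation between age and
#'   latent skill, in (-1, 0].
#' @param fs Sampling rate in Hz.
#' @param task_duration,baseline_duration Recording lengths in seconds.
#' @param epoch_length Epoch length in seconds.
#' @param montage Electrode positions (default [montage_1020()]).
#' @param n_blink,n_amplitude Artifacts planted per subject in the task
#'   recording.
#' @param effects Effect-size list; see `eegwcst:::default_effects()` for
#'   the fields and defaults.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 60L, seed = 1L,
                          age_groups = default_age_groups(),
                          skill_age_correlation = -0.62,
                          fs = 1024, task_duration = 300,
                          baseline_duration = 30, epoch_length = 5,
                          montage = montage_1020(),
                          n_blink = 2L, n_amplitude = 1L,
                          effects = default_effects()) {
  stopifnot_scalar(n_subjects, "n_subjects", min = 3)
  stopifnot_scalar(skill_age_correlation, "skill_age_correlation",
                   min = -1 + 1e-9, max = 0)
  stopifnot_scalar(task_duration, "task_duration", min = epoch_length)
  stopifnot_scalar(baseline_duration, "baseline_duration",
                   min = epoch_length)
  if (!is.data.frame(age_groups) ||
      !all(c("group", "lo", "hi", "prop") %in% names(age_groups)) ||
      any(age_groups$lo > age_groups$hi) || any(age_groups$prop < 0)) {
    stop("invalid `age_groups` specification", call. = FALSE)
  }
  check_pools_in_montage(montage$label)
  structure(list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
                 age_groups = age_groups,
                 skill_age_correlation = skill_age_correlation,
                 fs = fs, task_duration = task_duration,
                 baseline_duration = baseline_duration,
                 epoch_length = epoch_length, montage = montage,
                 n_blink = as.integer(n_blink),
                 n_amplitude = as.integer(n_amplitude),
                 effects = effects),
            class = "cohort_config")
}

allocate_groups <- function(n, groups) {
  # largest-remainder allocation keeps the group composition deterministic
  raw <- n * groups$prop / sum(groups$prop)
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1L
  }
  rep(groups$group, base)
}

#' Ground-truth parameters for every subject of a synthetic cohort
#'
#' Draws ages by group, constructs a latent skill whose sample correlation
#' with age equals the configured target exactly (by orthogonalizing the
#' noise against standardized age), and derives each subject's spectral
#' targets: band powers declining with age, alpha peak frequencies
#' (left-hemisphere decline with age; right hemisphere weakly age- and
#' skill-dependent so that left-right asymmetry tracks performance),
#' coherence targets with age-declining frontal/right couplings and a
#' skill-dependent FL-PR coupling, and WCST agent parameters via logistic
#' links on skill.
#'
#' @param config A [cohort_config()].
#' @return List of `subject_truth` objects.
#' @export
cohort_truths <- function(config) {
  n <- config$n_subjects
  ef <- config$effects
  seeds <- derive_seeds(config$seed, 6L)
  grp <- allocate_groups(n, config$age_groups)
  ages <- with_seed(seeds[1], {
    g <- config$age_groups
    vapply(grp, function(gg) {
      r <- g[g$group == gg, ]
      stats::runif(1, r$lo, r$hi)
    }, 0)
  })

  skill <- with_seed(seeds[2], {
    e <- stats::rnorm(n)
    r <- config$skill_age_correlation
    if (stats::sd(ages) == 0) {
      # degenerate cohort: correlation undefined, skill is pure noise
      as.numeric(scale(e))
    } else {
      za <- as.numeric(scale(ages))
      e_perp <- stats::residuals(stats::lm(e ~ za))
      as.numeric(r * za + sqrt(1 - r^2) * scale(e_perp))
    }
  })

  apf_noise <- with_seed(seeds[3], matrix(stats::rnorm(2 * n), n))
  pow_jit <- with_seed(seeds[4], matrix(stats::rnorm(8 * n), n))
  subj_seeds <- matrix(derive_seeds(seeds[5], 4L * n), n)
  art_draw <- with_seed(seeds[6], stats::runif(n))  # reserved artifact slots

  pairs <- pool_couplings()
  pair_ids <- paste(pairs[, 1], pairs[, 2], sep = "-")
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    age <- ages[i]
    sk <- skill[i]
    apf_l <- min(max(ef$apf_left_base - ef$apf_left_age_slope * (age - 50) +
                       ef$apf_left_sd * apf_noise[i, 1], 8.4), 12.5)
    apf_r <- min(max(ef$apf_right_base - ef$apf_right_age_slope * (age - 50) -
                       ef$apf_right_skill_slope * sk +
                       ef$apf_right_sd * apf_noise[i, 2], 8.4), 12.5)
    apf <- c(FL = apf_l, FR = apf_r, PL = apf_l, PR = apf_r)

    pool_names <- names(pool_spec())
    bp <- expand.grid(pool = pool_names, band = c("alpha", "theta"),
                      span = c("task", "baseline"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    jit <- function(p, b) {
      exp(ef$power_jitter_sd *
            pow_jit[i, match(p, pool_names) + 4 * (b == "theta")])
    }
    bp$power <- mapply(function(p, b, s) {
      base <- if (b == "alpha") {
        ef$alpha_power_base * exp(-ef$alpha_power_age_slope * (age - 50))
      } else {
        ef$theta_power_base * exp(-ef$theta_power_age_slope * (age - 50))
      }
      span_f <- if (s == "baseline") {
        if (b == "alpha") ef$baseline_alpha_factor else ef$baseline_theta_factor
      } else 1
      base * span_f * jit(p, b)
    }, bp$pool, bp$band, bp$span)

    co <- expand.grid(pair = pair_ids, band = c("alpha", "theta"),
                      span = c("task", "baseline"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    co$coherence <- mapply(function(pr, b, s) {
      if (s == "baseline") return(ef$coh_baseline[[b]])
      v <- ef$coh_base[[pr]] - ef$coh_age_slope[[pr]] * (age - 50) +
        ef$coh_skill_slope[[pr]] * sk
      min(max(v, ef$coh_range[1]), ef$coh_range[2])
    }, co$pair, co$band, co$span)

    truths[[i]] <- structure(list(
      subject_id = sprintf("S%03d", i),
      age = age, age_group = grp[i], latent_skill = sk,
      apf = apf, apf_left = apf_l, apf_right = apf_r,
      band_power = bp, coherence = co,
      channel_noise_power = ef$channel_noise_power,
      global_power = ef$global_power,
      wcst = list(
        skill = stats::plogis(ef$wcst_know[1] + ef$wcst_know[2] * sk),
        perseveration_rate = stats::plogis(ef$wcst_persev[1] +
                                             ef$wcst_persev[2] * sk),
        distraction_rate = stats::plogis(ef$wcst_distract[1] +
                                           ef$wcst_distract[2] * sk)),
      seeds = list(eeg_task = subj_seeds[i, 1],
                   eeg_baseline = subj_seeds[i, 2],
                   wcst = subj_seeds[i, 3],
                   artifacts = subj_seeds[i, 4]),
      artifact_ledger = NULL), class = "subject_truth")
  }
  truths
}

#' @export
print.subject_truth <- function(x, ...) {
  cat(sprintf("<subject_truth> %s: age %.1f (%s), skill %+.2f, APF L/R %.2f/%.2f Hz\n",
              x$subject_id, x$age, x$age_group, x$latent_skill,
              x$apf_left, x$apf_right))
  invisible(x)
}

#' Synthesize the recordings and trial log for one subject
#'
#' @param truth A `subject_truth`.
#' @param config The [cohort_config()] it came from.
#' @param artifacts Plant the configured artifacts into the task recording?
#' @return List with `truth` (ledger filled in), `task`, `baseline`
#'   (`eeg_recording`s) and `trial_log`.
#' @export
subject_recordings <- function(truth, config, artifacts = TRUE) {
  task <- synthesize_eeg(truth, config$task_duration, config$fs,
                         config$montage, truth$seeds$eeg_task, "task")
  baseline <- synthesize_eeg(truth, config$baseline_duration, config$fs,
                             config$montage, truth$seeds$eeg_baseline,
                             "baseline")
  ledger <- data.frame(epoch = integer(), kind = character(),
                       stringsAsFactors = FALSE)
  if (artifacts && (config$n_blink > 0L || config$n_amplitude > 0L)) {
    n_ep <- floor(config$task_duration / config$epoch_length)
    n_art <- config$n_blink + config$n_amplitude
    if (n_art > n_ep) stop("more artifacts than epochs", call. = FALSE)
    slots <- with_seed(truth$seeds$artifacts, sample.int(n_ep, n_art))
    planted <- plant_artifacts(
      task,
      blink_epochs = slots[seq_len(config$n_blink)],
      amplitude_epochs = slots[config$n_blink + seq_len(config$n_amplitude)],
      seed = truth$seeds$artifacts,
      epoch_length = config$epoch_length)
    task <- planted$recording
    ledger <- planted$ledger
  }
  truth$artifact_ledger <- ledger
  log <- simulate_wcst_agent(truth$wcst$skill,
                             truth$wcst$perseveration_rate,
                             truth$wcst$distraction_rate,
                             seed = truth$seeds$wcst)
  list(truth = truth, task = task, baseline = baseline, trial_log = log)
}

#' Generate a full synthetic cohort
#'
#' Materializes every subject of the configured cohort: ground truth,
#' task and baseline recordings (with planted artifacts) and a WCST trial
#' log. Deterministic for a given config and seed. For large cohorts at
#' long durations consider [cohort_truths()] plus [subject_recordings()]
#' subject by subject, which [run_pipeline()] does internally to bound
#' memory.
#'
#' @param config A [cohort_config()].
#' @param artifacts Plant artifacts into the task recordings?
#' @return List of per-subject bundles (see [subject_recordings()]).
#' @export
generate_cohort <- function(config, artifacts = TRUE) {
  truths <- cohort_truths(config)
  lapply(truths, subject_recordings, config = config, artifacts = artifacts)
}

#' Sample Pearson correlation between age and latent skill
#'
#' @param truths List of `subject_truth` objects.
#' @return Pearson r, or `NA` when age has zero variance.
#' @export
age_skill_correlation <- function(truths) {
  ages <- vapply(truths, `[[`, 0, "age")
  skill <- vapply(truths, `[[`, 0, "latent_skill")
  if (stats::sd(ages) == 0 || stats::sd(skill) == 0) return(NA_real_)
  stats::cor(ages, skill)
}
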