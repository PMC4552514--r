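# Per-subject feature extraction: preprocessing chain -> spectra ->
# individualized band powers, pool coherences, APF metrics.

#' Preprocessing parameters
#'
#' @param highpass,lowpass,mains Filter settings in Hz.
#' @param ocular_correction Run ICA ocular correction? Disable for
#'   recordings known to be blink-free (the corrector is then a near
#'   no-op).
#' @param ica_threshold Ocular component correlation threshold.
#' @param epoch_length Epoch length in seconds.
#' @param amp_thresh,ptp_thresh Rejection thresholds in uV/m^2.
#' @param correction Baseline correction mode (`"subtract"` or
#'   `"log_ratio"`).
#' @return A list of validated parameters.
#' @export
preprocess_params <- function(highpass = 0.3, lowpass = 100, mains = 50,
                              ocular_correction = TRUE, ica_threshold = 0.7,
                              epoch_length = 5, amp_thresh = 500,
                              ptp_thresh = 800,
                              correction = c("subtract", "log_ratio")) {
  list(highpass = highpass, lowpass = lowpass, mains = mains,
       ocular_correction = ocular_correction, ica_threshold = ica_threshold,
       epoch_length = epoch_length, amp_thresh = amp_thresh,
       ptp_thresh = ptp_thresh, correction = match.arg(correction))
}

#' Run the fixed preprocessing chain on one recording
#'
#' Band-pass (0.3-100 Hz) and mains notch filtering, ICA ocular correction,
#' current source density referencing, 5 s epoching and amplitude /
#' peak-to-peak rejection over the pooled analysis channels, in that fixed
#' order.
#'
#' @param rec A raw `eeg_recording`.
#' @param params See [preprocess_params()].
#' @param seed Seed for the ICA step.
#' @return An `eeg_epochs` object at stage `"csd"` with rejection applied.
#' @export
preprocess_recording <- function(rec, params = preprocess_params(),
                                 seed = 1L) {
  rec <- bandpass_filter(rec, params$highpass, params$lowpass)
  rec <- notch_filter(rec, params$mains)
  rec <- if (isTRUE(params$ocular_correction)) {
    remove_ocular(rec, seed = seed,
                  threshold = params$ica_threshold)$recording
  } else {
    set_stage(rec, "ocular_corrected")
  }
  rec <- apply_csd(rec)
  eps <- segment_epochs(rec, params$epoch_length)
  reject_epochs(eps, params$amp_thresh, params$ptp_thresh,
                channels = pool_channels())
}

#' Spectral features of one subject
#'
#' Preprocesses the task and baseline recordings, estimates epoch-averaged
#' spectra over the 12 pooled channels, detects each pool's alpha peak
#' frequency on the task spectra (the same individualized bands are reused
#' for the baseline span), and assembles band powers (absolute and
#' baseline-corrected), pool-pair coherences and APF/asymmetry metrics.
#'
#' @param task,baseline Raw `eeg_recording`s.
#' @param params See [preprocess_params()].
#' @param seed Seed for the ICA steps.
#' @return List with `features` (one-row data.frame), `bands` (per-pool
#'   band scheme), `epochs` (accepted/total counts) and `rejection`
#'   (per-span reports).
#' @export
subject_features <- function(task, baseline,
                             params = preprocess_params(), seed = 1L) {
  eps_task <- preprocess_recording(task, params, seed)
  eps_base <- preprocess_recording(baseline, params, seed + 1L)
  spec_task <- estimate_spectra(eps_task, pool_channels())
  spec_base <- estimate_spectra(eps_base, pool_channels())
  pools <- pool_spec()

  apf <- lapply(pools, function(chs) detect_apf(spec_task, chs))
  bands <- lapply(apf, function(a) band_limits(a$apf))

  row <- list()
  for (p in names(pools)) {
    for (b in c("alpha", "theta")) {
      tv <- band_power(spec_task, pools[[p]], bands[[p]][[b]])
      bv <- band_power(spec_base, pools[[p]], bands[[p]][[b]])
      row[[sprintf("pow_%s_%s_task", b, p)]] <- tv
      row[[sprintf("pow_%s_%s_baseline", b, p)]] <- bv
      row[[sprintf("pow_%s_%s_corrected", b, p)]] <-
        as.numeric(baseline_correct(tv, bv, params$correction))
    }
    row[[sprintf("apf_%s", p)]] <- apf[[p]]$apf
  }
  prs <- pool_couplings()
  for (q in seq_len(nrow(prs))) {
    pa <- prs[q, 1]; pb <- prs[q, 2]
    pair_bands <- band_limits(mean(c(apf[[pa]]$apf, apf[[pb]]$apf)))
    for (b in c("alpha", "theta")) {
      tv <- pool_coherence(spec_task, pools[[pa]], pools[[pb]],
                           pair_bands[[b]])
      bv <- pool_coherence(spec_base, pools[[pa]], pools[[pb]],
                           pair_bands[[b]])
      row[[sprintf("coh_%s_%s_%s_task", b, pa, pb)]] <- tv
      row[[sprintf("coh_%s_%s_%s_baseline", b, pa, pb)]] <- bv
      row[[sprintf("coh_%s_%s_%s_corrected", b, pa, pb)]] <- tv - bv
    }
  }
  row$apf_asym_frontal <- apf_asymmetry(apf$FL, apf$FR)
  row$apf_asym_parietal <- apf_asymmetry(apf$PL, apf$PR)
  row$apf_low_confidence <-
    any(vapply(apf, `[[`, TRUE, "low_confidence"))

  list(features = as.data.frame(row),
       bands = bands,
       epochs = c(task_accepted = n_epochs(eps_task, TRUE),
                  task_total = n_epochs(eps_task),
                  baseline_accepted = n_epochs(eps_base, TRUE),
                  baseline_total = n_epochs(eps_base)),
       rejection = list(task = rejection_report(eps_task),
                        baseline = rejection_report(eps_base)))
}
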