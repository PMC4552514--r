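---
title: "Methods: EEG spectral correlates of WCST performance"
author: "eegwcst"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EEG spectral correlates of WCST performance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`eegwcst` implements an analysis chain for studying how scalp EEG rhythms
relate to executive performance on the Wisconsin Card Sorting Test (WCST)
across the adult lifespan: behavioural scoring and clustering, EEG
preprocessing, individualized-band spectral features, and the statistical
designs that separate age-dependent from age-independent markers. Because
raw human recordings of this kind are rarely shareable, the package ships a
synthetic cohort generator with known ground truth; every stage of the
pipeline is validated end to end against that truth and against closed-form
oracles.

# The WCST model

Four decks differ along three categories (color, shape, number of symbols);
deck *d* carries the *d*-th attribute of every category. Each trial, a
stimulus card must be matched to a deck under a hidden sorting rule;
feedback is binary. The rule changes after 10 consecutive correct matches
(one *completed category*), always to a different rule, and the test ends
after nine completed categories or 128 cards.

Scoring follows the classical taxonomy:

* **completed categories** — number of 10-consecutive-correct runs;
* **perseverative errors** — incorrect responses whose chosen deck matches
  the rule that was active before the most recent shift;
* **nonperseverative errors** — all other incorrect responses, split into
  *efficient* (before the first correct match under the new rule, i.e.
  rule-search) and *distraction* (after the rule had been demonstrated).

A response that is both perseverative and pre-acquisition counts as
perseverative: perseveration is treated as its own class. "Rule acquired"
is operationalized as the first correct trial under the current rule; this
is the simplest reading of "after discovering the category in use".
Perseverative responses are recognized anywhere in the current rule period,
not only immediately after the shift (configurable by scoring the matched
categories of each choice).

Each measure *V* is standardized across the cohort,
*z* = (*V* − mean(*V*)) / SD(*V*), with the sample SD (n − 1). The pooled
performance score is a weighted average of the three z-scores with the
category weight positive and both error weights negative; the magnitudes
are not fixed by the source design, so the default is (+1, −1, −1)
normalized by the sum of absolute weights — the simplest weighted average
with the stated signs — and the result is invariant to positive rescaling.
Performance levels are one-dimensional k-means (k = 3, best of 25 seeded
random starts, clusters relabelled good/medium/poor by descending mean);
k-means initialization details are otherwise unidentified, so
reproducibility drove the choice.

# Preprocessing chain

The order is fixed: band-pass filter → mains notch → ICA ocular correction
→ current source density (CSD) → 5 s epoching → amplitude rejection.

**Filters.** "Zero-phase Butterworth, 48 dB/oct" is realized as the squared
magnitude response of a 4th-order Butterworth (24 dB/oct each pass of the
forward–backward equivalent), applied in the frequency domain. This is the
exact zero-phase counterpart of forward–backward filtering, without startup
transients, and filters all channels with one FFT round trip — an order of
magnitude faster than time-domain `filtfilt` at study sizes. High-pass
0.3 Hz, low-pass 100 Hz; the quoted 0.5305 s time constant is 1/(2π·0.3)
and is treated as redundant with the cutoff. The notch is a zero-phase
2nd-order (squared) Butterworth band-stop, 2 Hz wide around 50 Hz; no
stop-band width is specified upstream, and 2 Hz leaves 45/55 Hz essentially
untouched.

**Ocular correction.** The montage carries no EOG leads, so the ocular
reference is a frontal proxy: the mean of the two most anterior channels.
A deflationary fixed-point ICA (logcosh contrast) extracts components one
at a time on whitened, time-decimated data; extraction stops when a
component fails to converge. This stopping rule is principled: directions
spanning a Gaussian subspace carry no contrast and are unidentifiable, so
once the non-Gaussian (artifact-like) part of the signal is exhausted the
iteration must stall. On blink-free Gaussian-like data nothing is
extracted and the correction is exactly the identity. A component is
flagged as ocular when its time course correlates with the frontal proxy
above 0.7 *and* its scalp pattern is frontally dominant, loading on both
anterior-most channels — the joint-loading clause matters because a
single-channel noise component correlates ~1/√2 ≈ 0.707 with a two-channel
mean, right at the threshold.

Flagged components are subtracted *time-locally*: activity is detected
where the component exceeds 5 robust SDs, dilated by ±0.3 s with a 0.1 s
cosine ramp, and the scalp pattern is re-estimated from those
high-signal-to-noise samples before subtraction. Continuous subtraction
was tried and rejected: it injects the pattern-estimation noise into every
sample, and the subsequent surface Laplacian amplifies that noise above
the rejection thresholds at random epochs.

**Current source density.** Spherical-spline surface Laplacian with spline
stiffness m = 4, regularization λ = 1e−5, 50 Legendre terms, on a 0.1 m
head sphere (units μV/m²). The transform is precomputed as a single
channels-by-channels matrix; a spatially uniform potential maps to zero by
construction (the spline's sum-to-zero constraint), and linearity is exact.

**Epoching and rejection.** Contiguous, non-overlapping 5 s epochs, not
locked to task events; trailing partial epochs are discarded. An epoch is
rejected when any inspected channel exceeds 500 μV/m² absolute amplitude
or 800 μV/m² peak-to-peak; the pipeline inspects the 12 pooled analysis
channels (the thresholds' channel scope is not specified upstream; pooled
channels are the ones entering every downstream statistic). When both
rules fire, the amplitude reason is recorded. Rejection is monotone in the
thresholds.

# Spectral features

Per accepted epoch, Hann-tapered periodograms and cross-periodograms are
averaged (no sub-epoch splitting: spectra are computed per 5 s segment,
giving 0.2 Hz resolution). The taper is power-normalized so the one-sided
PSD integrates (trapezoid) to the signal variance; the trapezoid rule also
makes band power exactly additive over adjacent bands.

The alpha peak frequency (APF) of a pool is the argmax of the pool-averaged
PSD on the 8–13 Hz grid, ties toward the lower frequency. The estimate is
flagged low-confidence when the maximum sits on a window edge (monotone
spectrum, e.g. pure 1/f) or rises less than 5% above the in-window median.
Bands are individualized per pool: alpha = APF ± 2 Hz, theta = APF − 7 to
APF − 3 Hz. APF is detected once per subject on the task spectra and the
same bands are reused for the baseline span, so task/baseline contrasts
compare identical frequency ranges.

Pool coherence is magnitude-squared coherence (msc) from the
epoch-averaged spectra — |C_ij|²/(C_ii·C_jj) — averaged over band bins and
then over the 9 cross-pool channel pairs. Averaging the 9 pairwise
statistics, rather than computing coherence of pool-averaged signals, was
chosen because signal averaging before coherence conflates within-pool
phase alignment with between-pool coupling. msc from a single epoch is
identically 1, so at least 2 accepted epochs are required. For a pool
pair with different APFs the pair band is anchored at the mean of the two
pools' peaks. Baseline correction defaults to subtraction of absolute
values (a dB log-ratio mode is provided for power); APF asymmetry is the
signed left-minus-right difference (frontal FL−FR, parietal PL−PR).

# Statistical designs

Per feature: (i) two-way ANOVA on age group × performance cluster with
Type II sums of squares — the main-effects-focused choice for unbalanced
designs; the interaction enters only when every cell holds ≥ 2
observations; (ii) OLS regression on age and performance z-score;
(iii) first-order partial correlations — feature–age controlling z-score
and feature–z-score controlling age — because age and performance are
strongly collinear (the generator plants r = −0.62). The partial
correlation equals the correlation of residuals from regressing each
variable on the control (a property the tests verify to 1e−10); p-values
use t with n − 3 df. Confirmatory subgroup modes restrict to good
performers (age effects) or to the oldest group (performance effects).
No multiple-testing correction by default; Benjamini–Hochberg is a flag.

# The synthetic cohort generator

The generator emulates the statistical structure of an aging/WCST study:

* **Ages** in three groups (young 20–34, mid 51–64, elder 67–82) with
  proportions 19/28/15 of 62, the composition fixed by largest-remainder
  allocation.
* **Latent skill** standardized, with sample correlation against age made
  *exactly* the configured target (default −0.62) by orthogonalizing the
  noise against standardized age. Skill maps to WCST agent parameters by
  logistic links (probability of knowing the active rule, perseveration
  and lapse rates), so measured z-scores correlate with age at ≈ −0.55.
* **Spectra.** Signals are frequency-domain random-phase surrogates: each
  component has a deterministic amplitude spectrum and random phases, so
  component band powers equal their targets exactly. Per channel: a 1/f
  background (exponent 1) with a 10% white floor; a near-uniform slow
  (0.3–0.9 Hz) global field of ~18 μV rms that the Laplacian suppresses;
  per pool, an alpha oscillator centred at the subject's APF — a broad
  Gaussian hump (σ = 0.6 Hz, 65% of the oscillator power) plus a sharp
  dominant-frequency line (σ = 0.06 Hz, 35%), mirroring the identifiable
  peak real alpha spectra show; and a flat theta component filling the
  band-power budget. Without the line, the hump's flat top leaves the
  planted peak undetermined at grid resolution under realistic epoch
  counts.
* **Coherence** is planted with one shared band-limited source per pool
  pair and band, added to all six channels of the two pools. For a shared
  source of in-band SNR γ over independent noise, msc = (γ/(1+γ))² — the
  closed-form oracle. Gains are solved from the coherence targets as
  g² = √(c·P_i·P_j). Within the alpha band, all components share the same
  hump-plus-line spectral shape (shared sources centred midway between the
  two coupled pools' peaks) so msc is approximately flat across the band
  and the band average matches the target. Pool patterns are spatially compact (members only):
  smooth spatial spreads were tried and rejected because cross-pool leakage
  of the oscillators adds spurious coherence well above the targets.
* **Planted effects** (per year of age, on the log scale for powers):
  alpha and theta power decline at 1.2% and 1.0% per year in all pools
  with 15% lognormal between-subject jitter; APF-left declines
  0.022 Hz/yr (SD 0.25 Hz); APF-right is nearly age-flat and weakly
  skill-dependent so the left–right asymmetry tracks performance; frontal
  and right fronto-parietal couplings (FL–FR, FR–PR, FR–PL) decline with
  age; FL–PR and PL–PR couplings depend on skill only (slopes 0.03 and
  0.015 msc per skill SD). The FL–PR slope was fixed by a design-stage
  power analysis: the elders-only subgroup has n ≈ 15, and a slope of
  0.03 gives the subgroup analysis adequate power at 20 analysis epochs.
  Baseline spans carry higher alpha/lower theta power (×1.35 / ×0.72) and
  a higher, effect-free coherence level, matching the qualitative
  task-versus-rest contrast the designs probe.
* **Artifacts.** Blinks are 300 ms raised-cosine transients band-limited
  below 6 Hz (real blinks carry no alpha-band energy; the raw pulse's
  spectral sidelobes would otherwise contaminate the alpha band), with a
  smooth, dipole-like frontally dominant topography (parietal floor 0.02 —
  a flatter parietal weight would move parietal variance by far more than
  the few percent a blink should). High-amplitude artifacts are brief
  focal bursts on one pooled channel, sized through the montage's own CSD
  operator to exceed the 500 μV/m² threshold post-transform in exactly the
  planted epochs.

**Amplitude calibration.** The rejection thresholds are fixed in physical
units, so the generator's amplitude scales were calibrated once so that
clean post-CSD data peaks near 300 μV/m² (peak-to-peak ≈ 600) — a
realistic margin under thresholds of 500/800 — while planted artifacts
reach ≈ 1500. This pins the raw band powers to the 10⁻³–10⁻² μV² scale:
post-CSD realism was deliberately preferred over raw-microvolt realism,
because every decision the pipeline makes (rejection, features,
statistics) happens after the transform.

# What the synthetic data do and do not show

The generator reproduces the *statistical* structure the designs care
about: age-graded spectra, calibrated coherence, individualized peaks,
performance-linked behaviour, stereotyped artifacts. It does not attempt
biophysical head modelling, event-locked dynamics, non-stationarity
beyond artifact transients, or realistic channel covariance beyond the
planted sources; its components are Gaussian surrogates except the
artifacts. Passing tests therefore demonstrate that the pipeline measures
what was planted under study-like conditions — not that real EEG meets the
generator's assumptions. One known interaction: shared coherence sources
sit spectrally between the two coupled pools' alpha peaks, so when
hemispheres are given very different APFs at high coupling, peak estimates
blend by a fraction of the split; at the cohort's planted asymmetries
(≲ 0.5 Hz) the bias is below one grid step.

# Problem sizes and numerical choices

Validation runs use sizes chosen for tight, repeatable checks: the
coherence oracle uses 500 five-second epochs at five SNRs (max |Δmsc| ≤
0.02); Parseval uses 60 epochs (±2%); artifact-ledger and blink checks run
cohorts at the full 1024 Hz over 100 s spans; the multi-seed
effect-recovery experiment uses 20 cohorts of n = 60 at 256 Hz with 100 s
task / 30 s baseline spans (20/6 analysis epochs), clean recordings, and
the ocular stage disabled — the corrector is separately verified to be an
exact no-op on blink-free data, and 256 Hz leaves all analysis bands
(≤ 15 Hz) and the 100 Hz low-pass far below Nyquist. Recordings default to
1024 Hz, 300 s task and 30 s baseline in `cohort_config()`.

Other numerical conventions: band-edge bins are inclusive with trapezoid
half-weights; APF ties break toward the lower frequency; the shared-source
test pair extends its source 0.5 Hz beyond the analysis band so Hann-taper
leakage does not dilute the edge bins; k-means uses 25 starts under a
fixed seed; EDF round-trips quantize to 16 bits against per-channel
symmetric physical ranges.

# Known limitations

* The ocular detector assumes blinks dominate the frontal proxy; very
  sparse blinks in long recordings lower the proxy correlation toward the
  0.7 threshold.
* Coherence estimates carry the usual ≈ 1/n_epochs positive bias; planted
  targets are recovered as ordering/effects at study epoch counts and as
  values only asymptotically.
* The two-way ANOVA drops the interaction in sparse designs rather than
  estimating it; tiny cohorts (n < 5) cannot support the regression or
  partial-correlation designs at all and are reported with those rows
  omitted.
* EDF support covers the continuous, equal-rate recordings the pipeline
  produces; annotations and variable-rate signals are out of scope.
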