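---
title: "coregload: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{coregload: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What this package computes

`coregload` analyzes co-registered EEG and eye-tracking recordings as
physiological proxies of cognitive load, and ships a synthetic-session
generator so that every stage of the analysis can be verified against
ground truth when no participant data is available.

The analysis chain is the one standard in fixation-related EEG work:

1. **Synchronization** — stimulus triggers recorded in both streams are
   matched by label and an affine map `eeg_sample = offset + scale * et_sample`
   is fit by least squares (`estimate_offset()`). The affine form absorbs
   clock drift; with none, the fitted scale is the rate ratio. Eye-tracking
   channels are linearly upsampled to the EEG rate and appended as extra
   channels (`upsample_et()`, `merge_streams()`).
2. **Gaze events** — blinks are the dropout-sentinel runs of the pupil
   channel, padded by 50 ms per side and linearly interpolated
   (`interpolate_blinks()`). Saccades come from an adaptive velocity
   detector: a centered moving-window velocity estimate, per-axis
   thresholds `eta = lambda * sigma` with the median-based scale
   `sigma = sqrt(median(v^2) - median(v)^2)`, criterion
   `(vx/eta_x)^2 + (vy/eta_y)^2 > 1` (`detect_saccades()`). Fixations are
   the complement of saccades and blinks (`derive_fixations()`), labelled
   by centroid containment in screen rectangles (`assign_aoi()`), with the
   three load proxies — fixation counts per AOI, mean picture-fixation
   duration, and text-picture transitions — from `gaze_metrics()`.
3. **EEG cleaning** — linear-phase FIR band-pass 0.25–48 Hz applied with
   exact group-delay compensation (`fir_filter()`); ocular components
   identified by correlation with an EOG reference and removed via ICA
   (`remove_eog()`); average re-reference (`rereference_average()`); 2 s
   epochs, stimulus-locked (tiled from each block onset) or
   fixation-related (locked to picture-AOI fixation onsets)
   (`extract_epochs()`); epochs with any sample strictly beyond ±100 µV
   rejected (`reject_artifacts()`).
4. **Spectra** — per epoch, 500 ms Hanning windows stepped by 250 ms,
   zero-padded to a 0.125 Hz grid, averaged, restricted to 2–30 Hz
   (`epoch_power()`); band power is the inclusive-bin mean over theta
   (4–6 Hz) and alpha (8–13 Hz) (`band_power()`). Per condition `c`,

   `ERD/ERS%_c = (P_c - B) / B * 100`,

   where `P_c` is the mean band power over the condition's kept epochs and
   the *global condition baseline* `B` is the unweighted mean of the `P_c`
   over all conditions of the task, computed separately per task, band,
   analysis (stimulus/fixation) and subject (`erd_ers()`). By construction
   the condition mean of `1 + value/100` is exactly 1 — this identity is
   asserted in the tests. Negative values mean desynchronization.
5. **Statistics** — repeated-measures ANOVA with Greenhouse–Geisser
   epsilon from the covariance of orthonormal within-subject contrasts and
   partial eta squared (`rm_anova()`); Holm-corrected paired post hocs
   (`posthoc_paired_t()`); per-electrode paired comparisons by
   subject-level sign-flip permutation of the paired t statistic with
   Benjamini–Hochberg FDR across the montage (`permutation_topo_test()`);
   repeated-measures correlation via the ANCOVA decomposition with
   `df = N(k-1) - 1` (`rmcorr()`); Cousineau-normalized condition SEMs
   with the Morey `sqrt(M/(M-1))` correction (`within_subject_sem()`).

Channels of interest default to the conventional load electrodes: Fz for
theta (frontal-midline, load-positive) and Pz for alpha (parietal,
load-negative).

## The synthetic world

`sim_config()` + `simulate_session()` generate a session with known truth:

- **EEG** = per-channel independent `1/f^beta` background (default
  `beta = 1`, 10 µV RMS, spectrum flattened below 1 Hz as a real
  high-passed amplifier would show) **plus** two narrow-band Gaussian
  noise carriers — theta 4–6 Hz projected with a frontal-midline-maximal
  topography (3 µV RMS at Fz), alpha 8–13 Hz with a parietal-maximal
  topography (4 µV RMS at Pz) — **plus** ocular transients (blink bumps of
  150 µV and a gaze-angle EOG of 10 µV/° at the frontal maximum) projected
  frontally, and a pure `EOG` reference channel. Carriers are *noise*, not
  sinusoids: a sinusoid would concentrate in single FFT bins and
  trivialize the band-power estimator; with noise carriers the power, not
  the phase, carries the condition effect. Condition effects are amplitude
  multipliers per band (power scales with the square).
- **Eye tracking** at 250 Hz: gamma-distributed fixation durations (mean
  250 ms), raised-cosine saccade profiles with durations 20–80 ms growing
  with amplitude (main-sequence-like; the kinematic model is a package
  choice, no canonical value exists), bounded-uniform fixational jitter
  (±1.5 px, bounded so that every saccade provably clears the jitter
  velocity floor), text/picture AOI targeting, a pupil channel
  (baseline + per-condition offset + slow drift) and blinks placed inside
  fixations with the dropout sentinel 0. There is no luminance model for
  the pupil: load offsets only.
- **Triggers** in both streams share labels; stimulus onsets are placed on
  the common 4 ms grid so both streams can represent them exactly, and the
  EEG-side copies get an integer jitter of at most ±3 samples. The ET
  stream leads by a configurable clock offset (default 400 ms).

Defaults mirror the recording situation the analysis targets: 1000 Hz EEG
over 30 scalp electrodes (+ EOG), 250 Hz binocular-style ET, four
decorative-picture conditions CC/IC/DC/NC in counterbalanced contiguous
blocks, 20 paragraphs x 20 s per reading block, n-back blocks of 60 trials
at exactly 2 s spacing with one-third targets. Where the recording
situation pins no value (carrier amplitudes in µV, blink rate, fixation
and saccade distributions), values were fixed once at field-typical
magnitudes and are not tuned to test outcomes.

What a green test does **not** establish: the generator has Gaussian
backgrounds, stationary carriers, rectangular AOI gaze, no smooth pursuit,
no line noise, no channel drift or bad electrodes, and no luminance-driven
pupil dynamics. Recovery results here bound the pipeline's correctness,
not its performance on real recordings.

## Analytic expectations

Because the band-power estimator smears power across bins (a 500 ms Hann
window has a multi-Hz main lobe), the expected *estimate* differs from the
raw band variance. `expected_band_power()`/`expected_erd()` convolve the
known synthesis spectra with the window's power kernel in closed form, and
account for average re-referencing (carrier weights become `w - mean(w)`;
independent backgrounds lose a factor `1 - 1/C`). Parameter-recovery tests
compare pipeline output against these expectations, never against numbers
derived by running the pipeline itself.

## Numerical choices

- **FIR design**: windowed-sinc, Hamming (~53 dB stopband). High-pass
  transition 0.125–0.25 Hz; low-pass transition 48–60 Hz so that mains-like
  60 Hz activity is already attenuated by >= 40 dB. The symmetric kernel is
  applied once by FFT convolution with exact integer group-delay
  compensation (zero phase, latencies preserved). The kernel is ~13.5 k
  taps at 1000 Hz; recordings shorter than the kernel are rejected.
- **ICA**: deflation FastICA (tanh), deterministic given a seed, estimated
  on an evenly spaced ~30 k-sample subsample. A symmetric scheme cannot
  converge on this generator's data — the background is exactly Gaussian,
  so the non-ocular subspace has no identifiable rotation and the
  symmetric update is noise-driven. Deflation pulls out the strongly
  non-Gaussian ocular components first and stops at the first
  non-converging component; components whose time courses correlate with
  the EOG reference above 0.7 (absolute) are subtracted. The removal report
  (component count, correlations) makes the automated selection auditable,
  replacing visual component screening.
- **Permutation scheme**: subject-level sign flips of paired differences
  (exchangeable under the paired null). When `2^N <= n_perm` all flips are
  enumerated exactly. Sampled p-values use the `(1 + hits)/(1 + n_perm)`
  estimator.
- **GG correction**: reported always, alongside the uncorrected p; effects
  with epsilon < 0.75 carry a sphericity flag.
- **Epoch windows** are `[onset, onset + 2 s)`; epochs may run into
  unlabeled gaps but are dropped if they cross into a *different*
  condition; overlapping fixation-locked epochs are retained (a
  `min_anchor_gap` option enforces non-overlap if wanted).
- **Rejection** is strict: a sample exactly at ±100.0 µV keeps the epoch.
- **Baseline weighting**: condition means enter the global baseline
  unweighted; `epoch_weighted_baseline = TRUE` switches to the
  epoch-weighted grand mean.
- **Event mapping** rounds half away from zero, making cross-stream sample
  mapping bit-exact and platform-independent.
- **Sentinel**: 0 is reserved for ET dropouts; upsampling propagates
  sentinel runs instead of interpolating across them; blink repair is the
  gaze module's job.
- **Jitter gate**: with uniform trigger jitter <= j, least-squares
  residuals can reach ~2j, so the pipeline's marker-residual gate defaults
  to twice the jitter bound. Offset recovery accuracy is unaffected
  (averaging over markers).

## Degenerate inputs

Flat gaze yields "no variability" and an empty saccade list; an
all-sentinel pupil channel, an all-condition-empty epoch set, and
zero-within-subject-variance correlations are errors; a condition with
zero kept epochs raises a classed condition so the pipeline can exclude
that subject from that analysis (mirroring the exclusion of a participant
with no distractor-picture fixations); zero-variance post hoc differences
are flagged rather than adjusted; all-equal ANOVA cells are flagged
degenerate instead of reporting F = 0/0.

## Known limitations

Single-eye gaze analysis path is the default (the binocular combination
rule in the literature is unstated; per-eye detection with temporal
intersection is available); no smooth-pursuit or microsaccade taxonomy; no
pupil foreshortening correction; no proprietary vendor formats (TSV
interchange only); topographic results are tables, not plots.
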