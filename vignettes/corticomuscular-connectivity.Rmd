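---
title: "Estimating corticomuscular connectivity from EEG and surface EMG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating corticomuscular connectivity from EEG and surface EMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

During object manipulation, the motor cortex and the muscles of the arm and
hand exchange information through the corticospinal pathway. Corticomuscular
connectivity quantifies the statistical dependence between cortical rhythms
recorded by EEG over sensorimotor sites (C3, Cz, C4) and the surface EMG of
the muscles executing the movement (anterior deltoid AD, brachioradialis B,
flexor digitorum FD, common extensor digitorum CED, first dorsal
interosseous FDI). In a reach--grasp--lift--replace paradigm each trial
begins with a 2 s rest baseline, a visual cue starts the movement, and the
object is replaced roughly 8 s into the trial; the experimental factor is
the object's contact surface (Sandpaper, Suede, Silk), i.e. the haptic
sensation during grip.

`cmconn` implements the full analysis path for this paradigm:

1. **Synthetic sessions with ground truth** (`session_spec()`,
   `generate_session()`),
2. **signal conditioning** (`preprocess_session()`),
3. **cortical characterisation**: relative power (`relative_power()`,
   `psd_hanning()`) and event-related desynchronization maps (`erd()`),
4. **muscle characterisation**: RMS activation envelopes
   (`rms_envelope()`, `summarize_activation()`),
5. **power-based connectivity** (PBC, `pbc()`): Spearman correlation of
   length-matched spectral feature vectors,
6. **windowed mutual information** (MI, `mi_session()`), and
7. **group statistics** across surfaces, channels and muscles
   (`run_studies()`).

Because the public grasp-and-lift recordings that motivate this design are
an external resource, the package is organised around a generative model
whose coupling structure is known exactly; every estimator is validated by
parameter recovery on those synthetic sessions.

## The generative model

`generate_trial()` draws, per EEG channel,

* a 1/f-amplitude Gaussian background (`noise_sd`, default 4 uV),
* a mu rhythm (10 Hz, amplitude 10 uV) whose amplitude is multiplied by
  `erd_amplitude_factor` (default 0.5) from the cue onward -- the injected
  event-related desynchronization; a halved amplitude corresponds to a
  -75% change in oscillatory power,
* a beta rhythm (20 Hz, amplitude 5 uV), constant across the trial,
* `kappa * drive_scale_eeg * D(t)`: a shared band-limited latent drive,
  gated to the movement interval `[cue, replace]` with 250 ms raised-cosine
  ramps.

Each muscle is band-limited (20--150 Hz) unit-variance noise whose envelope
rises by `emg_activation_gain` (default 2) during the movement, plus
`kappa * g_m * drive_scale_emg * D(t)` with the same drive resampled to the
EMG rate. The per-muscle gain `g_m` is highest for AD (2 versus 1), making
the anterior deltoid the dominant coupled muscle, which is also what gives
it the largest RMS envelope. The per-surface gain `kappa` defaults to
Sandpaper 0.6, Suede 1.0, Silk 0.3, with a +/-10% uniform per-subject
jitter so that group statistics see realistic between-subject variance.

Two generator choices deserve explanation:

* **The drive has a 1/f-tilted spectrum inside its band.** The PBC method
  (below) compares *positionally aligned* feature vectors; a spectrally
  decreasing drive imprints a consistent rank ordering on both modalities,
  which is the mechanism that makes mean connectivity increase with
  `kappa`.
* **The default drive band is 14--48 Hz** rather than the classical beta
  band alone. With the study's filters, a 14--30 Hz drive reaches only four
  of the 44 sEMG feature points (20, 23, 26, 29 Hz), which caps the
  attainable rank-correlation response well below the between-subject noise
  at realistic sample sizes. A drive spanning the full EEG-sEMG spectral
  overlap restores a cleanly recoverable effect; `drive_band = c(14, 30)`
  reproduces the beta-only variant.

What the generator does **not** emulate: motor-unit physiology of the EMG,
volume conduction and scalp topography beyond three channels, ocular or
movement artifacts (trials are generated inside the +/-350 uV bounds), and
any transmission delay between cortex and muscle (the coupling is
zero-lag, matching the MI estimator's zero-lag design). Passing tests on
synthetic sessions therefore demonstrate correctness of the estimators and
recoverability of the designed effects, not biological validity on real
recordings.

## Signal conditioning

The fixed pipeline order is resample, common average reference, band-pass,
notch, trial rejection, epoch split:

* EEG is polyphase-upsampled from 500 Hz to the EMG rate of 4 kHz with an
  interpolating windowed-sinc kernel (Kaiser beta 10, 16 taps per side).
  Because the kernel is a Nyquist filter, the original samples are
  preserved exactly; integer ratios only.
* "Eighth-order zero-phase Butterworth" is realised as a 4th-order design
  applied forward--backward, i.e. an 8th-order zero-phase magnitude
  response (`filter_mode = "double"` gives the 16th-order-effective
  reading). EEG band 6--50 Hz, sEMG band 20--150 Hz, 50 Hz notch with
  quality factor 25 (about 2 Hz wide).
* Trials whose filtered EEG exceeds +/-350 uV in any channel are rejected
  for all channels of both modalities; a subject is flagged when more than
  10% of trials are rejected. A config switch moves rejection before
  filtering.
* Baseline/task epochs split at the cue, half-open so no sample is shared.

One consequence of the band-pass worth knowing: the two-pass magnitude
response is down to roughly -6 dB *at* the band edges, so the conditioned
EMG spectrum carries a deterministic arch across 20--150 Hz. This shapes
the PBC baseline (below).

## ERD maps

`erd_time_frequency()` convolves each trial with analytic Morlet wavelets
(5 cycles at every frequency, 8--50 Hz in 1 Hz steps, 50 ms stride) and
expresses each time-frequency cell as the percentage power change against
that trial's mean baseline power at the same frequency
(`(A - B)/B * 100`); per-trial baselines are the default, trial-averaged
baselines are a flag. The per-frequency baseline average excludes the
wavelet cone of influence (3 sigma_t) at the trial edge; without this the
baseline is biased low at low frequencies and the significance mask
over-fires. Since the analysis band ends at 50 Hz, the map is computed on
the signal decimated to 500 Hz (`decimate_to`), which is lossless here and
about 60x cheaper than transforming at 4 kHz.

Significance is assessed per cell with a bootstrap-t (t-percentile)
interval on the across-trial mean: trials are resampled as whole units
(1000 replicates by default), a cell is marked when the two-sided interval
excludes zero, and no multiplicity correction is applied to the mask. The
acceptance suite verifies both calibration (significant fraction near the
nominal 5% on stationary sessions) and recovery (the injected mu
suppression is recovered at 10 Hz within the design tolerance, slightly
shallower than -75% because the 1/f background dilutes the oscillatory
power and the per-trial baseline ratio carries a small positive bias).

## Power-based connectivity

Per trial, the task-segment Welch PSD (1 s Hamming windows, 50% overlap,
1 Hz native resolution) of each EEG channel is compared with each muscle's
spectrum on the 20--150 Hz grid at 3 Hz resolution (44 points). To give
both feature vectors the same length, each EEG band is re-gridded to the
matched resolution

    FR = (EBL - 1) / (MBL - 1)

where EBL counts the band's integer frequencies and MBL = 44. For beta
(14--30 Hz, EBL = 17) this yields 16/43 = 0.372 -> 0.37 Hz. The published
values for the other bands (0.16 mu, 0.65 gamma, 1.25 All) are not
reproducible from any stated band edges with MBL = 44 (mu 8--13 gives
5/43 = 0.116, gamma 30--50 gives 20/43 = 0.465, All 8--50 gives 42/43 =
0.977); the package always reports the formula's value for the configured
edges. Re-gridding uses linear interpolation of the 1 Hz-native PSD;
feature vectors are min-max normalised per vector; the beta/gamma edge bin
at 30 Hz belongs to both bands unless `gamma_disjoint = TRUE`.

Connectivity is the Spearman rank correlation of the two vectors with a
one-sided p-value for rho > 0 (t approximation), computed per trial on the
task segment only; a one-sample Kolmogorov-Smirnov screen
(`normality_check()`) documents why the rank statistic is the appropriate
choice for these spectral features. Both conditioned signals live far
below 250 Hz, so the Welch features are computed on the signals decimated
to 500 Hz (`analysis_fs`), which leaves the features unchanged.

**A structural property to be aware of:** the estimator's null is not
centred at zero. Min-max-normalised PSD vectors have deterministic shapes
-- the decreasing 1/f EEG spectrum, the band-pass arch of the conditioned
EMG -- and two shaped vectors rank-correlate even when the underlying
signals are independent. The package's property tests therefore compare
the zero-coupling mean against a trial-shuffled pairing (the exact
independence baseline) rather than against zero, and group comparisons are
differences across surfaces, which remove the common baseline. Mean
connectivity is monotone in the injected gain, which is what the surface
studies rely on.

## Windowed mutual information

The trial is cut into adjacent 100 ms windows from t = 0 (400 samples at
4 kHz). Per window and signal, the bin count is
`(max - min) / (3.5 * sd * n^(-1/3))`, rounded, clamped to [1, 256]; an
IQR-based Freedman-Diaconis width is available behind
`optimal_bins(rule = "fd")`, but the SD-based width is the default
estimator. Entropies are computed from one joint histogram on each
signal's own equal-width edges; marginals are the joint's margins, which
makes MI exactly non-negative and MI(x, x) = H(x). No lag scan is
performed (the coupling of interest is zero-lag by design). Time courses
are averaged across trials first, then across EEG channels per muscle; the
two means commute on complete data.

A limitation the tests make explicit: because the bin count adapts to each
window's distribution, the estimator's finite-sample bias tracks the
*shape* of the signal distribution. A change in the EEG distribution alone
-- e.g. the post-cue mu suppression -- shifts the MI level by a few
hundredths of a bit even with zero coupling. Null checks therefore use
fully stationary sessions, and the coupled-versus-rest contrast is
established by the gated-coupling recovery test (MI elevated during
[cue, replace], declining after the replace event).

## Group studies

Four comparisons mirror the surface-contact analysis: (1) connectivity
averaged over muscles, compared across surfaces per channel and band; (2)
averaged over channels, per muscle and band; (3) broadband per-pair
connectivity compared across muscles within channel and across surfaces
within pair; (4) subject-level mean MI per muscle compared across muscles
per surface. The analysis unit is always the subject-level aggregate (mean
over trials). Two levels get a pooled-variance two-sample t-test; more
levels get one-way ANOVA with all pairwise t-tests Bonferroni-corrected
(raw p times the number of comparisons, capped at 1). Assumptions are
reported via Shapiro-Wilk or one-sample Kolmogorov-Smirnov normality
checks plus Levene's test (mean-centred); both normality variants are kept
because different parts of the original analysis used different screens.
No repeated-measures model is fitted -- the design gives no within-subject
error structure to exploit beyond the subject aggregate, and the paired
option covers the two-level case.

## Numerical choices and problem sizes

* Zero-phase filtering uses reflective padding of up to 3000 samples to
  suppress edge transients; filters are designed with `signal::butter`
  and applied by a compiled direct-form-II-transposed kernel.
* Degenerate inputs are handled explicitly: constant feature vectors are
  flagged (`pbc_spearman`), constant windows get one histogram bin,
  constant cells make the bootstrap interval collapse to the point mass.
* The bootstrap resamples whole trials, so spatial correlation across map
  cells is preserved; quantiles are the type-7 defaults.
* Validation scales: the surface-recovery study runs 20 replicates of 12
  subjects x 3 surfaces x 11 trials (sessions are generated and analysed
  per subject, streaming, to keep memory flat); ERD recovery and
  calibration use 50 trials and 1000 bootstrap replicates; MI gating uses
  100 trials. These sizes were chosen so each check has comfortable power
  at the designed effect sizes.

## Known limitations

* PBC compares feature vectors positionally, not at matched frequencies;
  its absolute value mixes genuine coupling with structural shape
  correlation and is best interpreted through contrasts.
* The histogram MI estimator carries a distribution-shape-dependent bias
  (see above); absolute MI levels should not be compared across conditions
  that change the signal distributions.
* The synthetic EMG is a phenomenological noise model, not a motor-unit
  simulation; absolute activation levels are arbitrary units.
* `resample_eeg()` supports integer upsampling ratios only.
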