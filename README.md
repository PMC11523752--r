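# cmconn

Corticomuscular connectivity analysis for EEG and surface EMG in R.

During object manipulation (reach, grasp, lift, hold, replace), cortical
rhythms recorded over sensorimotor sites (C3, Cz, C4) and the surface EMG of
the executing muscles (AD, B, FD, CED, FDI) become statistically coupled
through the corticospinal pathway. `cmconn` is for researchers who want to
quantify that coupling and compare it across experimental conditions — here,
the haptic quality of the grasped object's contact surface (Sandpaper,
Suede, Silk) — with two complementary estimators:

* **Power-based connectivity (PBC).** Per trial, the task-segment Welch PSD
  of an EEG band is re-gridded to the matched resolution
  `FR = (EBL − 1)/(MBL − 1)` — `EBL` the band's integer frequencies at the
  native 1 Hz resolution, `MBL = 44` the sEMG grid 20–150 Hz in 3 Hz steps —
  min–max normalised, and rank-correlated (Spearman ρ with a one-sided test
  of ρ > 0) against the equally normalised sEMG spectrum. For the β band
  (14–30 Hz) the matched resolution is 16/43 ≈ 0.37 Hz.
* **Windowed mutual information (MI).** Adjacent 100 ms windows; per window
  and signal the histogram bin count is
  `(max − min)/(3.5 · sd · n^(−1/3))`, and
  `MI = H(X) + H(Y) − H(X, Y)` in bits, with all three entropies taken from
  one joint histogram so that MI ≥ 0 holds exactly.

Around the estimators sit the full supporting pipeline: a synthetic
EEG/sEMG session generator with known coupling gains and
desynchronization depth (ground truth for validation), signal conditioning
(polyphase resampling to 4 kHz, common average reference, 8th-order
zero-phase Butterworth band-pass, 50 Hz notch, ±350 µV trial rejection),
event-related desynchronization maps (5-cycle Morlet wavelets, bootstrap-t
significance), RMS muscle-activation envelopes, and the four group studies
comparing connectivity across surfaces, channels and muscles (one-way
ANOVA with Bonferroni-corrected post-hoc t-tests on subject-level
aggregates).

## Worked example

Simulate a small cohort, condition it, estimate PBC, and compare surfaces
on the broadband (8–50 Hz) channel aggregate:

```r
library(cmconn)

spec <- session_spec(n_subjects = 4, n_trials_per_surface = 5, seed = 42)
session <- generate_session(spec)
epochs  <- preprocess_session(session)
records <- pbc(epochs)
summary(records)
#>      surface  band  mean_rho
#> 1  Sandpaper   all 0.5163928
#> 2       Silk   all 0.4402532
#> 3      Suede   all 0.6327813
#> ...

agg <- pbc_aggregate(records, mode = "per_channel")
cz  <- subset(agg, eeg_channel == "Cz" & band == "all")
compare_groups(cz$rho, cz$surface)
#> one-way ANOVA + Bonferroni post-hoc across Sandpaper, Silk, Suede
#>   omnibus p = 1.259e-05
#>    level_a level_b        p_raw  p_corrected significant
#>  Sandpaper    Silk 3.335558e-03 0.0100066748        TRUE
#>  Sandpaper   Suede 1.729759e-03 0.0051892758        TRUE
#>       Silk   Suede 6.133739e-05 0.0001840122        TRUE
```

The generator injected per-surface coupling gains κ = {Suede 1.0,
Sandpaper 0.6, Silk 0.3}; the broadband mean ρ recovers exactly that
ordering (0.63 > 0.52 > 0.44), and the ANOVA on subject-level aggregates
flags the surface effect. Note that the zero-coupling baseline of this
estimator is not 0 but ≈ 0.4–0.5: min–max-normalised spectra have
deterministic shapes that rank-correlate even for independent signals, so
PBC values are best read through contrasts (see the methods vignette).

The matched-resolution arithmetic itself:

```r
matched_resolution(band_definition("beta", 14, 30))
#> matched grid for beta (14-30 Hz): EBL = 17, MBL = 44, FR = 0.3721 Hz (0.37)
```

A full run — ERD maps, activation envelopes, MI time courses, study
tables, manifest — goes through `run_pipeline(pipeline_config(...))`, or
from a shell via the thin wrapper `inst/scripts/run-pipeline.R`.

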