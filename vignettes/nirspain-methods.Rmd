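---
title: "Methods: simulating and analysing fNIRS pain-modulation experiments"
author: "nirspain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing fNIRS pain-modulation experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirspain)
```

# Scope

`nirspain` implements the complete analysis chain of a functional
near-infrared spectroscopy (fNIRS) study of pain modulation by breathing
practice, together with a forward simulator of the whole experiment. The
study design it targets: two groups (traditional mindful breathing, TMB, and
virtual-reality-guided breathing, VRB) of 20 healthy adults each, measured at
two lab visits one week apart. Each session consists of a 5-minute rest, a
10-minute breathing practice, twenty trials of a thermal quantitative sensory
test (tQST: a thermode ramps from 30 °C at 1 °C/s until the subject signals
first pain, ceiling 50 °C, 10 s rest between trials), and a closing 5-minute
rest. Optical data are recorded at 25 Hz from a 45-channel montage (8
emitters, 28 detectors, 3 cm separation) at 690 and 830 nm.

Because no recording from the original cohort is publicly deposited, every
stage is validated property-wise against the simulator's ground truth and
against independent oracles (closed forms, hand-stepped algorithms,
Monte-Carlo calibration). The acceptance script reports the same quantities.

# Data model

A `probe_layout` stores emitter-detector pairs in a canonical order (sorted
by emitter, then detector); every downstream matrix indexes channels in this
order. Channel-to-region assignment is a static, editable table shipped as
configuration: the original localisation pipeline (photogrammetry, MNI
registration, atlas lookup) requires hardware and atlas assets and
contributes nothing to the statistics, so regions are plain labels (aPFC,
DLPFC, PMC, SMA, M1, S1, V1, STG, TPJ, IPL, other). The default montage is a
deterministic stand-in with the correct counts; the published montage has no
machine-readable pairing list, so only the counts and region vocabulary are
meaningful. Recordings round-trip through a plain-directory container (one
CSV intensity matrix per wavelength, JSON metadata at full float precision,
CSV-compatible events in the metadata), which is dependency-light and
diffable.

Time is seconds from recording start; events occupy half-open intervals
`[onset, onset + duration)`.

# From raw intensity to hemoglobin

Optical density change is `dOD(t) = -log(I(t)/Ibar)` per channel and
wavelength. `Ibar` is the temporal **geometric** mean of the session
(equivalently, `dOD = -(log I - mean(log I))`): this makes every dOD trace
exactly zero-mean, so concentration changes are referenced to the session
baseline. An arithmetic-mean baseline would leave a DC offset of about half
the OD variance (Jensen's inequality), which breaks exact forward-inverse
round trips without changing any fluctuation-based statistic.

The modified Beer-Lambert model relates dOD to chromophore concentration
changes:

`dOD_λ = (ε_HbO,λ ΔHbO + ε_HbR,λ ΔHbR) · L · DPF_λ`

with ε the molar extinction coefficients (cm⁻¹ M⁻¹), L the emitter-detector
separation (cm) and DPF the differential pathlength factor. The shipped
extinction table is the standard compiled one for 690/830 nm
(HbO 276 / HbR 2051.96 at 690 nm; 974 / 693.04 at 830 nm); DPF defaults to
6.0 at both wavelengths. Published fNIRS reports rarely state their
conversion constants; these defaults only rescale concentrations and cancel
out of all
t-statistics, and both are arguments of `od_to_hemoglobin()`. The 2×2 system
is solved exactly per time point, so with HbR modeled the inversion is a
genuine two-chromophore solve, not a one-unknown shortcut.

# Resampling and filtering

Decimation (25 → 2 Hz before activation modeling, 25 → 4 Hz before
connectivity) is zero-phase: a 6th-order Butterworth low-pass at 90 % of the
target Nyquist applied forward-backward, followed by spline evaluation on the
target grid. Output length is `floor(n·target/current)`; no group delay is
introduced, so event-locked responses keep their timing. (A polyphase
resampler from the `signal` package was rejected after it showed a
~0.2 s phase error on slow sinusoids; the defect and the in-package
replacement are regression-tested.)

Band-pass filtering is a high-pass/low-pass cascade of 4th-order Butterworth
sections, each applied with `filtfilt`. Order 4 per section was chosen so
that through the squared (zero-phase) response a mid-band tone keeps ≥ 95 %
of its amplitude while a tone one octave outside either edge loses > 90 %;
order 3 misses the 95 % passband requirement at 0.05 Hz in the 0.01–0.08 Hz
band. The cascade form stays numerically stable when the lower edge is far
below Nyquist (0.01 Hz at 25 Hz sampling).

A critical implementation detail: the first-level design is built at the
acquisition rate and passed through the *same* decimator as the data
(`build_design_decimated()`). The prewhitened fit weights exactly the
frequencies the anti-alias filter shapes, so a regressor built directly at
2 Hz biases amplitudes downward by several percent; sharing the filter
removes the bias to numerical precision (the noiseless pipeline recovers
amplitudes to ~1e-12).

# First-level activation model

Per channel, the HbO series at 2 Hz is modeled as `W y = W X β + W ε`:

* `X` contains one regressor per condition — the trial boxcar (duration =
  ramp time, known per trial) convolved with a canonical double-gamma HRF
  (unit peak at 6 s, 1/6 undershoot, 32 s support) — plus intercept and
  linear drift. Convolution uses the continuous-time convention (discrete
  sum × sample period), so amplitudes are rate-independent.
* `W` is an autoregressive whitening filter estimated from the residuals
  (Yule-Walker, order chosen by AIC up to 16 × rate, i.e. 32 at 2 Hz). The
  generous ceiling matters: narrowband physiological processes that survive
  decimation (Mayer wave, respiration) need AR orders well beyond the
  conventional 4 × rate before the whitened residuals are flat enough for
  nominal confidence-interval coverage (0.94 with the high ceiling vs 0.90
  at order 8 under the generator's default physiology); AIC still selects
  small orders when the noise is simple, and type-I calibration under AR(1)
  noise is unaffected (0.053 at α = 0.05).
* The regression is robust: Tukey bisquare M-estimation (tuning 4.685) via
  `MASS::rlm`.
* Whitening and reweighting alternate until the coefficient change falls
  below 1e-6 (at most 10 passes; non-convergence keeps the last iterate and
  flags the channel). Noise-free channels short-circuit to exact OLS.

Coefficient covariance comes from the robust fit on the whitened data; the
residual dof is `n - p`. Under AR(1) noise with lag-1 correlation 0.8 the
empirical type-I error at α = 0.05 is calibrated (the acceptance suite
requires [0.035, 0.065], while plain OLS on the same data exceeds 0.10), and
95 % CIs attain ~0.94 coverage under the generator's full physiological
noise. Only HbO is analysed — HbO dominates the measured hemoglobin signal
change — HbR exists in the model so the Beer-Lambert step stays honest.

# Group-level activation

Group maps model the per-subject first-level coefficients channel-wise with
a linear mixed-effects model, `β ~ 1 + (1 | subject)` (REML, Satterthwaite
degrees of freedom via `lmerTest`), and test the fixed effect with a
two-tailed t-test, `t = B̂ / sqrt(Cov_group)`. When each subject contributes
a single coefficient the random intercept is unidentifiable and the model
reduces to the one-sample t-test (vectorised, flagged `method = "fixed"`);
singular random-effect fits fall back the same way with a warning. Channel
p-values are Benjamini-Hochberg adjusted across the montage. Pooling
conventions that merge visits and conditions into a single large degrees-of-
freedom figure are not imitated; this package reports its own dof per model
in the `group_activation` table.

# Functional connectivity

Connectivity is computed on breathing-phase HbO at 4 Hz in two bands chosen
to avoid systemic physiology (Mayer ~0.1 Hz, respiration 0.3–0.5 Hz, cardiac
1–1.5 Hz): low 0.01–0.08 Hz (hemodynamic; the default analysis band) and
high 0.5–1 Hz. Per channel pair:

1. each band-passed series is prewhitened by its own AIC-selected AR filter
   (band-limited series are heavily autocorrelated; correlating raw series
   would inflate the effective dof),
2. a Pearson correlation with Tukey bisquare weights on the standardized
   bivariate residual distance is iterated to convergence (cutoff 6 on a
   distance that is approximately chi-distributed with 2 dof, so only gross
   outliers are discarded); a plain-Pearson flag exists as an oracle
   escape hatch,
3. the correlation is Fisher-Z transformed, `z = atanh(r)`.

Matrices are symmetric with a masked diagonal; numerically perfect pairs
(duplicated channels) are masked with a warning. Group edge maps reuse the
mixed-model/t-test machinery; the "significant pattern" flag marks edges
with p < .001 (the map threshold used for group connectivity figures), and
an FDR-adjusted column is always present.

# Heart-rate variability

The cardiac pulse is read from the 830 nm optical-density traces: the first
principal component across channels (the pulse is systemic, so averaging
boosts SNR; a single channel can be requested), band-passed to 0.01–2 Hz.
Because in-band hemodynamic fluctuations are larger than the pulse, beat
detection is two-stage: the cardiac fundamental f₀ is located as the
dominant spectral peak in 0.6–2 Hz, the signal is re-band-limited to
[0.5 f₀, 2 f₀], and peaks are detected there by local maxima with an
adaptive *topographic prominence* threshold (35 % of the 95th-percentile
candidate prominence) and a 0.4 s refractory period, with parabolic
sub-sample refinement. SDNN is the sample standard deviation (N−1
denominator) of the normal-to-normal intervals; the formula images in the
source text are unrenderable, so the standard sample-SD convention was
fixed and verified against a hand example (peaks at 0, 0.8, 1.8, 3.0 s give
SDNN exactly 0.2 s). Planted 50 ms beat variability is recovered within
~10 % from 5-minute resting segments.

# Brain-behavior edge selection

Edge features are the standardized upper-triangle Fisher-Z values (990 per
band), one row per subject-visit; the response is the mean tQST threshold in
°C. The elastic-net mixing weight sweeps 0 → 1 in steps of 0.1; for each
weight a penalty path (30 values) is fit and the cross-validated MSE is
averaged over 100 Monte-Carlo repetitions of random 10-fold assignments.
The (weight, penalty) pair at the CV minimum is selected, with exact ties
broken toward the sparser model. A 1-SE rule is config-exposed and used for
null-coupling checks (where "near-empty" means at most 5 of 990 edges): it
picks the most parsimonious model over the whole grid whose CV error lies
within one standard error of the minimum, with the SE computed as the
per-repetition fold SE averaged over repetitions (repetitions reuse the
same observations and must not shrink it). Without the parsimony extension
the ridge column can win on null data, and ridge coefficients are never
exactly zero — "selection" would degenerate to all 990 edges. Edges with
|coefficient| > 1e-8 count as selected at every mixing weight, including
the ridge end. Selected edges are reported
with Pearson r (t-based two-tailed p) and Spearman ρ (two-tailed p) against
the threshold — the rank correlation guards the per-edge report against
outliers — plus FDR-adjusted columns. Selection runs per group with visits
pooled as rows (group-specific edge sets are the reported object; the
convention is switchable by subsetting the behavioral table). Fold
assignments derive from the seed, so identical seeds give identical
selections.

# The forward simulator

`simulate_cohort()` generates the full design with known truth at every
level the chain estimates. Per subject-session, HbO per channel is the sum
of:

* **activation**: per-channel amplitude β (µM) times the trial
  boxcar ∗ canonical HRF; trial durations follow the subject's per-trial
  thresholds through the 1 °C/s ramp;
* **planted connectivity**: a band-limited (0.01–0.08 Hz) resting
  fluctuation built from per-edge latent factors with √|r| loadings, so each
  planted pair hits its target correlation and the structure survives the
  band-pass analysis (a latent-factor construction rather than covariance
  Cholesky); a positive-semidefiniteness check rejects infeasible edge sets.
  Subject-level edge strength varies as Fisher-Z ~ Normal(atanh r, 0.3);
* **cardiac**: a cosine driven by a phase accumulator over the beat-period
  sequence, so ground-truth SDNN is exact by construction. Beat periods are
  mean 1/1.1 s with AR(1) deviations over beats (lag-1 0.8, marginal SD
  50 ms): autonomic RR modulation is slow relative to the beat, and white
  beat-to-beat jitter would place FM sidebands beyond the 2 Hz analysis
  band. The beat train is systemic (shared across channels with
  channel-specific gain) — that is what lets a principal component recover
  the pulse;
* **Mayer and respiratory oscillations**: channel-local narrowband Gaussian
  processes centred on 0.1 and 0.35 Hz (±20 %), amplitude 0.15 µM. They are
  deliberately *not* shared across channels: local vasomotor coupling
  varies, and a perfectly coherent systemic oscillation — even one strongly
  attenuated by the analysis band — would be re-amplified by prewhitening
  and flood the null edges;
* **noise**: AR(1) (lag-1 0.3 at 25 Hz, marginal SD 0.3 µM) per channel.

HbR is −1/3 of the neural HbO component plus small independent noise — the
typical physiological ratio, present so that the two-wavelength inversion is
a genuine 2×2 solve. Concentrations are forward-projected through the same
Beer-Lambert model the analysis inverts and exponentiated around positive
baseline intensities with random per-channel gains (which also exercises the
gain invariance of the OD transform). Stored concentration truth is
referenced to the session mean, matching what any baseline-referenced
analysis can recover.

Thresholds are drawn around group × visit means of 45.4/46.0 °C (TMB visits
1/2) and 46.5/47.1 °C (VRB), truncated to the 30–50 °C thermode range, with
the first planted edge coupled at 3 °C per Fisher-Z unit and residual SD
0.9 °C (coupling R² ≈ 0.5). The activation default β = 0.1 µM was calibrated
once so that first-level t-statistics land at ~3–5 under the default
physiology at the study's trial count, matching the regime the method is
meant for; it is config-exposed. All randomness flows from one root seed
through documented per-group/subject/visit substreams, so cohorts are
bit-reproducible.

Band-limited noise components are synthesised spectrally (Gaussian Fourier
coefficients on the band, inverse FFT at a 2-3-5-smooth padded length) —
exactly band-limited and O(n log n).

## What the simulator does not emulate

Motion artifacts, superficial/extracerebral physiology and short-separation
regression, optode-coupling drift, realistic photon transport (amplitudes
enter through a fixed DPF), non-Gaussian HRV dynamics, and any group
difference in connectivity density (group contrasts beyond planted effects
are null by construction). Green tests therefore certify the statistical
machinery under the modeled physiology, not performance on artifact-laden
real recordings.

# Problem sizes used by the test and acceptance runs

Monte-Carlo validation uses the study's statistical structure at reduced
problem sizes, chosen once as the package's validation design: group-map
cohorts simulate at 5 Hz with 10 s rests (only the thermal phase feeds the
GLM; the 2 Hz analysis rate is unchanged); edge-recovery cohorts simulate
natively at 4 Hz with 240 s breathing segments; elastic-net replicates use
20 Monte-Carlo CV repetitions instead of 100; the end-to-end check runs the
full 25 Hz two-visit pipeline on 2 × 10 subjects with a shortened closing
rest (the closing rest feeds no statistic). Type-I, coverage, and recovery
targets are at the full replicate counts stated in the tests.

# Known limitations

* The robust-correlation scheme follows the cited toolbox's published
  approach in spirit (prewhiten, then bivariate bisquare reweighting); the
  exact algorithm of the original toolbox is not published, so numerical
  equality with it cannot be claimed.
* Group dof conventions are per-model (mixed-model Satterthwaite or
  `n - 1`); pooled conventions from other toolchains will not match
  numerically.
* The SNIRF/HDF5 container is not read or written; the plain-directory
  container is the supported format.
* With one observation per subject the "mixed" group model is by necessity a
  fixed-effects t-test; between-subject variance is then not separable from
  within-subject error.
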