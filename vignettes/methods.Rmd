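---
title: "Methods: simulation, preprocessing, activation mapping, features, classification and diffusion augmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirsicpp)
```

# The problem

Idiopathic central precocious puberty (ICPP) is currently diagnosed with an
invasive GnRH stimulation test. Functional near-infrared spectroscopy
(fNIRS) over the prefrontal cortex during a mental-arithmetic (MA) task is
a candidate noninvasive screen: premature sex-hormone exposure alters
prefrontal activation, and those alterations are measurable as channel-wise
hemodynamic amplitudes. `nirsicpp` implements the complete analysis chain
for such a study — from raw dual-wavelength light intensities to a
classifier score — together with a seeded synthetic-cohort generator, so
that every stage can be validated end to end without access to clinical
recordings.

# The synthetic cohort generator

The generator defines the study conditions the rest of the package is
tested under.

**Paradigm.** Two trials of (2-s prompt, 30-s MA block, 2-s prompt, 30-s
rest), sampled at 1 Hz: 128 s and 128 samples per subject
(`build_paradigm()`).

**Hemodynamics.** Each channel's oxy-hemoglobin signal is
`true_beta[ch] * (MA boxcar convolved with the canonical HRF)` plus noise;
deoxy-hemoglobin is the task component scaled by `-r` (default r = 0.3)
plus its own attenuated noise, reproducing the sign inversion of
task-evoked HbR; total hemoglobin is their sum. Ground-truth amplitudes
are stored so recovery can be scored exactly.

**Noise model** (`noise_config()`, amplitudes in umol/l, chosen once as
field-realistic values; the source study reports no generative model):

| component | default | rationale |
|---|---|---|
| respiratory | 0.25 Hz, 0.05 | breathing sits above 0.2 Hz |
| Mayer wave | 0.10 Hz, 0.08 | blood-pressure oscillation near 0.1 Hz |
| linear drift | 0.002 / s | slow instrument/physiology drift |
| white noise | sd 0.05 | measurement noise; also the alias of cardiac pulsation, which at >0.5 Hz cannot be represented at a 1 Hz sampling rate |
| motion spikes | 0.5 / min, 1.0 | sparse high-amplitude artifacts |
| bad channels | p = 0.01 per channel | roughly 10% of subjects discarded at 10 channels, a realistic attrition |
| antiphase pair | channels (2, 7), 0.2 at 0.04 Hz | a shared oscillation with opposite sign on two channels, emulating negatively correlated network activity; it lies inside the 0.1 Hz passband so it survives filtering |

**Cohort structure.** Default cell sizes mirror the study population
(57/28 normal and 54/28 ICPP females/males). Per-cell mean activation
profiles (`cohort_effects()`) encode the qualitative findings the study
design presumes: broader, stronger activation in normal children
(especially females) and attenuation over left-hemisphere channels in
ICPP; per-subject amplitudes are Gaussian around the cell profile
(between-subject sd 0.15 umol/l). Demographics and clinical markers are
truncated Gaussians around the published summary statistics, with markers
archived only for ICPP subjects.

**Forward optics.** Intensities follow the modified Beer-Lambert law in
the forward direction at 775 and 855 nm, 30 mm source-detector separation,
DPF 6.0 at both wavelengths, and extinction coefficients interpolated from
standard compiled hemoglobin spectra (the source study states neither DPF
nor extinction values). The generator emits exactly two trials per
subject.

**What the generator does not emulate:** spatially correlated physiology
across channels, serially correlated (AR) noise, systemic superficial
contamination, subject-specific HRF variability, or head/optode geometry.
Passing tests therefore demonstrate correctness of the analysis machinery
under a plausible generative model, not clinical performance on real
recordings.

# Preprocessing

The chain is quality screen, MBLL, detrend, low-pass, motion repair.

**Quality screen.** The coefficient of variation of raw intensity,
`CV = sd(I)/mean(I) * 100`, is computed per channel and wavelength; a
channel's CV is the maximum over wavelengths (a channel is only as good as
its worse wavelength; whether the screen is per wavelength is not
specified in the source). Channels with CV strictly exceeding 15% are bad
(a CV of exactly 15% is kept), and a subject with any bad channel is
discarded.

**MBLL.** The two-wavelength attenuation changes
`dA(lambda) = log10(I0/I)/DPF(lambda)` are solved for dHbO and dHbR using
the extinction-coefficient matrix and the source-detector distance;
dHbT = dHbO + dHbR by definition. The baseline `I0` is unobservable on a
continuous-wave instrument, so the default is each channel's temporal mean
intensity, making the outputs mean-referenced relative concentrations.
For simulated data the true baseline is available (`i0 = "stored"`), and
with it the conversion inverts the forward model to numerical precision
(the roundtrip is tested below 1e-9 umol/l).

**Detrending.** Least-squares polynomial fit per channel, default order 1
(intercept + linear drift), removed; the residual is orthogonal to the
polynomial basis.

**Low-pass.** Third-order Butterworth, cutoff 0.1 Hz, applied
forward-backward so the response is zero-phase with the squared
single-pass magnitude; zero phase matters because a phase lag would shift
the data relative to the GLM regressors. Signals are odd-reflection
padded (10/cutoff samples) before `signal::filtfilt`, which otherwise
leaves large start/end transients because it does not match initial
filter states. Note the digital (bilinear) design at a 1 Hz rate
attenuates 0.2 Hz somewhat more strongly than the analog prototype
arithmetic suggests (measured gain ~0.008 versus ~0.015).

**TDDR motion repair.** Temporal derivative distribution repair
iteratively reweights derivative fluctuations with Tukey's biweight
(tuning constant 4.685 on robust-standardized values, scale 1.4826 x
MAD), zeroing gross outliers, then reintegrates. The reference
formulation first splits the signal at 0.5 Hz and repairs only the
low-frequency part; at a 1 Hz sampling rate 0.5 Hz *is* the Nyquist
frequency, so no such split exists. Naively biweighting the whole
centered derivative is destructive here: half the samples of a block
design are plateaus with near-zero derivative, so the robust scale
collapses and the block transitions of the clean hemodynamic response are
rejected as outliers (in development this drove the recovered amplitudes
toward zero). The package therefore estimates the derivative's slow
component with a short running median (width 5), restores it untouched,
and applies the biweight to the fast residual only — the same
protect-the-slow-component intent as the original 0.5 Hz split, adapted
to the 1 Hz rate. A degenerate-scale guard (scale floor at 1e-6 of the
largest residual) ensures isolated gross excursions are still rejected
when the residual distribution is otherwise exactly zero. Measured on
clean signals the correction changes less than ~2% RMS and removes ~99%
of a 10x-amplitude spike. TDDR runs after the low-pass, following the
published order; note that a spike already smeared by the 0.1 Hz filter
is no longer repairable, so the unit-level spike guarantees apply to the
operator itself, and the step order is configurable.

# Activation mapping

The canonical HRF is the standard double-gamma (peak delay 6 s,
undershoot delay 16 s, unit dispersions, ratio 1:6, 32-s support,
peak-normalized); none of these values are given in the source, so the
standard parameterization is used. The design matrix contains an
intercept and the HRF-convolved MA and rest boxcars (prompts unmodeled);
rest is an explicit regressor, so the paired contrast is MA-beta versus
rest-beta. Because detrending and zero-phase filtering are linear, the
same operations are applied to the regressors (`match_preprocess = TRUE`);
fitting filtered data against unfiltered regressors attenuates the
amplitude estimates by about 7% in this configuration, which would exceed
the 5% recovery-bias budget.

Channel-wise ordinary least squares yields per-subject amplitudes.
Group statistics are summary-statistics t tests per channel: paired
(MA versus rest) within group x gender, and two-sample with pooled
variance (Welch optional) between groups, each family adjusted with
Benjamini-Hochberg FDR at 0.05 (the source names only "FDR"; BH is the
standard step-up choice, applied per species x gender x test family).
Shapiro-Wilk and Levene checks are available for the amplitude samples.
Pearson correlation links amplitudes to clinical markers.

The a priori power calculation is exposed in both printed forms: the
closed-form normal approximation `n = 2 (z_a/2 + z_b)^2 / d^2` gives 63
per group at alpha = 0.05, power 0.80, d = 0.5, while the exact
noncentral-t solution iterated over integer group sizes gives 64 — the
discrepancy between the printed formula and the printed answer is real
and both are reported rather than reconciled.

# Feature families

Trials are 60-s windows: each MA block concatenated with its rest block,
prompts excluded. Five families are built from a state fitted on the
training split only; applying the state to held-out trials never refits
(this is asserted in tests).

* **A (8):** per trial, the 10x10 Pearson matrix across channels is
  scanned for its most negative entry; the modal pair across training
  trials (ties: more negative mean correlation, then lexicographic) is
  fixed, and mean, sample variance (denominator n-1), moment skewness and
  Fisher excess kurtosis of the two pair channels are the features.
  Constant channels are excluded from candidacy with a warning. One
  global pair per training set is used (the alternative per-subject
  reading of the source is not implemented; the study's results reference
  a single fixed pair).
* **B (30):** PCA per channel with trials as observations and time
  samples as variables, mean-centered, top 3 scores. (Whether trials or
  time points are the observations is unstated in the source; trials are
  chosen so the basis transfers to held-out trials.)
* **C (14):** A concatenated with the 3 PCA scores of each pair channel.
* **D (30):** per channel, EMD per trial; IMFs aligned by index
  (zero-padded past the decomposition depth), and per IMF index a PCA
  across trials keeps the first-component score. Three IMF indices per
  channel.
* **E (10):** per-trial GLM on the 60-s window (intercept + HRF-convolved
  MA and rest half-window boxcars); the MA amplitude per channel.

The EMD is the standard sifting loop: cubic-spline envelopes through
interior extrema with the series endpoints as additional support, mean
envelope subtracted until the Cauchy-type criterion (threshold 0.2)
stops, at most 10 IMFs, monotone residues terminate. Completeness — IMFs
plus residue reconstruct the input — holds by construction and is tested
to 1e-10.

# Classification

The split is 80:20, stratified by class, seeded. The default split unit
is the subject, keeping a subject's two trials together (a trial-level
split is available to mirror the source protocol, but subject-level is
the default because within-subject trials are strongly dependent).
Five families — RBF support vector machine, decision tree, random
forest, linear discriminant, k-nearest-neighbor — are tuned by
exhaustive grid search over documented default grids, scored by mean
10-fold cross-validated accuracy (the source does not state the scoring
metric; accuracy is assumed), ties to the first grid row, refit on the
full training set. Evaluation reports the confusion counts with ICPP
(label 1) positive, accuracy and specificity as percentages, and
precision/recall/F1 computed per class and averaged with weights equal
to the true class counts, matching the weighted protocol for imbalanced
cohorts.

# Conditional diffusion augmentation

A conditional denoising diffusion probabilistic model over standardized
HbO trial segments (10 x 60). The forward process uses a linear variance
schedule, 200 steps from 0.001 to 0.02; the closed-form marginal
`f_t = sqrt(abar_t) f0 + sqrt(1 - abar_t) eps` is tested against iterated
single-step noising, and `abar_200 ~ 0.121`.

**Denoiser.** A fully connected encoder (width 128) - bottleneck (64) -
decoder (128) network with GELU activations and a skip connection from
encoder to decoder, taking the noised segment, a sinusoidal timestep
embedding augmented with `sqrt(abar_t)` and `sqrt(1 - abar_t)`, the class
one-hot, and the standardized per-trial GLM amplitude vector. No
self-attention is used: at 10 x 60 the dense bottleneck already has a
global receptive field, and attention added complexity without benefit
at this scale. Forward and backward passes are hand-written matrix
algebra (gradients verified against finite differences in development);
optimization is AdamW (lr 0.001, weight decay 0.01, batch 64) with the
reference training length of 500 epochs; reduced desk-scale profiles are
used in tests.

**Objective.** The network predicts the clean segment and the noise
estimate follows analytically from the forward marginal; the training
loss is the mean squared error in clean-signal space, which equals the
noise-prediction MSE weighted per timestep by the inverse
signal-to-noise ratio. With an unweighted noise-space MSE this compact
denoiser spent its capacity on nearly-noiseless timesteps whose noise is
unpredictable anyway and never learned the class-conditional structure;
the SNR weighting is the standard remedy.

**Sampling.** Ancestral DDPM updates with the posterior variance
`sigma_t^2 = (1 - abar_(t-1))/(1 - abar_t) beta_t` and a deterministic
final step. Because the 200-step schedule terminates at `abar_T ~ 0.121`
— far from zero — the terminal marginal is not pure noise: its mean is
`sqrt(abar_T) x0 ~ 0.35 x0`. Sampling therefore starts from the forward
marginal around the class-conditional training mean rather than from a
unit Gaussian; a unit-Gaussian start sits measurably off the learned
manifold and biases every generated sample toward zero. Both the
posterior-variance choice and the marginal-matched start are standard
options; the commonly quoted `sigma_t^2 = beta_t` variant was measurably
worse here (over-dispersed trajectories on near-deterministic data).
On toy two-class data the generated class-conditional means land within
0.3 of the training means; generated within-class spread is tighter than
the training spread (mode-seeking), which is acceptable for
augmentation but means the model should not be read as a calibrated
density estimate.

**Protocol.** The model is trained on the real training split only;
augmentation generates synthetic segments equal in number to the real
training set with matching class proportions, flags them, and leaves the
test set untouched (a leakage check errors if any test trial was seen in
diffusion training). The per-trial amplitude condition is resampled from
the training pool of the requested class (per-trial rather than
per-subject conditioning, for shape consistency with segments).

# Orchestration and determinism

`run_experiment()` executes simulate, QC, preprocess, GLM and stat maps
per gender, segmentation, feature fitting/extraction, split, optional
diffusion augmentation, grid-search training, and evaluation, from a
single configuration with one master seed. Every stochastic stage
derives its own seed deterministically from the master seed through a
named substream, so identical configurations reproduce identical reports;
all thresholds (CV 15%, 0.1 Hz cutoff, FDR 0.05, 8:2 split, 200-step
schedule) live in the configuration with their study defaults.

# Problem sizes used by the test suite

The suite exercises the pipeline at sizes chosen to give each property a
clear signal on a single CPU: cohorts of 20-44 subjects for end-to-end
runs, 200 subjects x 50 replicates for the null FDR calibration, 500
replicates for confidence-interval coverage, 50 seeded cohorts for
channel-pair recovery, 10,000 Monte-Carlo draws for the diffusion
marginal checks, and reduced diffusion training (60-300 epochs, widths
96-128) for the generative checks. The paper-scale configuration
(57/28/54/28 subjects, 500 epochs) is available through the same
configuration objects.

# Known limitations

* The generator's independence assumptions (white noise, independent
  channels apart from the planted pair) are favorable to the GLM; real
  fNIRS noise is serially and spatially correlated, and no AR
  prewhitening is implemented.
* TDDR after a 0.1 Hz low-pass cannot repair already-smeared spikes; the
  operator order is configurable but the published order is the default.
* The diffusion sampler is mode-seeking on near-deterministic data; no
  DDIM or alternative samplers are provided.
* Specificity on small test sets is quantized (few normal subjects), so
  augmentation comparisons are averaged over seeds.
* No anatomical modeling, no MNI projection, no short-separation
  regression, no deep-learning classifiers.
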