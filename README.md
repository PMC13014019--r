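# nirsicpp

Prefrontal fNIRS analysis for screening idiopathic central precocious
puberty (ICPP): a complete, seeded pipeline from raw dual-wavelength light
intensities to a classifier decision, with a synthetic-cohort generator so
that every stage is testable without clinical recordings.

ICPP is diagnosed today with an invasive GnRH stimulation test. Because
premature sex-hormone exposure alters prefrontal function, channel-wise
hemodynamic responses measured with functional near-infrared spectroscopy
(fNIRS) during a mental-arithmetic (MA) task are a candidate noninvasive
screen. This package is aimed at researchers building or auditing such
pipelines: it implements the full analysis chain and validates each stage
against ground truth from a generative model of the experiment.

## What it implements

* **Cohort simulation** — block paradigm (2 trials of 2-s prompt / 30-s MA
  / 2-s prompt / 30-s rest at 1 Hz), HRF-convolved task responses with
  group- and gender-specific per-channel amplitudes, physiological noise
  (respiratory, Mayer wave, drift, motion spikes, aliased cardiac),
  occasional high-variance bad channels, and forward-modeled raw
  intensities at 775/855 nm via the modified Beer–Lambert law (MBLL).
* **Preprocessing** — channel quality screen by coefficient of variation
  (CV = σ(I)/μ(I) × 100, bad if > 15%); MBLL inversion to ΔHbO/ΔHbR/ΔHbT
  (μmol/l); polynomial detrending; third-order zero-phase Butterworth
  low-pass at 0.1 Hz; temporal derivative distribution repair (TDDR) for
  motion artifacts.
* **Activation mapping** — channel-wise GLM `y = Xβ + ε` with canonical
  double-gamma HRF regressors for MA and rest; paired (MA vs rest) and
  two-sample (normal vs ICPP) t maps per gender with Benjamini–Hochberg
  FDR at 0.05; Shapiro–Wilk/Levene checks; Pearson brain–marker
  correlation; a priori power analysis
  `n = 2 (z_{α/2} + z_β)² / d²` and its exact noncentral-t counterpart.
* **Feature extraction** — five families per 60-s trial: (A) time-domain
  statistics of the most frequently most-negatively-correlated channel
  pair, (B) first 3 PCA scores per channel, (C) their combination,
  (D) first-PC scores of EMD intrinsic mode functions, (E) per-trial GLM
  amplitudes.
* **Classification** — stratified seeded 8:2 split (subject-level by
  default), grid-search 10-fold cross-validation over SVM, decision tree,
  random forest, LDA and kNN, and evaluation with accuracy, specificity
  (TN/(TN+FP)) and class-weighted precision/recall/F1.
* **Conditional diffusion augmentation (C-DDPM)** — forward noising under
  a linear 200-step β schedule (0.001 → 0.02), a conditional denoiser
  (class one-hot + per-trial GLM amplitudes + timestep embedding) trained
  with AdamW, ancestral sampling, and a train-only augmentation protocol
  that doubles the training set while the test set stays real.

## Worked example

```r
library(nirsicpp)

pdg  <- build_paradigm()
coh  <- sample_cohort(n_per_group = list(normal = c(female = 8, male = 8),
                                         ICPP   = c(female = 8, male = 8)),
                      seed = 42)
prep <- preprocess_cohort(coh)          # QC + MBLL + detrend + low-pass + TDDR
cg   <- cohort_glm(prep$hemo, pdg)      # per-subject channel-wise GLM

meta  <- coh$subjects[coh$subjects$subject_id %in% prep$kept, ]
fem_n <- meta$subject_id[meta$group == "normal" & meta$gender == "female"]
fem_i <- meta$subject_id[meta$group == "ICPP"   & meta$gender == "female"]
group_t_map(cg$beta_ma[fem_n, ], cg$beta_ma[fem_i, ])
#>    channel       t p.value p.adjusted significant
#>  1       1  4.28   0.00108    0.00655 TRUE
#>  2       2  3.27   0.00671    0.0168  TRUE
#>  3       3  2.79   0.0163     0.0325  TRUE
#>  4       4  3.94   0.00197    0.00657 TRUE
#>  5       5  4.17   0.00131    0.00655 TRUE
#>  6       6  1.74   0.108      0.179   FALSE
#>  7       7 -1.27   0.227      0.325   FALSE
#>  ...
```

Two of the 32 simulated subjects were discarded at QC. The generator
plants reduced ICPP activation on channels 1–5 for females, and the
FDR-corrected two-sample t map recovers exactly those channels: positive
t means stronger activation in the normal group, and `significant` flags
adjusted p < 0.05.

```r
required_sample_size(power = 0.80, alpha = 0.05, d = 0.5)
#>   n_per_group n_total achieved_power method
#> 1          64     128          0.801 noncentral_t
```

64 participants per group (128 total) are needed for a two-sided
two-sample t test at α = 0.05, power 0.80, d = 0.5; the closed-form
normal approximation (`method = "normal_approx"`) gives 63.

```r
cfg <- default_config(7)
cfg$diffusion$enabled    <- TRUE
cfg$diffusion$epochs     <- 60
cfg$diffusion$batch_size <- 16
res <- run_experiment(cfg)
res
#> <experiment_result> feature set A, tree classifier; 56 train / 16 test trials
#>   accuracy 75.00%, specificity 50.00%
#>   augmented: accuracy 81.25%, specificity 62.50%
```

The end-to-end run simulates a 40-subject cohort, preprocesses it, builds
feature set A, trains a decision tree by grid-search cross-validation, and
evaluates on held-out real trials with and without diffusion-generated
synthetic training data; here augmentation lifts both accuracy and
specificity on the same real test set. `make_report(res, "out/")` writes
the activation TSVs, metric tables and a provenance manifest.

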