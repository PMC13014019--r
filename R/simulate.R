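#' Physiological and instrumental noise configuration
#'
#' Describes the additive noise components of the hemodynamic forward model:
#' respiratory and Mayer-wave oscillations, slow linear drift, white
#' measurement noise (which, at a 1 Hz acquisition rate, also stands in for
#' cardiac pulsation aliased from above the Nyquist frequency), sparse
#' motion spikes, a probability of high-variance "bad" channels, and a
#' shared antiphase oscillation planted on one channel pair to emulate
#' negatively correlated network activity.
#'
#' Amplitudes are in umol/l; frequencies in Hz and below the 0.5 Hz Nyquist
#' limit of 1 Hz sampling.
#'
#' @param respiratory_freq,respiratory_amp Breathing oscillation (default
#'   0.25 Hz, 0.05 umol/l).
#' @param mayer_freq,mayer_amp Mayer wave (default 0.1 Hz, 0.08 umol/l).
#' @param drift_slope Linear drift in umol/l per second (default 0.002).
#' @param white_sd White-noise standard deviation in umol/l (default 0.05).
#' @param spike_rate Motion spikes per minute (default 0.5).
#' @param spike_amp Spike amplitude in umol/l (default 1).
#' @param bad_channel_prob Per-channel probability of a high-variance bad
#'   channel (default 0.01, about 10% of subjects discarded at 10
#'   channels).
#' @param anticorr_pair Channel pair carrying the shared antiphase
#'   oscillation (default `c(2, 7)`); `NULL` disables it.
#' @param anticorr_amp,anticorr_freq Amplitude (umol/l) and frequency (Hz) of
#'   the antiphase oscillation (defaults 0.2 and 0.04).
#' @param hbr_task_ratio Ratio r in (0, 1) linking the HbR task response to
#'   the HbO task response as `-r * task` (default 0.3).
#' @param hbr_noise_scale Multiplier on noise amplitudes for HbR (default 0.5).
#'
#' @return An object of class `noise_config` (a named list).
#' @export
noise_config <- function(respiratory_freq = 0.25, respiratory_amp = 0.05,
                         mayer_freq = 0.1, mayer_amp = 0.08,
                         drift_slope = 0.002, white_sd = 0.05,
                         spike_rate = 0.5, spike_amp = 1,
                         bad_channel_prob = 0.01,
                         anticorr_pair = c(2, 7), anticorr_amp = 0.2,
                         anticorr_freq = 0.04,
                         hbr_task_ratio = 0.3, hbr_noise_scale = 0.5) {
  amps <- c(respiratory_amp, mayer_amp, white_sd, spike_amp, anticorr_amp)
  if (any(amps < 0)) stop("Noise amplitudes must be non-negative.", call. = FALSE)
  freqs <- c(respiratory_freq, mayer_freq, anticorr_freq)
  if (any(freqs >= 0.5)) {
    stop("Noise frequencies must be below the Nyquist frequency (0.5 Hz at 1 Hz sampling).",
      call. = FALSE
    )
  }
  if (!(hbr_task_ratio > 0 && hbr_task_ratio < 1)) {
    stop("`hbr_task_ratio` must lie in (0, 1).", call. = FALSE)
  }
  structure(
    list(
      respiratory_freq = respiratory_freq, respiratory_amp = respiratory_amp,
      mayer_freq = mayer_freq, mayer_amp = mayer_amp,
      drift_slope = drift_slope, white_sd = white_sd,
      spike_rate = spike_rate, spike_amp = spike_amp,
      bad_channel_prob = bad_channel_prob,
      anticorr_pair = anticorr_pair, anticorr_amp = anticorr_amp,
      anticorr_freq = anticorr_freq,
      hbr_task_ratio = hbr_task_ratio, hbr_noise_scale = hbr_noise_scale
    ),
    class = "noise_config"
  )
}

#' Noise configuration with every component silenced
#'
#' Convenience constructor for noiseless ground-truth simulations.
#' @return A `noise_config` with all amplitudes, slopes, rates and
#'   probabilities set to zero.
#' @export
noise_config_quiet <- function() {
  noise_config(
    respiratory_amp = 0, mayer_amp = 0, drift_slope = 0, white_sd = 0,
    spike_rate = 0, spike_amp = 0, bad_channel_prob = 0,
    anticorr_pair = NULL, anticorr_amp = 0
  )
}

#' Subject metadata record
#'
#' @param subject_id Subject identifier.
#' @param group `"normal"` or `"ICPP"`.
#' @param gender `"female"` or `"male"`.
#' @param age,education Years.
#' @param true_beta Ground-truth per-channel MA-task amplitude in umol/l.
#' @param markers Named list of clinical markers (`lh_iu_l`, `fsh_iu_l`,
#'   `estradiol_pmol_l`, `testosterone_nmol_l`, `bone_age_years`); only
#'   diagnosed (ICPP) subjects carry archived markers, so it must be `NULL`
#'   for the normal group.
#'
#' @return An object of class `subject_record`.
#' @export
subject_record <- function(subject_id, group = c("normal", "ICPP"),
                           gender = c("female", "male"),
                           age = NA_real_, education = NA_real_,
                           true_beta = numeric(10), markers = NULL) {
  group <- match.arg(group)
  gender <- match.arg(gender)
  if (group == "normal" && !is.null(markers)) {
    stop("Clinical markers are archived only for ICPP subjects.", call. = FALSE)
  }
  structure(
    list(
      subject_id = as.character(subject_id), group = group, gender = gender,
      age = age, education = education, true_beta = as.numeric(true_beta),
      markers = markers
    ),
    class = "subject_record"
  )
}

new_hemo_recording <- function(hbo, hbr, fs, subject_id = NA_character_,
                               provenance = character(), truth = NULL) {
  stopifnot(identical(dim(hbo), dim(hbr)))
  structure(
    list(
      hbo = hbo, hbr = hbr, hbt = hbo + hbr, fs = fs,
      subject_id = subject_id, provenance = provenance, truth = truth
    ),
    class = "hemo_recording"
  )
}

#' @export
print.hemo_recording <- function(x, ...) {
  cat(sprintf(
    "<hemo_recording> %s: %d channels x %d samples at %g Hz; steps: %s\n",
    x$subject_id, nrow(x$hbo), ncol(x$hbo), x$fs,
    if (length(x$provenance)) paste(x$provenance, collapse = " -> ") else "(raw truth)"
  ))
  invisible(x)
}

#' Simulate one subject's ground-truth hemodynamics
#'
#' Builds channel-wise oxy-hemoglobin time courses as the subject's
#' ground-truth task amplitude times the HRF-convolved MA boxcar, plus
#' respiratory and Mayer oscillations (random phase per channel), linear
#' drift, white noise, sparse motion spikes, and the planted antiphase pair
#' oscillation. The deoxy-hemoglobin signal is the negatively scaled task
#' component (ratio `hbr_task_ratio`) plus its own attenuated noise,
#' reproducing the sign inversion seen in task-evoked HbR.
#'
#' @param subject A `subject_record` (its `true_beta` drives the task
#'   response).
#' @param paradigm A `paradigm_spec`.
#' @param noise A `noise_config`.
#' @param hrf An `hrf_kernel`; defaults to `canonical_hrf(paradigm$fs)`.
#' @param seed Integer seed; required, so every simulation is reproducible.
#'
#' @return A `hemo_recording` with channels x time matrices `hbo`, `hbr`,
#'   `hbt` (umol/l) and the ground-truth task component stored in `truth`.
#' @export
simulate_subject <- function(subject, paradigm, noise = noise_config(),
                             hrf = NULL, seed) {
  if (missing(seed) || is.null(seed)) {
    stop("`seed` is required: simulations must be reproducible.", call. = FALSE)
  }
  if (is.null(hrf)) hrf <- canonical_hrf(paradigm$fs)
  n_ch <- length(subject$true_beta)
  n_t <- paradigm$n_samples
  tt <- paradigm_times(paradigm)
  task <- hrf_convolve(paradigm_boxcar(paradigm, "MA"), hrf)

  withr::with_seed(seed, {
    hbo <- matrix(0, n_ch, n_t)
    hbr <- matrix(0, n_ch, n_t)
    task_comp <- outer(subject$true_beta, task)
    for (ch in seq_len(n_ch)) {
      osc <- numeric(n_t)
      if (noise$respiratory_amp > 0) {
        osc <- osc + noise$respiratory_amp *
          sin(2 * pi * noise$respiratory_freq * tt + stats::runif(1, 0, 2 * pi))
      }
      if (noise$mayer_amp > 0) {
        osc <- osc + noise$mayer_amp *
          sin(2 * pi * noise$mayer_freq * tt + stats::runif(1, 0, 2 * pi))
      }
      drift <- noise$drift_slope * tt
      white <- if (noise$white_sd > 0) stats::rnorm(n_t, 0, noise$white_sd) else numeric(n_t)
      spikes <- numeric(n_t)
      if (noise$spike_rate > 0 && noise$spike_amp > 0) {
        n_spk <- stats::rpois(1, noise$spike_rate * n_t / paradigm$fs / 60)
        if (n_spk > 0) {
          at <- sample.int(n_t, min(n_spk, n_t))
          spikes[at] <- noise$spike_amp * sample(c(-1, 1), length(at), replace = TRUE)
        }
      }
      hbo[ch, ] <- task_comp[ch, ] + osc + drift + white + spikes
      hbr[ch, ] <- -noise$hbr_task_ratio * task_comp[ch, ] +
        noise$hbr_noise_scale *
          (if (noise$white_sd > 0) stats::rnorm(n_t, 0, noise$white_sd) else numeric(n_t))
    }
    if (!is.null(noise$anticorr_pair) && noise$anticorr_amp > 0) {
      ij <- noise$anticorr_pair
      s <- noise$anticorr_amp * sin(2 * pi * noise$anticorr_freq * tt + stats::runif(1, 0, 2 * pi))
      hbo[ij[1], ] <- hbo[ij[1], ] + s
      hbo[ij[2], ] <- hbo[ij[2], ] - s
    }
    new_hemo_recording(
      hbo, hbr,
      fs = paradigm$fs, subject_id = subject$subject_id,
      truth = list(task_component = task_comp, true_beta = subject$true_beta)
    )
  })
}

#' Forward-model raw light intensities from hemoglobin signals
#'
#' Applies the modified Beer-Lambert law in the forward direction: the
#' attenuation change at each wavelength is
#' `dA = d * DPF * (eHbO * dHbO + eHbR * dHbR)` (with d in cm and
#' concentrations converted from umol/l to mmol/l so units match the
#' extinction coefficients), and the detected intensity is
#' `I = I0 * 10^(-dA)`. This is the exact inverse of [mbll_convert()] when
#' the baseline intensity is known.
#'
#' @param hemo A `hemo_recording` (umol/l).
#' @param optodes An `optode_config`.
#' @param paradigm The `paradigm_spec` the recording was simulated under.
#' @param subject Optional `subject_record` carried along as metadata.
#'
#' @return An object of class `raw_intensity_recording`: list with
#'   `intensity` (array wavelength x channel x time), `optodes`, `paradigm`,
#'   `subject`.
#' @export
forward_intensity <- function(hemo, optodes = optode_config(), paradigm = NULL,
                              subject = NULL) {
  if (!all(is.finite(hemo$hbo)) || !all(is.finite(hemo$hbr))) {
    stop("Hemoglobin signals must be finite.", call. = FALSE)
  }
  n_ch <- nrow(hemo$hbo)
  stopifnot(n_ch == optodes$n_channels)
  n_t <- ncol(hemo$hbo)
  d_cm <- optodes$distance_mm / 10
  eps <- optodes$extinction
  intensity <- array(NA_real_, dim = c(2, n_ch, n_t))
  for (w in 1:2) {
    # umol/l -> mmol/l to match l.mmol^-1.cm^-1 extinction units
    d_a <- d_cm * optodes$dpf[w] *
      (eps[w, "HbO"] * hemo$hbo + eps[w, "HbR"] * hemo$hbr) / 1000
    intensity[w, , ] <- optodes$baseline_intensity[w, ] * 10^(-d_a)
  }
  structure(
    list(
      intensity = intensity, optodes = optodes, paradigm = paradigm,
      subject = subject, fs = hemo$fs, subject_id = hemo$subject_id
    ),
    class = "raw_intensity_recording"
  )
}

#' @export
print.raw_intensity_recording <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf(
    "<raw_intensity_recording> %s: %d wavelengths x %d channels x %d samples\n",
    x$subject_id %||% "?", d[1], d[2], d[3]
  ))
  invisible(x)
}

#' Group- and gender-specific activation profiles
#'
#' Mean ground-truth MA-task amplitudes (umol/l) per channel for each
#' group x gender cell, emulating the qualitative activation contrasts of a
#' prefrontal MA study: normal children (females especially) show broader
#' and stronger activation, while the ICPP profile is attenuated over the
#' left-hemisphere channels (here channels 1-5).
#'
#' @param n_channels Number of channels (default 10).
#' @return Named list of numeric vectors, one per `"group_gender"` cell.
#' @export
cohort_effects <- function(n_channels = 10) {
  base <- function(v) v[seq_len(n_channels)]
  list(
    normal_female = base(c(0.60, 0.60, 0.55, 0.55, 0.50, 0.50, 0.45, 0.45, 0.40, 0.40)),
    normal_male   = base(c(0.50, 0.50, 0.45, 0.45, 0.45, 0.45, 0.40, 0.40, 0.35, 0.35)),
    ICPP_female   = base(c(0.30, 0.30, 0.30, 0.30, 0.25, 0.45, 0.40, 0.40, 0.35, 0.35)),
    ICPP_male     = base(c(0.40, 0.40, 0.30, 0.40, 0.40, 0.40, 0.25, 0.40, 0.35, 0.35))
  )
}

sample_markers <- function(gender) {
  clamp <- function(x, lo) pmax(x, lo)
  m <- list(
    bone_age_years = clamp(stats::rnorm(1, 12.27, 1.88), 6),
    lh_iu_l = clamp(stats::rnorm(1, 4.81, 3.47), 0.1),
    fsh_iu_l = clamp(stats::rnorm(1, 4.76, 2.30), 0.1)
  )
  if (gender == "female") {
    m$estradiol_pmol_l <- clamp(stats::rnorm(1, 118.58, 98.32), 5)
  } else {
    m$testosterone_nmol_l <- clamp(stats::rnorm(1, 12.75, 4.69), 0.5)
  }
  m
}

#' Simulate a full cohort of raw-intensity recordings
#'
#' Draws per-subject ground-truth activation amplitudes from group- and
#' gender-specific distributions, simulates each subject's hemodynamics,
#' forward-models raw dual-wavelength intensities, and injects occasional
#' high-variance bad channels. Demographics are drawn from truncated
#' Gaussians around the study-population summary values (age ~10.7 +/- 2.5
#' years; education ~4.8 +/- 2.4 years; clinical markers for ICPP subjects
#' only). The default cell sizes mirror the study cohort (57/28 normal and
#' 54/28 ICPP females/males).
#'
#' @param n_per_group Named list of cell sizes:
#'   `list(normal = c(female =, male =), ICPP = c(female =, male =))`.
#' @param effects Per-cell mean activation profiles as from
#'   [cohort_effects()].
#' @param between_sd Between-subject SD of the per-channel amplitudes
#'   (umol/l, default 0.15).
#' @param noise A `noise_config`.
#' @param paradigm A `paradigm_spec`.
#' @param optodes An `optode_config`.
#' @param seed Integer seed (required).
#'
#' @return An object of class `nirs_cohort`: list with `recordings` (list of
#'   `raw_intensity_recording`), `subjects` (metadata tibble), `paradigm`,
#'   `optodes`, `noise`, `seed`.
#' @export
sample_cohort <- function(n_per_group = list(
                            normal = c(female = 57, male = 28),
                            ICPP = c(female = 54, male = 28)
                          ),
                          effects = cohort_effects(),
                          between_sd = 0.15,
                          noise = noise_config(),
                          paradigm = build_paradigm(),
                          optodes = optode_config(),
                          seed) {
  if (missing(seed) || is.null(seed)) {
    stop("`seed` is required: simulations must be reproducible.", call. = FALSE)
  }
  sizes <- unlist(n_per_group)
  if (length(sizes) == 0 || sum(sizes) < 1) {
    stop("Cohort must contain at least one subject.", call. = FALSE)
  }
  n_ch <- optodes$n_channels

  withr::with_seed(seed, {
    recordings <- list()
    meta <- list()
    idx <- 0
    for (group in names(n_per_group)) {
      for (gender in names(n_per_group[[group]])) {
        n_cell <- n_per_group[[group]][[gender]]
        cell <- paste(group, gender, sep = "_")
        mu <- effects[[cell]]
        if (is.null(mu)) stop(sprintf("No effect profile for cell '%s'.", cell), call. = FALSE)
        for (i in seq_len(n_cell)) {
          idx <- idx + 1
          beta <- stats::rnorm(n_ch, mu, between_sd)
          markers <- if (group == "ICPP") sample_markers(gender) else NULL
          if (group == "ICPP") {
            age <- min(max(stats::rnorm(1, 10.90, 2.37), 5), 16)
            edu <- min(max(stats::rnorm(1, 4.91, 2.32), 0), 12)
          } else {
            age <- min(max(stats::rnorm(1, 10.67, 2.51), 5), 16)
            edu <- min(max(stats::rnorm(1, 4.71, 2.48), 0), 12)
          }
          subj <- subject_record(
            subject_id = sprintf("S%03d", idx), group = group, gender = gender,
            age = age, education = edu, true_beta = beta, markers = markers
          )
          hemo <- simulate_subject(subj, paradigm, noise,
            seed = stats::runif(1, 1, 2^31 - 2)
          )
          raw <- forward_intensity(hemo, optodes, paradigm, subj)
          bad <- stats::runif(n_ch) < noise$bad_channel_prob
          if (any(bad)) {
            n_t <- dim(raw$intensity)[3]
            for (ch in which(bad)) {
              jitter <- exp(stats::rnorm(n_t, 0, 0.25))
              raw$intensity[1, ch, ] <- raw$intensity[1, ch, ] * jitter
              raw$intensity[2, ch, ] <- raw$intensity[2, ch, ] * jitter
            }
          }
          raw$bad_channels_injected <- which(bad)
          recordings[[idx]] <- raw
          meta[[idx]] <- tibble::tibble(
            subject_id = subj$subject_id, group = group, gender = gender,
            age = age, education = edu,
            bone_age_years = markers$bone_age_years %||% NA_real_,
            lh_iu_l = markers$lh_iu_l %||% NA_real_,
            fsh_iu_l = markers$fsh_iu_l %||% NA_real_,
            estradiol_pmol_l = markers$estradiol_pmol_l %||% NA_real_,
            testosterone_nmol_l = markers$testosterone_nmol_l %||% NA_real_
          )
        }
      }
    }
    structure(
      list(
        recordings = recordings,
        subjects = dplyr::bind_rows(meta),
        paradigm = paradigm, optodes = optodes, noise = noise, seed = seed
      ),
      class = "nirs_cohort"
    )
  })
}

#' @export
print.nirs_cohort <- function(x, ...) {
  tab <- table(x$subjects$group, x$subjects$gender)
  cat(sprintf("<nirs_cohort> %d subjects (seed %s)\n", nrow(x$subjects), x$seed))
  print(tab)
  invisible(x)
}
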