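test_that("channel CV matches hand computation and is scale invariant", {
  expect_equal(channel_cv(matrix(c(10, 10, 10), 1))$cv, 0)
  # sd([8,12,8,12]) = 2.3094 (ddof 1), mean 10 -> 23.094%
  x <- matrix(c(8, 12, 8, 12), 1)
  expect_equal(channel_cv(x)$cv, sd(c(8, 12, 8, 12)) / 10 * 100)
  expect_equal(channel_cv(x)$cv, 23.094, tolerance = 1e-4)
  expect_equal(channel_cv(5 * x)$cv, channel_cv(x)$cv)
  expect_error(channel_cv(matrix(c(-1, 1), 1)), "mean")
  expect_error(channel_cv(matrix(1, 1, 1)), "2 samples")
})

test_that("QC discards subjects on strict CV threshold exceedance", {
  rec <- quiet_recording()
  expect_false(qc_screen(rec)$subject_discarded)

  # inflate one channel's variance past 15%
  bad <- rec
  n_t <- dim(bad$intensity)[3]
  withr::with_seed(1, {
    bad$intensity[1, 4, ] <- bad$intensity[1, 4, ] * exp(rnorm(n_t, 0, 0.25))
  })
  q <- qc_screen(bad)
  expect_true(q$subject_discarded)
  expect_true(4 %in% q$bad_channels)

  # a channel at exactly the threshold is kept ("exceeding" is strict)
  m <- matrix(c(10, 10), 1)
  expect_false(qc_screen(structure(
    list(intensity = array(rep(c(8, 12, 8, 12), 2), c(2, 1, 4)), subject_id = "x"),
    class = "raw_intensity_recording"
  ), threshold = channel_cv(matrix(c(8, 12, 8, 12), 1))$cv)$subject_discarded)
})

test_that("MBLL with known baseline inverts the forward model to precision", {
  p <- build_paradigm()
  withr::with_seed(10, {
    beta <- runif(10, 0.2, 1)
  })
  h <- simulate_subject(quiet_subject(beta), p, noise_config(), seed = 6)
  raw <- forward_intensity(h, optode_config(), p)
  back <- mbll_convert(raw, i0 = "stored")
  expect_lt(max(abs(back$hbo - h$hbo)), 1e-9)
  expect_lt(max(abs(back$hbr - h$hbr)), 1e-9)
  expect_equal(back$hbt, back$hbo + back$hbr)
})

test_that("mean-referenced MBLL recovers signals up to a per-channel offset", {
  p <- build_paradigm()
  h <- simulate_subject(quiet_subject(rep(0.8, 10)), p, noise_config(), seed = 12)
  raw <- forward_intensity(h, optode_config(), p)
  back <- mbll_convert(raw, i0 = "mean")
  resid <- back$hbo - h$hbo
  # each channel's residual is a constant shift
  expect_lt(max(apply(resid, 1, function(r) diff(range(r)))), 1e-6)
})

test_that("MBLL refuses non-positive intensities and I0 yields zero signals", {
  rec <- quiet_recording(beta = rep(0, 10))
  h <- mbll_convert(rec, i0 = "stored")
  expect_true(all(h$hbo == 0))
  rec$intensity[1, 1, 5] <- 0
  expect_error(mbll_convert(rec), "positive")
})

test_that("polynomial detrending removes trends and zero-means the output", {
  tt <- 0:99
  line <- 2 + 0.3 * tt
  expect_lt(max(abs(detrend_poly(line, 1))), 1e-10)

  sine <- sin(2 * pi * 0.1 * tt)
  out <- detrend_poly(sine + line, 1)
  expect_gt(cor(out, sine), 0.99)
  expect_lt(abs(mean(out)), 1e-12)
  expect_error(detrend_poly(sine, -1), "order")
})

test_that("zero-phase Butterworth has unit DC gain, a sharp stopband, and is linear", {
  tt <- 0:2047
  dc <- rep(3, 2048)
  expect_equal(lowpass_filter(dc), dc, tolerance = 1e-9)

  mid <- 500:1500
  fast <- sin(2 * pi * 0.2 * tt)
  gain_fast <- sd(lowpass_filter(fast)[mid]) / sd(fast[mid])
  expect_lt(gain_fast, 0.02) # analog two-pass bound 1/(1+2^6) ~ 0.0154

  slow <- sin(2 * pi * 0.02 * tt)
  gain_slow <- sd(lowpass_filter(slow)[mid]) / sd(slow[mid])
  expect_equal(gain_slow, 1, tolerance = 0.02)

  withr::with_seed(2, {
    x <- rnorm(256)
    y <- rnorm(256)
  })
  expect_equal(
    lowpass_filter(2 * x - 3 * y),
    2 * lowpass_filter(x) - 3 * lowpass_filter(y),
    tolerance = 1e-10
  )
  expect_error(lowpass_filter(x, cutoff = 0.5), "Nyquist")
})

test_that("TDDR removes gross spikes, spares clean signals, fixes constants", {
  p <- build_paradigm()
  hrf <- canonical_hrf(1)
  clean <- 0.6 * nirsicpp:::hrf_convolve(paradigm_boxcar(p, "MA"), hrf)

  out <- tddr_correct(clean)
  expect_lt(sqrt(mean((out - clean)^2)) / sqrt(mean(clean^2)), 0.05)

  spike_amp <- 10 * max(abs(clean))
  spiky <- clean
  spiky[60] <- spiky[60] + spike_amp
  fixed <- tddr_correct(spiky)
  expect_gt(1 - abs(fixed[60] - clean[60]) / spike_amp, 0.9)

  expect_equal(tddr_correct(rep(3, 50)), rep(3, 50))
  expect_error(tddr_correct(c(1, NA, 3)), "finite")
})

test_that("TDDR reduces the derivative kurtosis of spiky signals", {
  withr::with_seed(5, {
    x <- cumsum(rnorm(200, 0, 0.05))
    x[c(50, 120)] <- x[c(50, 120)] + 3
  })
  k_before <- e1071::kurtosis(diff(x), type = 1)
  k_after <- e1071::kurtosis(diff(tddr_correct(x)), type = 1)
  expect_lt(k_after, k_before)
})

test_that("the full chain records provenance and recovers the task signal", {
  p <- build_paradigm()
  withr::with_seed(21, beta <- runif(10, 0.3, 0.8))
  h <- simulate_subject(quiet_subject(beta), p, noise_config(), seed = 31)
  raw <- forward_intensity(h, optode_config(), p)
  pp <- run_preprocess(raw)
  expect_length(pp$provenance, 4)
  expect_match(pp$provenance[1], "mbll")
  expect_match(pp$provenance[4], "tddr")
  cors <- vapply(
    1:10,
    function(ch) cor(pp$hbo[ch, ], h$truth$task_component[ch, ]), 0
  )
  expect_true(all(cors > 0.9))
  expect_equal(pp$hbt, pp$hbo + pp$hbr)
})

test_that("preprocessing refuses subjects that failed QC", {
  rec <- quiet_recording()
  n_t <- dim(rec$intensity)[3]
  withr::with_seed(1, {
    rec$intensity[1, 2, ] <- rec$intensity[1, 2, ] * exp(rnorm(n_t, 0, 0.3))
  })
  expect_error(run_preprocess(rec), "QC")
})

test_that("noiseless pipeline recovers amplitudes with < 5% relative bias", {
  p <- build_paradigm()
  withr::with_seed(33, beta <- runif(10, 0.3, 0.9))
  h <- simulate_subject(quiet_subject(beta), p, noise_config_quiet(), seed = 3)
  raw <- forward_intensity(h, optode_config(), p)
  pp <- run_preprocess(raw)
  g <- fit_glm(pp, build_design(p))
  rel_bias <- (g$beta[, "MA"] - beta) / beta
  expect_true(all(abs(rel_bias) < 0.05))
})
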