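test_that("trial segmentation yields 60-s MA+rest windows starting at MA onset", {
  p <- build_paradigm()
  h <- simulate_subject(quiet_subject(rep(1, 10)), p, noise_config_quiet(), seed = 1)
  segs <- segment_trials(h, p)
  expect_length(segs, 2)
  expect_equal(dim(segs[[1]]$data), c(10, 60))
  # segment 1 starts at the first MA onset (t = 2 s -> sample index 3)
  expect_equal(segs[[1]]$data[1, 1], h$hbo[1, 3])

  p3 <- build_paradigm(3)
  h3 <- simulate_subject(quiet_subject(rep(1, 10)), p3, noise_config_quiet(), seed = 1)
  expect_length(segment_trials(h3, p3), 3)

  expect_error(segment_trials(h, p3), "match")
})

test_that("planted anticorrelated channels dominate pair selection", {
  withr::with_seed(90, {
    segs <- lapply(1:6, function(i) {
      base <- matrix(rnorm(10 * 60, 0, 0.2), 10, 60)
      s <- sin(2 * pi * 0.05 * (0:59) + runif(1, 0, 2 * pi))
      base[2, ] <- s + rnorm(60, 0, 0.05)
      base[7, ] <- -s + rnorm(60, 0, 0.05)
      make_segment(base, paste0("s", i))
    })
  })
  pair <- select_negative_pair(segs)
  expect_equal(pair$pair, c(2, 7))
  expect_lt(pair$mean_correlation, -0.8)

  expect_equal(select_negative_pair(segs[1])$pair, c(2, 7))
})

test_that("pair selection is near-uniform under independence", {
  withr::with_seed(91, {
    segs <- lapply(1:100, function(i) make_segment(matrix(rnorm(6 * 60), 6, 60)))
  })
  pair <- select_negative_pair(segs)
  # 15 candidate pairs -> expected frequency ~ 100/15; winner must not
  # exceed 3x that
  expect_lt(pair$frequency, 3 * 100 / 15)
})

test_that("constant channels are excluded from pair candidacy with a warning", {
  withr::with_seed(92, m <- matrix(rnorm(5 * 60), 5, 60))
  m[3, ] <- 2
  expect_warning(pair <- select_negative_pair(list(make_segment(m))), "Constant")
  expect_false(3 %in% pair$pair)
})

test_that("time-domain statistics match hand values and conventions", {
  st <- timedomain_stats(c(1, 2, 3, 4))
  expect_equal(st$mean, 2.5)
  expect_equal(st$variance, 5 / 3, tolerance = 1e-12)
  expect_equal(st$skewness, 0)

  const <- timedomain_stats(rep(2, 10))
  expect_equal(const$variance, 0)
  expect_true(const$degenerate)

  withr::with_seed(93, z <- rnorm(1e5))
  expect_equal(timedomain_stats(z)$kurtosis, 0, tolerance = 0.1)
})

test_that("per-channel PCA matches a direct eigendecomposition oracle", {
  withr::with_seed(94, {
    segs <- lapply(1:12, function(i) make_segment(matrix(rnorm(3 * 20), 3, 20)))
  })
  fit <- channel_pca(segs, channel = 2, k = 3)
  expect_equal(unname(crossprod(fit$rotation)), diag(3), tolerance = 1e-10)

  X <- do.call(rbind, lapply(segs, function(s) s$data[2, ]))
  Xc <- scale(X, center = TRUE, scale = FALSE)
  eig <- eigen(crossprod(Xc) / (nrow(Xc) - 1), symmetric = TRUE)
  # scores agree with the projection on the leading eigenvectors up to sign
  for (k in 1:3) {
    sc_oracle <- Xc %*% eig$vectors[, k]
    expect_equal(abs(as.numeric(cor(fit$scores[, k], sc_oracle))), 1,
                 tolerance = 1e-8)
  }

  # rank-1 trials: PC1 carries all the variance
  wave <- sin(2 * pi * 0.1 * (0:19))
  withr::with_seed(95, {
    segs1 <- lapply(1:8, function(i) make_segment(rbind(runif(1) * wave,
                                                        matrix(0, 2, 20))))
  })
  f1 <- channel_pca(segs1, 1, k = 1)
  expect_equal(f1$sdev[1]^2 / sum(f1$sdev^2), 1, tolerance = 1e-10)
})

test_that("EMD is complete, separates tones, and skips monotone input", {
  withr::with_seed(96, x <- cumsum(rnorm(128)))
  dec <- emd_decompose(x)
  recon <- colSums(rbind(dec$imfs, dec$residue))
  expect_lt(max(abs(recon - x)) / max(abs(x)), 1e-10)

  tt <- 0:511
  two <- sin(2 * pi * 0.4 * tt) + sin(2 * pi * 0.05 * tt)
  d2 <- emd_decompose(two)
  expect_gt(d2$n_imfs, 1)
  expect_gt(abs(cor(d2$imfs[1, ], sin(2 * pi * 0.4 * tt))), 0.9)

  ramp <- emd_decompose(seq(0, 1, length.out = 64))
  expect_equal(ramp$n_imfs, 0)
  expect_equal(ramp$residue, seq(0, 1, length.out = 64))

  expect_error(emd_decompose(1:5), "8 samples")
})

test_that("feature families produce the documented schemas", {
  p <- build_paradigm()
  withr::with_seed(97, {
    segs <- unlist(lapply(1:6, function(i) {
      beta <- runif(10, 0.3, 0.8)
      h <- simulate_subject(quiet_subject(beta, paste0("S", i)), p,
        noise_config(), seed = 100 + i
      )
      segment_trials(h, p, label = i %% 2)
    }), recursive = FALSE)
  })
  st <- fit_feature_state(segs)
  meta_cols <- 4
  expect_equal(ncol(extract_features(segs, "A", st)) - meta_cols, 8)
  expect_equal(ncol(extract_features(segs, "B", st)) - meta_cols, 30)
  expect_equal(ncol(extract_features(segs, "C", st)) - meta_cols, 14)
  expect_equal(ncol(extract_features(segs, "D", st)) - meta_cols, 30)
  expect_equal(ncol(extract_features(segs, "E", st)) - meta_cols, 10)
  expect_error(extract_features(segs, "F", st), "Unknown")

  fa <- extract_features(segs, "A", st)
  pair <- st$pair$pair
  expect_true(all(paste0(
    "ch", rep(pair, each = 4), "_", c("mean", "var", "skew", "kurt")
  ) %in% names(fa)))
  expect_false(anyNA(fa[setdiff(names(fa), "gender")]))
})

test_that("feature E recovers injected amplitudes up to scale on clean data", {
  p <- build_paradigm()
  withr::with_seed(98, beta <- runif(10, 0.2, 1))
  h <- simulate_subject(quiet_subject(beta), p, noise_config_quiet(), seed = 7)
  segs <- segment_trials(h, p, label = 1)
  st <- fit_feature_state(c(segs, segs), sets = "E")
  fe <- extract_features(segs, "E", st)
  est <- as.numeric(fe[1, paste0("ch", 1:10, "_beta")])
  expect_gt(cor(est, beta), 0.99)
})

test_that("applying a fitted state to held-out data never refits", {
  withr::with_seed(99, {
    train <- lapply(1:8, function(i) {
      base <- matrix(rnorm(10 * 60, 0, 0.2), 10, 60)
      s <- sin(2 * pi * 0.05 * (0:59))
      base[2, ] <- s + rnorm(60, 0, 0.05)
      base[7, ] <- -s + rnorm(60, 0, 0.05)
      make_segment(base, paste0("tr", i))
    })
    # held-out data whose dominant negative pair is different (3, 9)
    test <- lapply(1:4, function(i) {
      base <- matrix(rnorm(10 * 60, 0, 0.2), 10, 60)
      s <- sin(2 * pi * 0.05 * (0:59))
      base[3, ] <- s
      base[9, ] <- -s
      make_segment(base, paste0("te", i))
    })
  })
  st <- fit_feature_state(train, sets = c("A", "B"))
  snapshot <- st
  ft <- extract_features(test, "A", st)
  # the training pair (2,7) is applied unchanged to the held-out set
  expect_true(all(c("ch2_mean", "ch7_mean") %in% names(ft)))
  expect_false(any(c("ch3_mean", "ch9_mean") %in% names(ft)))
  expect_identical(st$pair$pair, snapshot$pair$pair)
  expect_identical(st$pca[[1]]$rotation, snapshot$pca[[1]]$rotation)
})
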