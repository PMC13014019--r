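test_that("canonical HRF is peak-normalized with a physiological peak time", {
  h <- canonical_hrf(fs = 1)
  expect_equal(max(h$values), 1)
  peak_t <- h$times_s[which.max(h$values)]
  expect_gte(peak_t, 4)
  expect_lte(peak_t, 8)
  expect_equal(h$values[1], 0)
})

test_that("design matrix has the expected shape and disjoint regressor support", {
  p <- build_paradigm()
  d <- build_design(p)
  expect_equal(dim(d$X), c(128, 3))
  expect_equal(colnames(d$X), c("intercept", "MA", "rest"))

  d2 <- build_design(p, include_rest = FALSE)
  expect_equal(dim(d2$X), c(128, 2))

  expect_true(all(paradigm_boxcar(p, "MA") * paradigm_boxcar(p, "rest") == 0))
})

test_that("OLS recovers exact coefficients and obeys the normal equations", {
  p <- build_paradigm()
  d <- build_design(p, match_preprocess = FALSE)
  y <- t(d$X %*% c(0.5, 2, 1))
  g <- fit_glm(y, d)
  expect_equal(unname(g$beta[1, ]), c(0.5, 2, 1), tolerance = 1e-12)
  expect_lt(max(abs(g$residuals %*% d$X)), 1e-9)

  # rank-deficient design is named
  d_bad <- d
  d_bad$X <- cbind(d$X, MA2 = d$X[, "MA"])
  expect_error(fit_glm(y, d_bad), "rank deficient")
})

test_that("OLS amplitude estimates are unbiased under white noise", {
  p <- build_paradigm()
  d <- build_design(p, match_preprocess = FALSE)
  withr::with_seed(40, {
    est <- vapply(seq_len(200), function(i) {
      fit_glm(matrix(rnorm(128), 1), d)$beta[, "MA"]
    }, 0)
  })
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est)), 2 * se + 1e-8)
})

test_that("assumption checks behave on Gaussian, identical and heavy-tailed input", {
  withr::with_seed(50, x <- matrix(rnorm(500), 250, 2))
  chk <- assumption_checks(x)
  expect_true(all(chk$shapiro$W > 0.98))
  expect_true(all(chk$shapiro$p.value > 0.05))

  both <- rbind(x, x)
  grp <- rep(c("a", "b"), each = 250)
  lev <- assumption_checks(both, grp)$levene
  expect_true(all(abs(lev$statistic) < 1e-10))

  withr::with_seed(51, {
    hits <- vapply(seq_len(100), function(i) {
      stats::shapiro.test(rcauchy(200))$p.value < 0.05
    }, TRUE)
  })
  expect_gt(mean(hits), 0.9)
})

test_that("BH adjustment matches the brute-force step-up definition", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")

  withr::with_seed(60, p6 <- runif(6))
  perms <- rbind(p6, rev(p6), sample(p6), sample(p6), sample(p6))
  for (i in seq_len(nrow(perms))) {
    expect_equal(fdr_adjust(perms[i, ]), brute_force_bh(perms[i, ]))
  }
  expect_true(all(fdr_adjust(p6) >= p6))
})

test_that("paired t map matches the textbook closed form and handles degeneracy", {
  a <- matrix(c(1, 2, 4), 3, 1)
  b <- matrix(c(0.5, 1, 2), 3, 1)
  m <- paired_t_map(a, b)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(3))
  expect_equal(m$t, t_hand, tolerance = 1e-12)

  # constant shift with zero difference variance is an explicit error, not NaN
  same <- matrix(rnorm(12), 4, 3)
  expect_error(paired_t_map(same + 0.5, same), "zero variance")
  expect_error(paired_t_map(a[1, , drop = FALSE], b[1, , drop = FALSE]), "2 subjects")
})

test_that("mean-zero paired differences give t = 0 everywhere", {
  withr::with_seed(61, base <- matrix(rnorm(40), 4, 10))
  diffs <- matrix(c(-1, 1, -0.5, 0.5), 4, 10) # exactly balanced
  m <- paired_t_map(base + diffs, base)
  expect_true(all(abs(m$t) < 1e-12))
  expect_true(all(m$p.value > 0.999))
})

test_that("two-sample t map matches the pooled-variance closed form", {
  xa <- matrix(c(1, 2, 3), 3, 1)
  xb <- matrix(c(2, 4, 6), 3, 1)
  m <- group_t_map(xa, xb)
  sp2 <- (2 * var(xa) + 2 * var(xb)) / 4
  t_hand <- (mean(xa) - mean(xb)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(m$t, as.numeric(t_hand), tolerance = 1e-12)

  # identical groups: zero mean difference, t = 0 on every channel
  withr::with_seed(63, x <- matrix(rnorm(40), 4, 10))
  m0 <- group_t_map(x, x)
  expect_true(all(m0$t == 0))
  expect_true(all(m0$p.value == 1))
})

test_that("a group effect confined to one channel localizes there", {
  withr::with_seed(62, {
    flags <- replicate(20, {
      a <- matrix(rnorm(30 * 10), 30, 10)
      b <- matrix(rnorm(30 * 10), 30, 10)
      b[, 5] <- b[, 5] + 1.2
      m <- group_t_map(a, b)
      m$significant
    })
  })
  hit5 <- mean(flags[5, ])
  other <- mean(flags[-5, ])
  expect_gt(hit5, 0.8)
  expect_lt(other, 0.1)
})

test_that("marker correlation reproduces exact and null relationships", {
  withr::with_seed(70, b <- rnorm(30))
  expect_equal(marker_correlation(b, 2 * b + 1)$r, 1)
  expect_equal(marker_correlation(b, -b)$r, -1)
  expect_error(marker_correlation(b, rep(1, 30)), "zero variance")
  expect_error(marker_correlation(b[1:2], b[1:2]), "3 paired")

  withr::with_seed(71, {
    rs <- vapply(seq_len(1000), function(i) {
      marker_correlation(rnorm(30), rnorm(30))$r
    }, 0)
  })
  expect_lt(abs(mean(rs)), 0.02)
})

test_that("sample-size calculation reproduces both printed answers", {
  exact <- required_sample_size(0.80, 0.05, 0.5, "noncentral_t")
  expect_equal(exact$n_per_group, 64L)
  expect_equal(exact$n_total, 128L)
  expect_gte(exact$achieved_power, 0.80)

  approx <- required_sample_size(0.80, 0.05, 0.5, "normal_approx")
  expect_equal(approx$n_per_group, 63L)

  # independent oracle: stats::power.t.test solves the same equation
  oracle <- ceiling(stats::power.t.test(
    delta = 0.5, sd = 1, sig.level = 0.05, power = 0.80
  )$n)
  expect_equal(exact$n_per_group, as.integer(oracle))

  # n scales as 1/d^2 in the normal approximation
  expect_equal(
    required_sample_size(0.80, 0.05, 1, "normal_approx")$n_per_group,
    ceiling(2 * (qnorm(0.975) + qnorm(0.8))^2)
  )
  expect_error(required_sample_size(d = 0), "infinite|positive")
})

test_that("GLM confidence intervals achieve near-nominal coverage", {
  p <- build_paradigm()
  d <- build_design(p, match_preprocess = FALSE)
  beta_true <- 0.5
  withr::with_seed(80, {
    cover <- vapply(seq_len(300), function(i) {
      y <- matrix(as.numeric(d$X %*% c(0, beta_true, 0)) + rnorm(128, 0, 0.4), 1)
      td <- tidy(fit_glm(y, d))
      row <- td[td$term == "MA", ]
      row$conf.low <= beta_true && beta_true <= row$conf.high
    }, TRUE)
  })
  expect_gte(mean(cover), 0.91)
  expect_lte(mean(cover), 0.99)
})
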