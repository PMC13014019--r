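test_that("the noise schedule obeys its invariants for arbitrary valid bounds", {
  sch <- make_schedule()
  expect_equal(sch$beta[1], 0.001)
  expect_equal(sch$beta[200], 0.02)
  expect_true(all(diff(sch$beta) > 0))
  expect_true(all(sch$beta > 0 & sch$beta < 1))
  expect_true(all(diff(sch$alpha_bar) < 0))
  # direct-product oracle
  expect_equal(sch$alpha_bar[200], prod(1 - seq(0.001, 0.02, length.out = 200)))

  withr::with_seed(30, {
    for (i in 1:5) {
      b0 <- runif(1, 1e-4, 0.01)
      b1 <- runif(1, b0, 0.5)
      s <- make_schedule(sample(2:300, 1), b0, b1)
      expect_true(all(diff(s$beta) >= 0))
      expect_true(all(diff(s$alpha_bar) < 0))
    }
  })

  s1 <- make_schedule(1, 0.003, 0.02)
  expect_equal(s1$beta, 0.003)
  expect_error(make_schedule(10, 0.02, 0.001), "beta_start")
  expect_error(make_schedule(10, 0, 0.02), "beta_start")
})

test_that("closed-form forward diffusion matches its algebra and marginals", {
  sch <- make_schedule()
  withr::with_seed(31, {
    eps <- matrix(rnorm(600), 10, 60)
  })
  # f0 = 0 reduces to pure scaled noise
  expect_equal(
    forward_diffuse(matrix(0, 10, 60), 150, eps, sch),
    sqrt(1 - sch$alpha_bar[150]) * eps
  )
  # t = 1 is a < 5% perturbation of unit-scale data
  f0 <- matrix(1, 10, 60)
  f1 <- forward_diffuse(f0, 1, eps, sch)
  expect_lt(max(abs(f1 - f0)) / max(abs(f0)), 0.05 * max(abs(eps)) + 0.05)
  expect_error(forward_diffuse(f0, 0, eps, sch), "out of")
  expect_error(forward_diffuse(f0, 201, eps, sch), "out of")
})

test_that("closed-form marginal matches iterated single-step noising", {
  sch <- make_schedule()
  n_draw <- 10000
  withr::with_seed(32, {
    f0 <- 1.3 # unit-scale scalar signal, exact moments known
    for (t in c(10, 100, 200)) {
      ab <- sch$alpha_bar[t]
      # iterated single-step noising: x_s = sqrt(alpha_s) x_{s-1} + sqrt(beta_s) z
      x <- rep(f0, n_draw)
      for (s in seq_len(t)) {
        x <- sqrt(sch$alpha[s]) * x + sqrt(sch$beta[s]) * rnorm(n_draw)
      }
      closed <- forward_diffuse(rep(f0, n_draw), t, rnorm(n_draw), sch)
      se_mean <- sqrt(1 - ab) / sqrt(n_draw)
      expect_lt(abs(mean(x) - mean(closed)), 3 * se_mean * sqrt(2))
      se_var <- (1 - ab) * sqrt(2 / n_draw)
      expect_lt(abs(var(x) - var(closed)), 3 * se_var * sqrt(2))
    }
  })
})

test_that("the ancestral step inverts known noise as alpha_bar approaches 1", {
  sch <- make_schedule()
  withr::with_seed(33, {
    f0 <- rnorm(600)
    eps <- rnorm(600)
  })
  oracle <- list(schedule = sch, trained = TRUE)
  errs <- vapply(c(1, 5, 20, 80), function(t) {
    oracle$eps_fn <- function(ft, tstep, cond) matrix(eps, ncol = 1)
    ft <- forward_diffuse(f0, t, eps, sch)
    prev <- denoise_step(ft, t, condition = NULL, state = oracle,
                         z = matrix(0, 600, 1))
    # one exact step from t to t-1 lands on the forward trajectory of f0,
    # up to the remaining noise (1 - abar_t - beta_t) term
    ab_prev <- if (t == 1) 1 else sch$alpha_bar[t - 1]
    mean(abs(prev - sqrt(ab_prev) * f0))
  }, 0)
  # residual noise shrinks as t -> 1 (alpha_bar -> 1)
  expect_true(all(diff(errs) > 0))
  expect_lt(errs[1], 0.05)
})

test_that("training reduces the loss on a learnable toy problem", {
  segs <- make_toy_segments(n_per_class = 16, seed = 44)
  labs <- vapply(segs, function(s) as.numeric(s$label), 0)
  st <- train_cddpm(segs, labs, epochs = 60, batch_size = 16, seed = 1)
  ll <- st$training_log$loss
  expect_lt(ll[length(ll)], 0.2 * ll[1])
  # smoothed early-epoch trend is decreasing
  k <- max(2, floor(length(ll) * 0.2))
  expect_lt(mean(ll[seq_len(k) + 2]), mean(ll[seq_len(k)]) + 1e-9)
})

test_that("training is deterministic under a fixed seed and inert at lr = 0", {
  segs <- make_toy_segments(n_per_class = 8, seed = 45)
  labs <- vapply(segs, function(s) as.numeric(s$label), 0)
  a <- train_cddpm(segs, labs, epochs = 15, batch_size = 8, seed = 7)
  b <- train_cddpm(segs, labs, epochs = 15, batch_size = 8, seed = 7)
  expect_identical(a$training_log, b$training_log)
  expect_identical(a$par, b$par)

  frozen <- train_cddpm(segs, labs, epochs = 30, batch_size = 8, lr = 0, seed = 7)
  ll <- frozen$training_log$loss
  # no optimization: no systematic trend beyond minibatch fluctuation
  expect_lt(abs(mean(ll[21:30]) - mean(ll[1:10])), 0.3 * mean(ll[1:10]))
})

test_that("sampling respects shape, count, class validity and determinism", {
  segs <- make_toy_segments(n_per_class = 8, seed = 46)
  labs <- vapply(segs, function(s) as.numeric(s$label), 0)
  st <- train_cddpm(segs, labs, epochs = 20, batch_size = 8, seed = 2)
  expect_length(sample_cddpm(st, 0, 1, seed = 1), 0)
  out <- sample_cddpm(st, 3, 1, seed = 5)
  expect_length(out, 3)
  expect_equal(dim(out[[1]]$data), c(10, 60))
  expect_true(out[[1]]$synthetic)
  out2 <- sample_cddpm(st, 3, 1, seed = 5)
  expect_identical(out[[1]]$data, out2[[1]]$data)
  expect_error(sample_cddpm(st, 2, 3, seed = 1), "Unknown class")
})

test_that("augmentation doubles the training set and never touches the test set", {
  segs <- make_toy_segments(n_per_class = 10, seed = 47)
  labs <- vapply(segs, function(s) as.numeric(s$label), 0)
  train <- segs[1:16]
  test <- segs[17:20]
  st <- train_cddpm(train, labs[1:16], epochs = 15, batch_size = 8, seed = 3)
  test_hash_before <- digest_segments(test)
  aug <- augment_train_set(train, st, seed = 9)
  expect_length(aug$segments, 2 * length(train))
  expect_equal(sum(aug$synthetic), length(train))
  expect_equal(sum(aug$labels == 1), 2 * sum(labs[1:16] == 1))
  expect_identical(digest_segments(test), test_hash_before)
  expect_error(check_no_leakage(st, train[1]), "Leakage")
  expect_silent(check_no_leakage(st, test))
})
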