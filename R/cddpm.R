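#' Linear diffusion noise schedule
#'
#' Variance schedule of the forward diffusion process: `beta_t` on a linear
#' grid from `beta_start` to `beta_end` over `T` timesteps, with
#' `alpha_t = 1 - beta_t` and `alpha_bar_t` the running product. Defaults
#' follow the standard configuration for short physiological time series:
#' 200 steps from 0.001 to 0.02.
#'
#' @param n_steps Number of diffusion timesteps T (default 200).
#' @param beta_start,beta_end Schedule endpoints, `0 < beta_start <=
#'   beta_end < 1`.
#' @return Object of class `noise_schedule`: list with `beta`, `alpha`,
#'   `alpha_bar`, `n_steps`.
#' @examples
#' sch <- make_schedule()
#' sch$alpha_bar[200] # ~ 0.121
#' @export
make_schedule <- function(n_steps = 200, beta_start = 0.001, beta_end = 0.02) {
  if (!(beta_start > 0 && beta_start <= beta_end && beta_end < 1)) {
    stop("Require 0 < beta_start <= beta_end < 1.", call. = FALSE)
  }
  if (n_steps < 1) stop("Need at least one timestep.", call. = FALSE)
  beta <- if (n_steps == 1) beta_start else seq(beta_start, beta_end, length.out = n_steps)
  alpha <- 1 - beta
  structure(
    list(beta = beta, alpha = alpha, alpha_bar = cumprod(alpha),
         n_steps = as.integer(n_steps)),
    class = "noise_schedule"
  )
}

#' Closed-form forward diffusion
#'
#' Jumps directly to timestep `t`:
#' `f_t = sqrt(alpha_bar_t) * f0 + sqrt(1 - alpha_bar_t) * eps`, which
#' equals the composition of `t` single-step Gaussian noisings in
#' distribution.
#'
#' @param f0 Clean signal (vector or matrix).
#' @param t Timestep in `1..n_steps`.
#' @param eps Noise of the same shape as `f0` (standard normal draws).
#' @param schedule A `noise_schedule`.
#' @return Noised signal, same shape as `f0`.
#' @export
forward_diffuse <- function(f0, t, eps, schedule) {
  if (t < 1 || t > schedule$n_steps) stop("`t` out of schedule range.", call. = FALSE)
  ab <- schedule$alpha_bar[t]
  sqrt(ab) * f0 + sqrt(1 - ab) * eps
}

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

# Sinusoidal timestep embedding plus the schedule coefficients the
# denoiser needs directly (sqrt(alpha_bar), sqrt(1 - alpha_bar)).
# Columns = samples.
time_embedding <- function(t, dim, schedule) {
  half <- dim %/% 2
  n_steps <- schedule$n_steps
  freqs <- exp(-log(1000) * (seq_len(half) - 1) / max(half - 1, 1))
  ang <- outer(freqs, t / n_steps * 2 * pi * n_steps / 10) # spread phases
  ab <- schedule$alpha_bar[t]
  rbind(sin(ang), cos(ang), sqrt(ab), sqrt(1 - ab))
}

init_denoiser <- function(d_in, d_out, hidden) {
  rnd <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / (nr + nc))), nr, nc)
  list(
    W1 = rnd(hidden[1], d_in), b1 = numeric(hidden[1]),
    W2 = rnd(hidden[2], hidden[1]), b2 = numeric(hidden[2]),
    W3 = rnd(hidden[1], hidden[2]), b3 = numeric(hidden[1]),
    W4 = rnd(d_out, hidden[1]), b4 = numeric(d_out)
  )
}

# Forward pass of the encoder-bottleneck-decoder denoiser with a skip
# connection from the encoder layer to the decoder layer. Columns of Z are
# samples. Returns prediction and the cached activations for backprop.
denoiser_forward <- function(par, Z) {
  A1 <- par$W1 %*% Z + par$b1
  H1 <- gelu(A1)
  A2 <- par$W2 %*% H1 + par$b2
  H2 <- gelu(A2)
  A3 <- par$W3 %*% H2 + par$b3
  H3 <- gelu(A3) + H1
  Y <- par$W4 %*% H3 + par$b4
  list(Y = Y, Z = Z, A1 = A1, H1 = H1, A2 = A2, H2 = H2, A3 = A3, H3 = H3)
}

denoiser_backward <- function(par, cache, dY) {
  dW4 <- dY %*% t(cache$H3)
  db4 <- rowSums(dY)
  dH3 <- t(par$W4) %*% dY
  dA3 <- dH3 * gelu_grad(cache$A3)
  dW3 <- dA3 %*% t(cache$H2)
  db3 <- rowSums(dA3)
  dH2 <- t(par$W3) %*% dA3
  dA2 <- dH2 * gelu_grad(cache$A2)
  dW2 <- dA2 %*% t(cache$H1)
  db2 <- rowSums(dA2)
  dH1 <- t(par$W2) %*% dA2 + dH3 # skip path
  dA1 <- dH1 * gelu_grad(cache$A1)
  list(
    W1 = dA1 %*% t(cache$Z), b1 = rowSums(dA1),
    W2 = dW2, b2 = db2, W3 = dW3, b3 = db3, W4 = dW4, b4 = db4
  )
}

adamw_step <- function(par, grads, opt, lr, weight_decay, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1
  for (nm in names(par)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    mhat <- opt$m[[nm]] / (1 - beta1^opt$t)
    vhat <- opt$v[[nm]] / (1 - beta2^opt$t)
    par[[nm]] <- par[[nm]] - lr * (mhat / (sqrt(vhat) + eps) + weight_decay * par[[nm]])
  }
  list(par = par, opt = opt)
}

segments_to_matrix <- function(segments) {
  do.call(rbind, lapply(segments, function(s) as.numeric(t(s$data))))
}

# Condition matrix: class one-hot (normal, ICPP) plus standardized
# per-trial GLM amplitudes. Columns = samples when transposed downstream.
build_condition_matrix <- function(labels, beta, beta_center, beta_scale) {
  onehot <- rbind(as.numeric(labels == 0), as.numeric(labels == 1))
  if (is.null(beta)) return(onehot)
  bz <- t(sweep(sweep(beta, 2, beta_center), 2, beta_scale, `/`))
  rbind(onehot, bz)
}

#' Train the conditional denoising diffusion model
#'
#' Learns a conditional noise predictor over flattened hemoglobin trial
#' segments. Segments are standardized per channel on training statistics;
#' at random timesteps the closed-form forward marginal produces noised
#' inputs, and a fully connected encoder-bottleneck-decoder network with a
#' skip connection predicts the injected noise from the noised segment, a
#' sinusoidal timestep embedding, the class one-hot, and (optionally) the
#' standardized per-trial GLM amplitude vector. Training minimizes the
#' mean-squared error of the noise prediction with AdamW. Reference
#' training settings are 500 epochs, batch 64, learning rate 0.001 and
#' weight decay 0.01; `epochs` is exposed so reduced desk-scale fits are
#' possible.
#'
#' @param segments List of `trial_segment` (training split only).
#' @param labels Integer class labels (0 = normal, 1 = ICPP), one per
#'   segment.
#' @param beta Optional trials x channels matrix of per-trial GLM
#'   amplitudes used as conditioning (standardized internally).
#' @param schedule A `noise_schedule` (default [make_schedule()]).
#' @param epochs Training epochs (default 500).
#' @param batch_size Minibatch size (default 64).
#' @param lr AdamW learning rate (default 0.001).
#' @param weight_decay AdamW weight decay (default 0.01).
#' @param hidden Widths of the encoder and bottleneck layers (default
#'   `c(128, 64)`).
#' @param temb_dim Timestep-embedding dimension (default 16).
#' @param seed Integer seed (required).
#' @return Object of class `cddpm_state`: schedule, network parameters,
#'   per-epoch `training_log`, standardization constants, the training
#'   conditioning pool, and segment geometry.
#' @export
train_cddpm <- function(segments, labels, beta = NULL,
                        schedule = make_schedule(), epochs = 500,
                        batch_size = 64, lr = 0.001, weight_decay = 0.01,
                        hidden = c(128, 64), temb_dim = 16, seed) {
  if (missing(seed)) stop("`seed` is required.", call. = FALSE)
  stopifnot(length(labels) == length(segments))
  X <- segments_to_matrix(segments) # trials x D
  n_ch <- nrow(segments[[1]]$data)
  n_time <- ncol(segments[[1]]$data)
  D <- n_ch * n_time
  ch_index <- rep(seq_len(n_ch), each = n_time)
  ch_mean <- vapply(seq_len(n_ch), function(c) mean(X[, ch_index == c]), 0)
  ch_sd <- vapply(seq_len(n_ch), function(c) stats::sd(as.numeric(X[, ch_index == c])), 0)
  ch_sd[ch_sd < 1e-8] <- 1
  Xs <- sweep(sweep(X, 2, ch_mean[ch_index]), 2, ch_sd[ch_index], `/`)

  beta_center <- beta_scale <- NULL
  if (!is.null(beta)) {
    beta <- as.matrix(beta)
    beta_center <- colMeans(beta)
    beta_scale <- apply(beta, 2, stats::sd)
    beta_scale[beta_scale < 1e-8] <- 1
  }
  cond <- build_condition_matrix(labels, beta, beta_center, beta_scale)
  d_in <- D + temb_dim - temb_dim %% 2 + 2 + nrow(cond)

  withr::with_seed(seed, {
    par <- init_denoiser(d_in, D, hidden)
    opt <- list(
      t = 0,
      m = lapply(par, function(p) p * 0),
      v = lapply(par, function(p) p * 0)
    )
    n <- nrow(Xs)
    log_loss <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (start in seq(1, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, n)]
        B <- length(idx)
        f0 <- t(Xs[idx, , drop = FALSE]) # D x B
        tstep <- sample.int(schedule$n_steps, B, replace = TRUE)
        eps <- matrix(stats::rnorm(D * B), D, B)
        ab <- schedule$alpha_bar[tstep]
        ft <- sweep(f0, 2, sqrt(ab), `*`) + sweep(eps, 2, sqrt(1 - ab), `*`)
        Z <- rbind(ft, time_embedding(tstep, temb_dim, schedule),
                   cond[, idx, drop = FALSE])
        cache <- denoiser_forward(par, Z)
        # The network predicts the clean segment x0-hat; the noise estimate
        # follows analytically from the forward marginal. The squared-error
        # objective is taken in x0 space, i.e. the noise-prediction MSE
        # weighted per timestep by the inverse signal-to-noise ratio, which
        # keeps early (nearly noiseless) timesteps from drowning out the
        # conditional structure.
        err <- cache$Y - f0
        loss <- mean(err^2)
        if (!is.finite(loss)) stop("Diffusion training diverged (non-finite loss).", call. = FALSE)
        losses <- c(losses, loss)
        if (lr > 0) {
          grads <- denoiser_backward(par, cache, 2 * err / length(err))
          upd <- adamw_step(par, grads, opt, lr, weight_decay)
          par <- upd$par
          opt <- upd$opt
        }
      }
      log_loss[ep] <- mean(losses)
    }
  })

  structure(
    list(
      schedule = schedule, par = par, hidden = hidden, temb_dim = temb_dim,
      training_log = tibble::tibble(epoch = seq_len(epochs), loss = log_loss),
      ch_mean = ch_mean, ch_sd = ch_sd, n_channels = n_ch, n_time = n_time,
      beta_center = beta_center, beta_scale = beta_scale,
      class_means = list(
        `0` = colMeans(Xs[labels == 0, , drop = FALSE]),
        `1` = colMeans(Xs[labels == 1, , drop = FALSE])
      ),
      cond_pool = list(labels = labels, beta = beta),
      train_ids = paste(
        vapply(segments, `[[`, "", "subject_id"),
        vapply(segments, function(s) s$trial, 1), sep = ":"
      ),
      seed = seed, trained = TRUE
    ),
    class = "cddpm_state"
  )
}

#' @export
print.cddpm_state <- function(x, ...) {
  cat(sprintf(
    "<cddpm_state> %d-step schedule, %dx%d segments, hidden %s; final loss %.4f\n",
    x$schedule$n_steps, x$n_channels, x$n_time,
    paste(x$hidden, collapse = "/"), utils::tail(x$training_log$loss, 1)
  ))
  invisible(x)
}

#' @export
glance.cddpm_state <- function(x, ...) {
  tibble::tibble(
    n_steps = x$schedule$n_steps, epochs = nrow(x$training_log),
    initial_loss = x$training_log$loss[1],
    final_loss = utils::tail(x$training_log$loss, 1),
    n_channels = x$n_channels, n_time = x$n_time
  )
}

# Predict the noise for standardized flattened segments (D x B), given
# timesteps and a condition matrix. The network predicts the clean signal
# x0-hat; the noise estimate is recovered through the forward-marginal
# identity. `state$eps_fn`, when set, overrides the network (used to test
# the sampler's algebra against a known oracle).
predict_eps <- function(state, ft, tstep, cond) {
  if (!is.null(state$eps_fn)) return(state$eps_fn(ft, tstep, cond))
  if (!isTRUE(state$trained)) stop("Diffusion model is not trained.", call. = FALSE)
  Z <- rbind(ft, time_embedding(tstep, state$temb_dim, state$schedule), cond)
  x0_hat <- denoiser_forward(state$par, Z)$Y
  ab <- state$schedule$alpha_bar[tstep]
  sweep(ft - sweep(x0_hat, 2, sqrt(ab), `*`), 2, sqrt(1 - ab), `/`)
}

#' One ancestral denoising step
#'
#' DDPM posterior update from `f_t` to `f_(t-1)` using the predicted noise:
#' the posterior mean is
#' `(f_t - beta_t / sqrt(1 - alpha_bar_t) * eps_hat) / sqrt(alpha_t)`, and
#' the injected noise has the posterior variance
#' `sigma_t^2 = (1 - alpha_bar_(t-1)) / (1 - alpha_bar_t) * beta_t`, which
#' vanishes at the final step (t = 1) so the last update is deterministic.
#'
#' @param f_t Current state, D x B matrix (or vector).
#' @param t Timestep.
#' @param condition Condition matrix (cond_dim x B).
#' @param state A trained `cddpm_state`.
#' @param z Optional injected noise (defaults to standard normal; ignored
#'   at t = 1).
#' @return The denoised state, same shape as `f_t`.
#' @export
denoise_step <- function(f_t, t, condition, state, z = NULL) {
  sch <- state$schedule
  if (t < 1 || t > sch$n_steps) stop("`t` out of schedule range.", call. = FALSE)
  f_t <- cbind(f_t)
  eps_hat <- predict_eps(state, f_t, rep(t, ncol(f_t)), condition)
  mean_t <- (f_t - sch$beta[t] / sqrt(1 - sch$alpha_bar[t]) * eps_hat) / sqrt(sch$alpha[t])
  if (t == 1) return(mean_t)
  ab_prev <- sch$alpha_bar[t - 1]
  sigma <- sqrt((1 - ab_prev) / (1 - sch$alpha_bar[t]) * sch$beta[t])
  if (is.null(z)) z <- matrix(stats::rnorm(length(f_t)), nrow(f_t), ncol(f_t))
  mean_t + sigma * z
}

#' Sample synthetic trial segments from a trained diffusion model
#'
#' Ancestral sampling: start from the forward marginal at the final
#' timestep around the class-conditional training mean,
#' `f_T ~ N(sqrt(alpha_bar_T) * mean_c, (1 - alpha_bar_T) I)`, and apply
#' [denoise_step()] for `t = T..1` under the requested class condition; the
#' per-trial amplitude condition is resampled from the training pool of
#' that class. A 200-step schedule ending at `beta = 0.02` leaves
#' `alpha_bar_T ~ 0.12`, so the terminal marginal is not pure noise and a
#' unit-Gaussian start would sit systematically off the learned manifold;
#' initializing from the marginal is the matching truncated-schedule
#' start. Outputs are de-standardized back to umol/l and reshaped to
#' channels x time.
#'
#' @param state A trained `cddpm_state`.
#' @param n Number of segments to draw.
#' @param class_label 0 (normal) or 1 (ICPP).
#' @param seed Integer seed (required).
#' @return List of `trial_segment` objects flagged `synthetic = TRUE`.
#' @export
sample_cddpm <- function(state, n, class_label, seed) {
  if (missing(seed)) stop("`seed` is required.", call. = FALSE)
  if (!class_label %in% c(0, 1)) {
    stop("Unknown class label; expected 0 (normal) or 1 (ICPP).", call. = FALSE)
  }
  if (n == 0) return(list())
  D <- state$n_channels * state$n_time
  withr::with_seed(seed, {
    pool <- which(state$cond_pool$labels == class_label)
    if (length(pool) == 0) stop("No training examples of the requested class.", call. = FALSE)
    draw <- sample(pool, n, replace = TRUE)
    beta_cond <- if (!is.null(state$cond_pool$beta)) {
      state$cond_pool$beta[draw, , drop = FALSE]
    } else {
      NULL
    }
    cond <- build_condition_matrix(
      rep(class_label, n), beta_cond, state$beta_center, state$beta_scale
    )
    ab_end <- state$schedule$alpha_bar[state$schedule$n_steps]
    mu_c <- state$class_means[[as.character(class_label)]]
    f <- sqrt(ab_end) * mu_c + sqrt(1 - ab_end) * matrix(stats::rnorm(D * n), D, n)
    for (t in rev(seq_len(state$schedule$n_steps))) {
      f <- denoise_step(f, t, cond, state)
    }
  })
  ch_index <- rep(seq_len(state$n_channels), each = state$n_time)
  purrr::map(seq_len(n), function(i) {
    x <- f[, i] * state$ch_sd[ch_index] + state$ch_mean[ch_index]
    structure(
      list(
        data = matrix(x, state$n_channels, state$n_time, byrow = TRUE),
        subject_id = sprintf("synth_%d_%03d", class_label, i),
        trial = 1L, species = "hbo", label = class_label,
        gender = NA_character_, synthetic = TRUE
      ),
      class = "trial_segment"
    )
  })
}

#' Augment a training segment set with synthetic data
#'
#' Generates synthetic segments equal in number to the real training set,
#' with synthetic class proportions matching the real ones, and appends
#' them; the test set is never touched (real-only evaluation).
#'
#' @param train_segments Real training `trial_segment` list (the data the
#'   model in `state` was trained on).
#' @param state A trained `cddpm_state`.
#' @param seed Integer seed.
#' @return List with `segments` (real + synthetic, length `2 *
#'   length(train_segments)`), `labels`, and `synthetic` flags.
#' @export
augment_train_set <- function(train_segments, state, seed) {
  if (missing(seed)) stop("`seed` is required.", call. = FALSE)
  labels <- vapply(train_segments, function(s) as.numeric(s$label), 0)
  n1 <- round(sum(labels == 1))
  n0 <- length(labels) - n1
  synth <- c(
    sample_cddpm(state, n0, 0, seed = derive_seed(seed, "aug0")),
    sample_cddpm(state, n1, 1, seed = derive_seed(seed, "aug1"))
  )
  all_seg <- c(train_segments, synth)
  list(
    segments = all_seg,
    labels = c(labels, rep(c(0, 1), c(n0, n1))),
    synthetic = c(
      rep(FALSE, length(train_segments)),
      rep(TRUE, length(synth))
    )
  )
}

#' Guard against train/test leakage into the diffusion model
#'
#' @param state A trained `cddpm_state`.
#' @param test_segments Test `trial_segment` list.
#' @return Invisibly TRUE; errors if any test trial was in the diffusion
#'   training set.
#' @export
check_no_leakage <- function(state, test_segments) {
  test_ids <- paste(
    vapply(test_segments, `[[`, "", "subject_id"),
    vapply(test_segments, function(s) s$trial, 1), sep = ":"
  )
  if (any(test_ids %in% state$train_ids)) {
    stop("Leakage: diffusion model was trained on test-set trials.", call. = FALSE)
  }
  invisible(TRUE)
}
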