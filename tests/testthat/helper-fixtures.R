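# Shared fixture builders; everything is generated in code under fixed seeds.

make_segment <- function(data, subject_id = "S1", trial = 1L, label = NA,
                         species = "hbo") {
  structure(
    list(
      data = data, subject_id = subject_id, trial = as.integer(trial),
      species = species, label = label, gender = NA_character_
    ),
    class = "trial_segment"
  )
}

# Two-class toy segments: constant class mean +/- mu with white jitter.
make_toy_segments <- function(n_per_class = 32, mu = 1, jitter = 0.1,
                              n_ch = 10, n_t = 60, seed = 42) {
  withr::with_seed(seed, {
    pos <- lapply(seq_len(n_per_class), function(i) {
      make_segment(matrix(mu + stats::rnorm(n_ch * n_t, 0, jitter), n_ch, n_t),
        subject_id = paste0("pos", i), label = 1L
      )
    })
    neg <- lapply(seq_len(n_per_class), function(i) {
      make_segment(matrix(-mu + stats::rnorm(n_ch * n_t, 0, jitter), n_ch, n_t),
        subject_id = paste0("neg", i), label = 0L
      )
    })
    c(pos, neg)
  })
}

quiet_subject <- function(beta = rep(0.5, 10), id = "S1", group = "normal") {
  subject_record(id, group, "female", age = 10, education = 5, true_beta = beta)
}

# A small raw recording straight from the forward model.
quiet_recording <- function(beta = rep(0.5, 10), seed = 1,
                            noise = noise_config_quiet(),
                            paradigm = build_paradigm()) {
  subj <- quiet_subject(beta)
  hemo <- simulate_subject(subj, paradigm, noise, seed = seed)
  forward_intensity(hemo, optode_config(), paradigm, subj)
}

# Independent brute-force implementation of the evaluation metrics used as
# the oracle for confusion_metrics(): per-class tallies computed by direct
# enumeration over label pairs.
brute_force_metrics <- function(truth, pred) {
  tp <- tn <- fp <- fn <- 0
  for (i in seq_along(truth)) {
    if (truth[i] == 1 && pred[i] == 1) tp <- tp + 1
    if (truth[i] == 0 && pred[i] == 0) tn <- tn + 1
    if (truth[i] == 0 && pred[i] == 1) fp <- fp + 1
    if (truth[i] == 1 && pred[i] == 0) fn <- fn + 1
  }
  n <- length(truth)
  per_class <- function(cls) {
    tpc <- sum(truth == cls & pred == cls)
    ppc <- sum(pred == cls)
    apc <- sum(truth == cls)
    prec <- if (ppc > 0) tpc / ppc else 0
    rec <- tpc / apc
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(prec = prec, rec = rec, f1 = f1, w = apc / n)
  }
  c0 <- per_class(0)
  c1 <- per_class(1)
  list(
    accuracy = mean(truth == pred) * 100,
    precision = (c0["prec"] * c0["w"] + c1["prec"] * c1["w"]) * 100,
    recall = (c0["rec"] * c0["w"] + c1["rec"] * c1["w"]) * 100,
    f1 = (c0["f1"] * c0["w"] + c1["f1"] * c1["w"]) * 100,
    specificity = tn / (tn + fp) * 100,
    tp = tp, tn = tn, fp = fp, fn = fn
  )
}

digest_segments <- function(segs) lapply(segs, function(s) s$data)

# Brute-force Benjamini-Hochberg step-up adjustment, straight from the
# definition: p_(i) * m / i, cumulative minimum from the largest rank down.
brute_force_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}
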