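#' Build a block-design mental-arithmetic paradigm
#'
#' Constructs the event timeline of the block paradigm: each trial is a task
#' prompt, a mental-arithmetic (MA) block, a second prompt, and a rest block.
#' With the defaults (2 trials, 2-s prompts, 30-s blocks, 1 Hz sampling) the
#' paradigm lasts 128 s, matching a two-trial prefrontal fNIRS session.
#'
#' @param n_trials Number of MA+rest trials (default 2).
#' @param prompt_s Prompt duration in seconds (default 2; 0 drops prompts).
#' @param block_s Duration of each MA and rest block in seconds (default 30).
#' @param fs Sampling rate in Hz (default 1).
#'
#' @return An object of class `paradigm_spec`: a list with `events` (a tibble
#'   with columns `label` in `{prompt, MA, rest}`, `onset_s`, `duration_s`),
#'   `fs`, `n_trials`, `duration_s` and `n_samples`.
#' @examples
#' pdg <- build_paradigm()
#' pdg$duration_s # 128
#' @export
build_paradigm <- function(n_trials = 2, prompt_s = 2, block_s = 30, fs = 1) {
  if (!is.numeric(n_trials) || n_trials < 1) {
    stop("`n_trials` must be a positive integer.", call. = FALSE)
  }
  if (block_s <= 0) stop("`block_s` must be positive.", call. = FALSE)
  if (prompt_s < 0) stop("`prompt_s` must be non-negative.", call. = FALSE)
  if (fs <= 0) stop("`fs` must be positive.", call. = FALSE)
  n_trials <- as.integer(n_trials)

  trial_len <- 2 * prompt_s + 2 * block_s
  events <- purrr::map_dfr(seq_len(n_trials), function(i) {
    t0 <- (i - 1) * trial_len
    ev <- tibble::tibble(
      label = c("prompt", "MA", "prompt", "rest"),
      onset_s = t0 + c(0, prompt_s, prompt_s + block_s, 2 * prompt_s + block_s),
      duration_s = c(prompt_s, block_s, prompt_s, block_s),
      trial = i
    )
    ev[ev$duration_s > 0, ]
  })

  out <- structure(
    list(
      events = events,
      fs = fs,
      n_trials = n_trials,
      prompt_s = prompt_s,
      block_s = block_s,
      duration_s = n_trials * trial_len,
      n_samples = as.integer(round(n_trials * trial_len * fs))
    ),
    class = "paradigm_spec"
  )
  validate_paradigm(out)
  out
}

validate_paradigm <- function(p) {
  ev <- p$events
  stopifnot(all(ev$onset_s >= 0), all(ev$duration_s > 0))
  if (is.unsorted(ev$onset_s)) stop("Paradigm events must be sorted by onset.", call. = FALSE)
  ends <- ev$onset_s + ev$duration_s
  if (any(ends[-nrow(ev)] > ev$onset_s[-1] + 1e-9)) {
    stop("Paradigm events overlap.", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.paradigm_spec <- function(x, ...) {
  cat(sprintf(
    "<paradigm_spec> %d trial(s), %g s total at %g Hz (%d samples)\n",
    x$n_trials, x$duration_s, x$fs, x$n_samples
  ))
  print(x$events)
  invisible(x)
}

#' Time axis of a paradigm
#'
#' @param paradigm A `paradigm_spec`.
#' @return Numeric vector of sample times in seconds (left-aligned bins).
#' @export
paradigm_times <- function(paradigm) {
  seq(0, by = 1 / paradigm$fs, length.out = paradigm$n_samples)
}

#' Boxcar regressor for one event label
#'
#' Indicator time series that is 1 while an event with the given label is in
#' progress and 0 elsewhere, sampled on the paradigm grid.
#'
#' @param paradigm A `paradigm_spec`.
#' @param label Event label (`"MA"`, `"rest"` or `"prompt"`).
#' @return Numeric vector of length `paradigm$n_samples`.
#' @export
paradigm_boxcar <- function(paradigm, label) {
  tt <- paradigm_times(paradigm)
  box <- numeric(length(tt))
  ev <- paradigm$events[paradigm$events$label == label, ]
  for (k in seq_len(nrow(ev))) {
    box[tt >= ev$onset_s[k] - 1e-9 & tt < ev$onset_s[k] + ev$duration_s[k] - 1e-9] <- 1
  }
  box
}
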