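#' Canonical hemodynamic response function
#'
#' Double-gamma HRF: a gamma-density peak minus a scaled gamma-density
#' undershoot, sampled on the acquisition grid and normalized so the kernel
#' maximum equals 1. Defaults are the standard canonical parameterization
#' (peak delay 6 s, undershoot delay 16 s, unit dispersions, peak:undershoot
#' ratio 6:1, 32-s support).
#'
#' @param fs Sampling rate in Hz.
#' @param peak_delay_s Delay of the response peak gamma (seconds).
#' @param undershoot_delay_s Delay of the undershoot gamma (seconds).
#' @param peak_disp_s,undershoot_disp_s Dispersions (gamma scale, seconds).
#' @param ratio Undershoot amplitude relative to peak (default 1/6).
#' @param duration_s Kernel support in seconds (default 32).
#'
#' @return An object of class `hrf_kernel`: list with `values` (numeric
#'   kernel, first sample at t = 0), `times_s` and `fs`.
#' @examples
#' h <- canonical_hrf(fs = 1)
#' h$times_s[which.max(h$values)] # peak near 5 s
#' @export
canonical_hrf <- function(fs = 1, peak_delay_s = 6, undershoot_delay_s = 16,
                          peak_disp_s = 1, undershoot_disp_s = 1,
                          ratio = 1 / 6, duration_s = 32) {
  stopifnot(fs > 0, duration_s > 0, peak_disp_s > 0, undershoot_disp_s > 0)
  tt <- seq(0, duration_s, by = 1 / fs)
  h <- stats::dgamma(tt, shape = peak_delay_s / peak_disp_s, scale = peak_disp_s) -
    ratio * stats::dgamma(tt, shape = undershoot_delay_s / undershoot_disp_s,
                          scale = undershoot_disp_s)
  h <- h / max(h)
  structure(list(values = h, times_s = tt, fs = fs), class = "hrf_kernel")
}

#' @export
print.hrf_kernel <- function(x, ...) {
  cat(sprintf(
    "<hrf_kernel> %d samples at %g Hz, peak at %g s\n",
    length(x$values), x$fs, x$times_s[which.max(x$values)]
  ))
  invisible(x)
}

# Convolve a stimulus time course with an HRF kernel, truncated to the
# stimulus length (causal convolution).
hrf_convolve <- function(stimulus, hrf) {
  full <- stats::convolve(stimulus, rev(hrf$values), type = "open")
  full[seq_along(stimulus)]
}
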