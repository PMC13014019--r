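#' Empirical mode decomposition
#'
#' Standard sifting: at each step, upper and lower envelopes are cubic
#' splines through the local maxima and minima (endpoints included as
#' support so the envelopes span the full record), and the envelope mean is
#' subtracted until the Cauchy-type stopping criterion
#' `sum((h_prev - h)^2) / sum(h_prev^2) < sd_thresh` is met. Extraction
#' stops when the residue is monotone (fewer than 2 interior extrema of
#' each kind) or `max_imf` components have been found. By construction the
#' components plus the residue reconstruct the input exactly.
#'
#' @param x Numeric vector, length >= 8.
#' @param sd_thresh Sifting stop threshold (default 0.2).
#' @param max_imf Maximum number of intrinsic mode functions (default 10).
#' @param max_sift Maximum sifting iterations per IMF (default 50).
#' @return Object of class `emd_decomposition`: list with `imfs` (matrix,
#'   one row per IMF; 0 rows for monotone input), `residue`, `n_imfs`.
#' @examples
#' x <- sin(2 * pi * 0.4 * (0:99)) + sin(2 * pi * 0.05 * (0:99))
#' dec <- emd_decompose(x)
#' max(abs(colSums(dec$imfs) + dec$residue - x)) # ~ 0
#' @export
emd_decompose <- function(x, sd_thresh = 0.2, max_imf = 10, max_sift = 50) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 8) stop("EMD needs at least 8 samples.", call. = FALSE)
  imfs <- list()
  residue <- x
  for (k in seq_len(max_imf)) {
    ext <- find_extrema(residue)
    if (length(ext$max_idx) < 2 || length(ext$min_idx) < 2) break
    h <- residue
    for (s in seq_len(max_sift)) {
      env <- envelope_mean(h)
      if (is.null(env)) break
      h_new <- h - env
      crit <- sum((h - h_new)^2) / max(sum(h^2), .Machine$double.eps)
      h <- h_new
      if (crit < sd_thresh) break
    }
    imfs[[k]] <- h
    residue <- residue - h
  }
  imf_mat <- if (length(imfs)) do.call(rbind, imfs) else matrix(0, 0, n)
  structure(
    list(imfs = imf_mat, residue = residue, n_imfs = length(imfs)),
    class = "emd_decomposition"
  )
}

#' @export
print.emd_decomposition <- function(x, ...) {
  cat(sprintf("<emd_decomposition> %d IMF(s) + residue (%d samples)\n",
              x$n_imfs, length(x$residue)))
  invisible(x)
}

# Interior local extrema (strict neighbors; plateaus use midpoint).
find_extrema <- function(x) {
  n <- length(x)
  dx <- diff(x)
  sg <- sign(dx)
  # collapse zero slopes to the previous sign so plateaus count once
  for (i in seq_along(sg)) if (sg[i] == 0 && i > 1) sg[i] <- sg[i - 1]
  turns <- diff(sg)
  max_idx <- which(turns < 0) + 1L
  min_idx <- which(turns > 0) + 1L
  list(max_idx = max_idx, min_idx = min_idx)
}

# Mean of the cubic-spline upper and lower envelopes; NULL if the signal
# has too few extrema to define them.
envelope_mean <- function(x) {
  n <- length(x)
  ext <- find_extrema(x)
  if (length(ext$max_idx) < 2 || length(ext$min_idx) < 2) return(NULL)
  tt <- seq_len(n)
  up_i <- unique(c(1L, ext$max_idx, n))
  lo_i <- unique(c(1L, ext$min_idx, n))
  upper <- stats::spline(up_i, x[up_i], xout = tt, method = "natural")$y
  lower <- stats::spline(lo_i, x[lo_i], xout = tt, method = "natural")$y
  (upper + lower) / 2
}
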