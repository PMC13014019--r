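#' Optode and probe configuration
#'
#' Describes the continuous-wave probe used to forward-model and invert raw
#' light intensities: the two laser wavelengths, the source-detector
#' separation, the differential pathlength factor (DPF) per wavelength, and
#' the molar extinction coefficients of oxy- and deoxy-hemoglobin at each
#' wavelength. Defaults describe a 10-channel prefrontal probe measuring at
#' 775 and 855 nm with 30 mm source-detector separation; extinction
#' coefficients are taken from standard compiled hemoglobin extinction
#' tables (in l·mmol^-1·cm^-1) and the DPF defaults to 6.0 at both
#' wavelengths.
#'
#' @param wavelengths_nm Numeric pair of wavelengths in nm.
#' @param distance_mm Source-detector distance in mm.
#' @param dpf Differential pathlength factor, length-2 (per wavelength).
#' @param extinction 2x2 matrix of molar extinction coefficients in
#'   l·mmol^-1·cm^-1; rows = wavelengths, columns = `c("HbO", "HbR")`.
#' @param n_channels Number of measurement channels.
#' @param baseline_intensity Baseline detected intensity I0, either a scalar
#'   or a `2 x n_channels` matrix (wavelength x channel), arbitrary units.
#'
#' @return An object of class `optode_config`.
#' @export
optode_config <- function(wavelengths_nm = c(775, 855),
                          distance_mm = 30,
                          dpf = c(6.0, 6.0),
                          extinction = default_extinction(),
                          n_channels = 10,
                          baseline_intensity = 1) {
  if (distance_mm <= 0) stop("`distance_mm` must be positive.", call. = FALSE)
  if (any(dpf <= 0)) stop("`dpf` entries must be positive.", call. = FALSE)
  extinction <- as.matrix(extinction)
  stopifnot(identical(dim(extinction), c(2L, 2L)))
  if (is.null(colnames(extinction))) colnames(extinction) <- c("HbO", "HbR")
  det_eps <- extinction[2, "HbR"] * extinction[1, "HbO"] -
    extinction[1, "HbR"] * extinction[2, "HbO"]
  if (abs(det_eps) < 1e-12) {
    stop("Extinction-coefficient matrix is singular; wavelengths are not spectrally distinct.",
      call. = FALSE
    )
  }
  i0 <- baseline_intensity
  if (length(i0) == 1) i0 <- matrix(i0, nrow = 2, ncol = n_channels)
  i0 <- as.matrix(i0)
  stopifnot(nrow(i0) == 2, ncol(i0) == n_channels, all(i0 > 0))
  structure(
    list(
      wavelengths_nm = wavelengths_nm,
      distance_mm = distance_mm,
      dpf = dpf,
      extinction = extinction,
      n_channels = as.integer(n_channels),
      baseline_intensity = i0
    ),
    class = "optode_config"
  )
}

#' Default hemoglobin extinction coefficients
#'
#' Molar extinction coefficients of HbO and HbR at 775 and 855 nm in
#' l·mmol^-1·cm^-1, interpolated from standard compiled in-vitro hemoglobin
#' extinction spectra. At 775 nm deoxy-hemoglobin dominates; past the ~800 nm
#' isosbestic point oxy-hemoglobin dominates, which is what makes the
#' two-wavelength inversion well conditioned.
#'
#' @return 2x2 matrix, rows = wavelengths (775, 855 nm), columns = HbO, HbR.
#' @export
default_extinction <- function() {
  m <- matrix(
    c(
      0.683, 1.102, # 775 nm: HbO, HbR
      1.070, 0.740  # 855 nm: HbO, HbR
    ),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("775", "855"), c("HbO", "HbR"))
  )
  m
}

#' @export
print.optode_config <- function(x, ...) {
  cat(sprintf(
    "<optode_config> %d channels, wavelengths %s nm, d = %g mm, DPF = %s\n",
    x$n_channels, paste(x$wavelengths_nm, collapse = "/"),
    x$distance_mm, paste(x$dpf, collapse = "/")
  ))
  invisible(x)
}
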