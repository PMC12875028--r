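#' Contrast-to-mass calibration line
#'
#' Mass photometry exploits the direct proportionality between a particle's
#' polarizability (hence interferometric contrast) and its molecular mass.
#' A `mp_calibration` is the affine map `contrast = slope * mass + intercept`
#' used both to inject simulated events at the correct contrast and to
#' convert fitted contrasts back to mass.
#'
#' @param slope contrast per kDa; must be positive.
#' @param intercept contrast offset (unitless).
#' @return An object of class `mp_calibration`.
#' @export
calibration <- function(slope = 2e-5, intercept = 0) {
  if (!is.finite(slope) || slope <= 0)
    stop("calibration slope must be a positive finite number")
  structure(list(slope = slope, intercept = intercept), class = "mp_calibration")
}

#' @export
print.mp_calibration <- function(x, ...) {
  cat(sprintf("Mass calibration: contrast = %.4g * mass[kDa] + %.4g\n",
              x$slope, x$intercept))
  invisible(x)
}

#' Convert mass to ratiometric contrast
#'
#' @param mass mass in kDa (positive for the forward direction).
#' @param cal an [calibration()] object.
#' @return Contrast (unitless).
#' @export
mass_to_contrast <- function(mass, cal) {
  stopifnot(inherits(cal, "mp_calibration"))
  if (any(mass <= 0)) stop("mass must be positive")
  cal$slope * mass + cal$intercept
}

#' Convert ratiometric contrast to mass
#'
#' Exact inverse of [mass_to_contrast()]; negative contrasts (unbinding
#' artifacts) map to negative apparent masses, as seen in MP histograms.
#'
#' @param contrast unitless contrast value(s).
#' @param cal an [calibration()] object.
#' @return Mass in kDa.
#' @export
contrast_to_mass <- function(contrast, cal) {
  stopifnot(inherits(cal, "mp_calibration"))
  if (cal$slope == 0) stop("calibration slope is zero")
  (contrast - cal$intercept) / cal$slope
}

#' Fit a calibration line from standards of known mass
#'
#' Ordinary least squares of measured contrast against known mass, as done
#' with a calibrant (e.g. an oligomer ladder) measured alongside each
#' experimental set.
#'
#' @param known_masses masses of the standards (kDa); at least two distinct.
#' @param measured_contrasts corresponding mean contrasts.
#' @return An [calibration()] object.
#' @export
fit_calibration <- function(known_masses, measured_contrasts) {
  if (length(known_masses) != length(measured_contrasts))
    stop("masses and contrasts must have equal length")
  if (length(unique(known_masses)) < 2)
    stop("need at least 2 distinct masses to fit a calibration line")
  fit <- lm(measured_contrasts ~ known_masses)
  calibration(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]))
}
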