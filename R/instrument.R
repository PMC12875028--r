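#' Instrument configuration
#'
#' Acquisition parameters of the simulated mass photometer. Defaults follow a
#' typical small-field MP configuration: 726 frames/s at 1.3 ms exposure with
#' 3x binned pixels of 84.4 nm, and a 64 x 64 px field of view (about 29 um^2).
#' `baseline_intensity` sets the constant reflectivity baseline of raw frames
#' in arbitrary counts; `pixel_noise_sigma` is the i.i.d. per-pixel, per-frame
#' Gaussian noise emulating a shot-noise-dominated buffer blank. The default
#' noise is co-calibrated with the default [calibration()] slope so that
#' optimally binding 180 kDa particles are measured with a mass-domain
#' resolving power of about 11 at n_avg = 10 (see [calibrate_noise()]).
#'
#' @param frame_rate acquisition rate, frames/s.
#' @param pixel_size pixel size, nm/px.
#' @param fov field of view `(H, W)` in pixels.
#' @param exposure_ms exposure time per frame (metadata only).
#' @param baseline_intensity constant raw-frame baseline, counts.
#' @param pixel_noise_sigma raw per-pixel noise standard deviation, counts.
#' @return An object of class `instrument_config`.
#' @export
instrument_config <- function(frame_rate = 726, pixel_size = 84.4,
                              fov = c(64L, 64L), exposure_ms = 1.3,
                              baseline_intensity = 1000,
                              pixel_noise_sigma = MP_DEFAULT_NOISE) {
  stopifnot(frame_rate > 0, pixel_size > 0, pixel_noise_sigma >= 0,
            baseline_intensity > 0, length(fov) == 2, all(fov >= 1))
  structure(list(frame_rate = frame_rate, pixel_size = pixel_size,
                 fov = as.integer(fov), exposure_ms = exposure_ms,
                 baseline_intensity = baseline_intensity,
                 pixel_noise_sigma = pixel_noise_sigma),
            class = "instrument_config")
}

# Default raw pixel noise (counts, for baseline 1000): frozen output of
# calibrate_noise(target_rp = 11) under the default PSF/calibration/n_avg = 10.
MP_DEFAULT_NOISE <- 0.715

#' @export
print.instrument_config <- function(x, ...) {
  area <- prod(x$fov) * (x$pixel_size / 1000)^2
  cat(sprintf(
    "Instrument: %g fps, %g nm/px, %d x %d px FOV (%.1f um^2), baseline %g, noise sd %g\n",
    x$frame_rate, x$pixel_size, x$fov[1], x$fov[2], area,
    x$baseline_intensity, x$pixel_noise_sigma))
  invisible(x)
}

#' Convert a lateral speed from nm/ms to px/frame
#'
#' `v[px/frame] = v[nm/ms] * (1000 / frame_rate)[ms/frame] / pixel_size[nm/px]`.
#'
#' @param v speed in nm/ms.
#' @param config an [instrument_config()].
#' @return Speed in pixels per frame.
#' @export
nm_ms_to_px_frame <- function(v, config) {
  v * (1000 / config$frame_rate) / config$pixel_size
}
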