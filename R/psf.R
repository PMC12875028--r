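#' @title PSF templates
#' @name psf_templates
#' @description
#' A PSF template stores a radially sampled, peak-normalized model of the
#' instrument point spread function on an upsampled pixel grid. It is the
#' shared currency of the simulator (which injects `-contrast * baseline *
#' PSF` into raw frames) and the fitter (which recovers the contrast by
#' least squares). Two constructors are provided: [analytical_psf()], a
#' two-jinc-times-Gaussian model, and [build_epsf()], an empirical average of
#' measured event thumbnails.
NULL

new_psf_template <- function(grid, upsample, origin, half_width, params = list()) {
  stopifnot(is.matrix(grid), all(is.finite(grid)))
  structure(
    list(grid = grid, upsample = as.integer(upsample), origin = origin,
         half_width = half_width, normalization = grid[origin[1], origin[2]],
         params = params),
    class = "psf_template"
  )
}

#' @export
print.psf_template <- function(x, ...) {
  cat("PSF template:", nrow(x$grid), "x", ncol(x$grid), "grid, upsample",
      x$upsample, ", half-width", x$half_width, "px, FWHM",
      round(psf_fwhm(x), 2), "px\n")
  invisible(x)
}

# jinc(x) = 2 J1(pi x) / (pi x), jinc(0) = 1
jinc <- function(x) {
  out <- rep(1, length(x))
  nz <- x != 0
  out[nz] <- 2 * besselJ(pi * x[nz], 1) / (pi * x[nz])
  out
}

#' Analytical PSF model (two jinc functions under a Gaussian envelope)
#'
#' Builds a radially symmetric PSF template as the superposition of two jinc
#' functions (`jinc(x) = 2 J1(pi x)/(pi x)`) with scales `jinc_scale_1` and
#' `jinc_scale_2`, weighted `1 : jinc_weight_2`, multiplied by a Gaussian
#' kernel of width `gaussian_sigma`. The default parameters give a central
#' lobe of FWHM close to 3.5 px, a typical value for binned MP acquisition,
#' so the template is well resolved by a 17 x 17 pixel fitting window.
#'
#' @param grid_half_width half-width of the template support in pixels
#'   (at least 8, so a 17 x 17 patch is covered).
#' @param jinc_scale_1,jinc_scale_2 radial scales of the two jinc terms (px).
#' @param jinc_weight_2 relative weight of the second jinc term.
#' @param gaussian_sigma width of the Gaussian envelope (px).
#' @param upsample_factor integer grid oversampling factor.
#' @return A `psf_template` whose peak amplitude is exactly 1.
#' @export
analytical_psf <- function(grid_half_width = 10, jinc_scale_1 = 2.43,
                           jinc_scale_2 = 3.89, jinc_weight_2 = 0.25,
                           gaussian_sigma = 4.5, upsample_factor = 4L) {
  if (jinc_scale_1 <= 0 || jinc_scale_2 <= 0 || gaussian_sigma <= 0)
    stop("PSF scale parameters must be positive")
  if (grid_half_width < 8) stop("grid_half_width must be >= 8 px")
  if (upsample_factor < 1) stop("upsample_factor must be >= 1")
  u <- as.integer(upsample_factor)
  coords <- seq(-grid_half_width, grid_half_width, by = 1 / u)
  r <- sqrt(outer(coords^2, coords^2, `+`))
  g <- (jinc(r / jinc_scale_1) + jinc_weight_2 * jinc(r / jinc_scale_2)) *
    exp(-r^2 / (2 * gaussian_sigma^2))
  g <- g / (1 + jinc_weight_2)  # peak (r = 0) normalized to 1
  centre <- grid_half_width * u + 1L
  new_psf_template(g, u, c(centre, centre), grid_half_width,
                   params = list(jinc_scale_1 = jinc_scale_1,
                                 jinc_scale_2 = jinc_scale_2,
                                 jinc_weight_2 = jinc_weight_2,
                                 gaussian_sigma = gaussian_sigma))
}

#' Evaluate a PSF template at arbitrary sub-pixel offsets
#'
#' @param psf a `psf_template`.
#' @param x,y offsets from the peak in pixels (column and row direction).
#' @return Numeric vector of template amplitudes (1 at the peak, 0 outside
#'   the template support).
#' @export
psf_eval <- function(psf, x, y) {
  stopifnot(inherits(psf, "psf_template"))
  cpp_psf_value(psf$grid, psf$upsample, psf$origin[1], psf$origin[2],
                as.numeric(x), as.numeric(y))
}

#' Sample a PSF template on a square pixel patch
#'
#' Evaluates the template on a `(2*half_width+1)^2` pixel patch whose peak
#' sits at sub-pixel position `(dx, dy)` relative to the patch centre.
#'
#' @inheritParams psf_eval
#' @param dx,dy sub-pixel peak position relative to the patch centre (px).
#' @param half_width patch half-width in pixels.
#' @return Numeric matrix (rows = y, columns = x).
#' @export
psf_patch <- function(psf, dx = 0, dy = 0, half_width = 8L) {
  stopifnot(inherits(psf, "psf_template"))
  cpp_psf_patch(psf$grid, psf$upsample, psf$origin[1], psf$origin[2],
                dx, dy, as.integer(half_width))
}

# FWHM of the radial profile, by bisection on the half-maximum crossing
psf_fwhm <- function(psf) {
  f <- function(r) psf_eval(psf, r, 0) - 0.5
  lo <- 0; hi <- psf$half_width
  if (f(hi) > 0) return(NA_real_)
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  2 * (lo + hi) / 2
}

# sub-pixel refinement of an extremum by separable quadratic interpolation
refine_extremum <- function(patch, r0, c0) {
  refine1 <- function(fm, f0, fp) {
    den <- fm - 2 * f0 + fp
    if (den == 0) return(0)
    max(min(0.5 * (fm - fp) / den, 0.5), -0.5)
  }
  dr <- dc <- 0
  if (r0 > 1 && r0 < nrow(patch))
    dr <- refine1(patch[r0 - 1, c0], patch[r0, c0], patch[r0 + 1, c0])
  if (c0 > 1 && c0 < ncol(patch))
    dc <- refine1(patch[r0, c0 - 1], patch[r0, c0], patch[r0, c0 + 1])
  c(r0 + dr, c0 + dc)
}

#' Build an empirical PSF (ePSF) from measured event thumbnails
#'
#' Each 2D event patch is sign-normalized so its dominant extremum is
#' positive, sub-pixel re-centred on that extremum, and resampled onto a
#' common upsampled grid. Patches are then scored by Pearson correlation
#' against the running mean template; the top `keep_fraction` are retained
#' and averaged, and the score/average cycle is iterated twice before
#' peak-normalizing the result.
#'
#' @param thumbnails list of 2D numeric matrices, each containing a single
#'   dominant extremum near its centre (at least 10 patches).
#' @param keep_fraction fraction of best-correlated patches retained.
#' @param upsample_factor integer grid oversampling factor.
#' @param half_width half-width (px) of the output template support.
#' @return A `psf_template`; the attribute `kept` records which input
#'   patches survived the similarity selection.
#' @export
build_epsf <- function(thumbnails, keep_fraction = 0.8, upsample_factor = 4L,
                       half_width = 8L) {
  if (!is.list(thumbnails) || length(thumbnails) < 10)
    stop("build_epsf needs at least 10 thumbnails")
  if (keep_fraction <= 0 || keep_fraction > 1)
    stop("keep_fraction must be in (0, 1]")
  u <- as.integer(upsample_factor)
  resampled <- lapply(thumbnails, function(p) {
    if (!is.matrix(p) || !all(is.finite(p))) stop("thumbnails must be finite matrices")
    ctr <- p - median(p)
    if (all(ctr == 0)) stop("degenerate all-constant thumbnail")
    idx <- which(abs(ctr) == max(abs(ctr)), arr.ind = TRUE)[1, ]
    s <- sign(ctr[idx[1], idx[2]])
    ps <- p * s
    pk <- refine_extremum(ps, idx[1], idx[2])
    cpp_resample_centered(ps, pk[1], pk[2], u, as.integer(half_width))
  })
  vecs <- vapply(resampled, as.vector, numeric(length(resampled[[1]])))
  n_keep <- max(1L, ceiling(keep_fraction * length(resampled)))
  keep <- seq_along(resampled)
  for (it in 1:2) {
    m <- rowMeans(vecs[, keep, drop = FALSE])
    scores <- apply(vecs, 2, function(v) suppressWarnings(cor(v, m)))
    scores[is.na(scores)] <- -Inf
    keep <- order(scores, decreasing = TRUE)[seq_len(n_keep)]
  }
  avg <- matrix(rowMeans(vecs[, keep, drop = FALSE]), nrow(resampled[[1]]))
  centre <- as.integer(half_width) * u + 1L
  avg <- avg / avg[centre, centre]
  out <- new_psf_template(avg, u, c(centre, centre), half_width,
                          params = list(source = "epsf", n_input = length(thumbnails),
                                        keep_fraction = keep_fraction))
  attr(out, "kept") <- sort(keep)
  out
}

#' Serialize a PSF template
#'
#' Templates travel as a single-object RDS file carrying the grid and its
#' metadata (upsample factor, origin, half-width, generating parameters).
#'
#' @param psf a `psf_template`.
#' @param path file path.
#' @return `read_psf` returns the `psf_template`.
#' @export
write_psf <- function(psf, path) {
  stopifnot(inherits(psf, "psf_template"))
  saveRDS(unclass(psf), path)
  invisible(path)
}

#' @rdname write_psf
#' @export
read_psf <- function(path) {
  obj <- readRDS(path)
  if (!all(c("grid", "upsample", "origin", "half_width") %in% names(obj)))
    stop("not a PSF template file: ", path)
  new_psf_template(obj$grid, obj$upsample, obj$origin, obj$half_width,
                   params = obj$params)
}
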