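#' Detection configuration
#'
#' `threshold1` is the minimum absolute peak ratiometric contrast and
#' `threshold2` the minimum absolute normalized cross-correlation with the
#' PSF template; both must pass for a candidate to be kept. Absolute
#' threshold values are instrument- and convention-specific: defaults here
#' sit well above the calibrated synthetic noise floor, while the
#' "permissive" profile used near the detection limit lowers `threshold1`
#' into the noise tail (accepting false positives that are later removed by
#' classification).
#'
#' @param threshold1 minimum |peak contrast| (unitless).
#' @param threshold2 minimum |template correlation| in `[0, 1]`.
#' @param nms_radius non-maximum-suppression radius (px).
#' @param link_radius spatial radius (px) for temporal linking of per-frame
#'   candidates belonging to one ramping event.
#' @param link_gap maximum frame gap bridged during temporal linking.
#' @param nn_filter_radius,nn_filter_window nearest-neighbor de-duplication
#'   radius (px) and window (ratiometric frames), see [nn_filter()].
#' @return A `detection_config`.
#' @export
detection_config <- function(threshold1 = 1e-3, threshold2 = 0.5,
                             nms_radius = 4L, link_radius = 4L,
                             link_gap = 5L, nn_filter_radius = 4,
                             nn_filter_window = 20L) {
  stopifnot(is.finite(threshold1), is.finite(threshold2), nms_radius > 0,
            nn_filter_radius > 0, nn_filter_window > 0)
  structure(list(threshold1 = threshold1, threshold2 = threshold2,
                 nms_radius = as.integer(nms_radius),
                 link_radius = link_radius, link_gap = as.integer(link_gap),
                 nn_filter_radius = nn_filter_radius,
                 nn_filter_window = as.integer(nn_filter_window)),
            class = "detection_config")
}

# union-find with path compression
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

# cluster rows of (x, y, t) with |dx|,|dy| <= radius and |dt| <= window,
# connected-component semantics; returns component id per row
cluster_events <- function(x, y, t, radius, window) {
  n <- length(x)
  if (n == 0) return(integer(0))
  parent <- uf_new(n)
  ord <- order(t)
  for (a in seq_len(n)) {
    i <- ord[a]
    b <- a + 1
    while (b <= n && t[ord[b]] - t[i] <= window) {
      j <- ord[b]
      if (abs(x[i] - x[j]) <= radius && abs(y[i] - y[j]) <= radius) {
        ri <- uf_find(parent, i); rj <- uf_find(parent, j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
      b <- b + 1
    }
  }
  vapply(seq_len(n), function(i) uf_find(parent, i), 0L)
}

#' Detect candidate landing events in a ratiometric movie
#'
#' Per frame, local extrema of the contrast image `rat - 1` whose absolute
#' peak value exceeds `threshold1` and whose 17 x 17 neighborhood correlates
#' with the PSF template above `threshold2` (in absolute value) are kept
#' after non-maximum suppression. Per-frame candidates are then linked over
#' time (an event ramps over `2*n_avg - 1` ratiometric frames) and each
#' linked event is represented by its frame of maximal absolute contrast.
#' Contrast follows the landing-positive convention `-(rat - 1)`.
#'
#' @param rat a ratiometric `movie_stack`.
#' @param psf a `psf_template`.
#' @param cfg a [detection_config()].
#' @return data.frame with columns `x, y, t, contrast, ncc` (one row per
#'   linked event; empty if nothing is found).
#' @export
detect_candidates <- function(rat, psf, cfg = detection_config()) {
  stopifnot(inherits(rat, "movie_stack"), rat$ratiometric)
  K <- psf_patch(psf, 0, 0, 8L)
  K0 <- K - mean(K)
  K0 <- K0 / sqrt(sum(K0^2))
  d <- dim(rat$frames)
  cand <- cpp_detect(rat$frames, d[1], d[2], d[3], K0,
                     cfg$threshold1, cfg$threshold2, cfg$nms_radius, 8L)
  if (nrow(cand) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), t = integer(0),
                      contrast = numeric(0), ncc = numeric(0)))
  comp <- cluster_events(cand$x, cand$y, cand$t, cfg$link_radius, cfg$link_gap)
  keep <- vapply(split(seq_len(nrow(cand)), comp), function(idx) {
    idx[which.max(abs(cand$contrast[idx]))]
  }, 0L)
  out <- cand[sort(keep), c("x", "y", "t", "contrast", "ncc")]
  rownames(out) <- NULL
  out
}

#' Fit the PSF template to one detected event
#'
#' Levenberg-Marquardt least squares of `amplitude * PSF(x - x0, y - y0) +
#' offset` against the 17 x 17 contrast patch at the event's peak
#' ratiometric frame. Returns the sub-pixel position, the signed contrast
#' (`-amplitude` under the landing-negative convention) and the fit residual
#' (the square root of the summed squared differences between the patch and
#' the fitted model over the window). Non-convergence yields an infinite
#' residual rather than dropping the event.
#'
#' @param rat a ratiometric `movie_stack`.
#' @param candidate list or one-row data.frame with `x`, `y`, `t` (integer
#'   pixel/frame from [detect_candidates()]).
#' @param psf a `psf_template`.
#' @param max_iter maximum LM iterations.
#' @return List with `x`, `y`, `contrast`, `residual`, `offset`, `converged`.
#' @export
fit_event <- function(rat, candidate, psf, max_iter = 100L) {
  stopifnot(inherits(rat, "movie_stack"), rat$ratiometric)
  d <- dim(rat$frames)
  ix <- round(candidate$x); iy <- round(candidate$y); t <- candidate$t
  hw <- 8L
  if (iy - hw < 1 || iy + hw > d[2] || ix - hw < 1 || ix + hw > d[3] ||
      t < 1 || t > d[1])
    stop("candidate outside the fittable region")
  patch <- rat$frames[t, (iy - hw):(iy + hw), (ix - hw):(ix + hw)] - 1
  c0 <- median(patch)
  a0 <- patch[hw + 1, hw + 1] - c0
  fit <- cpp_fit_psf(patch, psf$grid, psf$upsample, psf$origin[1],
                     psf$origin[2], 0, 0, a0, c0, as.integer(max_iter), 1e-8)
  list(x = ix + fit$dx, y = iy + fit$dy, contrast = -fit$amplitude,
       residual = if (fit$converged) sqrt(fit$rss) else Inf,
       offset = fit$offset, converged = fit$converged)
}

#' Nearest-neighbor de-duplication of detected events
#'
#' Among events lying within `nn_filter_radius` px and `nn_filter_window`
#' frames of one another (connected-component semantics), only the event
#' with the largest absolute contrast is kept; ties break toward the earlier
#' frame, then the smaller row index.
#'
#' @param events data.frame with `x`, `y`, `t`, `contrast`.
#' @param cfg a [detection_config()].
#' @return The de-duplicated subset of `events`.
#' @export
nn_filter <- function(events, cfg = detection_config()) {
  if (nrow(events) <= 1) return(events)
  comp <- cluster_events(events$x, events$y, events$t,
                         cfg$nn_filter_radius, cfg$nn_filter_window)
  keep <- vapply(split(seq_len(nrow(events)), comp), function(idx) {
    o <- order(-abs(events$contrast[idx]), events$t[idx], idx)
    idx[o[1]]
  }, 0L)
  out <- events[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fill event masses from contrasts
#'
#' Applies [contrast_to_mass()] element-wise. Negative contrasts (unbinding
#' artifacts) map to negative apparent masses, mirroring the negative-mass
#' side of MP histograms.
#'
#' @param events data.frame with a `contrast` column.
#' @param cal an [calibration()].
#' @return `events` with a `mass` column filled.
#' @export
quantify_masses <- function(events, cal) {
  events$mass <- contrast_to_mass(events$contrast, cal)
  events
}

#' Detect, fit and quantify all events in a movie
#'
#' Full detection pipeline: [detect_candidates()], per-event [fit_event()],
#' [nn_filter()] de-duplication and [quantify_masses()].
#'
#' @param movie a raw or ratiometric `movie_stack`.
#' @param psf a `psf_template`.
#' @param cal an [calibration()].
#' @param cfg a [detection_config()].
#' @param n_avg ratiometric substack length (used if `movie` is raw).
#' @return data.frame of detected events: `event_id, x, y, t, contrast,
#'   mass, residual, converged`.
#' @export
detect_events <- function(movie, psf, cal, cfg = detection_config(),
                          n_avg = 10L) {
  rat <- if (movie$ratiometric) movie else ratiometric_stack(movie, n_avg)
  cand <- detect_candidates(rat, psf, cfg)
  if (nrow(cand) == 0)
    return(data.frame(event_id = integer(0), x = numeric(0), y = numeric(0),
                      t = integer(0), contrast = numeric(0), mass = numeric(0),
                      residual = numeric(0), converged = logical(0)))
  fits <- lapply(seq_len(nrow(cand)), function(i) fit_event(rat, cand[i, ], psf))
  ev <- data.frame(
    x = vapply(fits, `[[`, 0, "x"),
    y = vapply(fits, `[[`, 0, "y"),
    t = cand$t,
    contrast = vapply(fits, `[[`, 0, "contrast"),
    residual = vapply(fits, `[[`, 0, "residual"),
    converged = vapply(fits, `[[`, TRUE, "converged")
  )
  ev <- nn_filter(ev, cfg)
  ev <- quantify_masses(ev, cal)
  ev <- ev[, c("x", "y", "t", "contrast", "mass", "residual", "converged")]
  cbind(event_id = seq_len(nrow(ev)), ev)
}
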