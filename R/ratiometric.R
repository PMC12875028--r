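#' Ratiometric differential processing
#'
#' Converts a raw movie into a ratiometric contrast movie by dividing the
#' element-wise mean of a trailing frame substack by the mean of the leading
#' substack: output frame `k = mean(raw[k+n_avg .. k+2*n_avg-1]) /
#' mean(raw[k .. k+n_avg-1])`. Static structure cancels exactly to 1; a
#' landing event appears as a single-signed transient ramping over
#' `2*n_avg - 1` frames. The integration time is `2*n_avg / frame_rate`.
#'
#' @param movie a raw `movie_stack` with at least `2*n_avg` frames.
#' @param n_avg substack length in frames (>= 1).
#' @return A ratiometric `movie_stack` with `T - 2*n_avg + 1` frames.
#' @export
ratiometric_stack <- function(movie, n_avg = 10L) {
  stopifnot(inherits(movie, "movie_stack"))
  if (movie$ratiometric) stop("movie is already ratiometric")
  n_avg <- as.integer(n_avg)
  if (n_avg < 1) stop("n_avg must be >= 1")
  d <- dim(movie$frames)
  T_raw <- d[1]
  if (T_raw < 2 * n_avg)
    stop("movie too short: need at least 2*n_avg = ", 2 * n_avg, " frames")
  M <- matrix(movie$frames, nrow = T_raw)
  S <- rbind(0, apply(M, 2, cumsum))  # S[k+1] = colsum of rows 1..k
  k <- seq_len(T_raw - 2 * n_avg + 1)
  lead <- (S[k + n_avg, , drop = FALSE] - S[k, , drop = FALSE]) / n_avg
  trail <- (S[k + 2 * n_avg, , drop = FALSE] - S[k + n_avg, , drop = FALSE]) / n_avg
  rat <- trail / lead
  movie_stack(array(rat, dim = c(length(k), d[2], d[3])),
              frame_rate = movie$frame_rate, pixel_size = movie$pixel_size,
              ratiometric = TRUE, n_avg = n_avg)
}

#' Extract a 3D event thumbnail
#'
#' Copies an `n_frames x 17 x 17` window of a ratiometric movie, spatially
#' centred on the integer pixel nearest `(x, y)` and temporally placing the
#' landing transition (ratiometric frame `t`) at index `n_frames/2`. Events
#' within 8 px of the field-of-view edge, or too close to the start or end
#' of the stack, are rejected with a boundary error.
#'
#' @param rat a ratiometric `movie_stack`.
#' @param x,y event position (px; sub-pixel accepted).
#' @param t ratiometric frame index of the landing transition.
#' @param n_frames thumbnail length (even).
#' @return An `mp_thumbnail`: list with `values [n_frames, 17, 17]`, `center`
#'   and `standardized` flag.
#' @export
extract_thumbnail <- function(rat, x, y, t, n_frames = 40L) {
  stopifnot(inherits(rat, "movie_stack"))
  if (!rat$ratiometric) stop("thumbnails are extracted from ratiometric movies")
  d <- dim(rat$frames)
  ix <- round(x); iy <- round(y)
  hw <- 8L
  if (iy - hw < 1 || iy + hw > d[2] || ix - hw < 1 || ix + hw > d[3])
    stop(sprintf("event at (%.1f, %.1f) is within %d px of the field edge", x, y, hw))
  half <- n_frames / 2
  t0 <- t - half; t1 <- t + half - 1
  if (t0 < 1 || t1 > d[1])
    stop(sprintf("temporal window [%d, %d] outside stack; valid t range is [%d, %d]",
                 t0, t1, 1 + half, d[1] - half + 1))
  vals <- rat$frames[t0:t1, (iy - hw):(iy + hw), (ix - hw):(ix + hw), drop = FALSE]
  structure(list(values = array(vals, dim = c(n_frames, 17, 17)),
                 center = c(x = x, y = y, t = t), standardized = FALSE),
            class = "mp_thumbnail")
}

#' Per-thumbnail z-score standardization
#'
#' Standardizes a thumbnail to mean 0 and population standard deviation 1
#' over all voxels: `Z = (X - mu) / sigma`. Standardization removes the
#' mass-dependent contrast scale so the classifier sees shape, not
#' amplitude. Constant or non-finite thumbnails are rejected.
#'
#' @param thumb an `mp_thumbnail` or a plain numeric array.
#' @return The standardized thumbnail (same class as the input).
#' @export
standardize <- function(thumb) {
  v <- if (inherits(thumb, "mp_thumbnail")) thumb$values else thumb
  if (!all(is.finite(v))) stop("thumbnail contains non-finite values")
  mu <- mean(v)
  sg <- sqrt(mean((v - mu)^2))  # population sd
  if (sg == 0) stop("degenerate thumbnail: zero variance")
  z <- (v - mu) / sg
  if (inherits(thumb, "mp_thumbnail")) {
    thumb$values <- z
    thumb$standardized <- TRUE
    thumb
  } else z
}

# vectorized per-thumbnail standardization of an [T,17,17,N] array
standardize_array <- function(arr) {
  d <- dim(arr)
  m <- matrix(arr, ncol = d[4])
  mu <- colMeans(m)
  sg <- sqrt(colMeans(m^2) - mu^2)
  if (any(!is.finite(sg)) || any(sg == 0))
    stop("thumbnail set contains degenerate or non-finite thumbnails")
  array(sweep(sweep(m, 2, mu), 2, sg, "/"), dim = d)
}
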