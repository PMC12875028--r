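#' Raw movie container
#'
#' A `movie_stack` holds a stack of grayscale frames as a numeric array
#' `[T, H, W]` together with acquisition metadata. Raw stacks carry intensity
#' counts; ratiometric stacks (see [ratiometric_stack()]) carry unitless
#' ratios with mean 1 far from events.
#'
#' @param frames numeric array `[T, H, W]`.
#' @param frame_rate frames/s.
#' @param pixel_size nm/px.
#' @param ratiometric logical; is this a ratiometric stack?
#' @param n_avg frames per ratiometric substack (`NA` for raw movies).
#' @return A `movie_stack`.
#' @export
movie_stack <- function(frames, frame_rate = 726, pixel_size = 84.4,
                        ratiometric = FALSE, n_avg = NA_integer_) {
  stopifnot(is.array(frames), length(dim(frames)) == 3)
  structure(list(frames = frames, frame_rate = frame_rate,
                 pixel_size = pixel_size, ratiometric = ratiometric,
                 n_avg = n_avg),
            class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("%s movie: %d frames of %d x %d px @ %g fps\n",
              if (x$ratiometric) "Ratiometric" else "Raw",
              d[1], d[2], d[3], x$frame_rate))
  invisible(x)
}

#' Synthesize a buffer-blank background movie
#'
#' Emulates a shot-noise-dominated buffer measurement: every raw frame is the
#' constant reflectivity baseline plus i.i.d. Gaussian pixel noise. Under
#' ratiometric division such a stack cancels to mean 1.
#'
#' @param n_frames number of raw frames.
#' @param config an [instrument_config()].
#' @param seed optional integer seed; if `NULL` the ambient RNG stream is used.
#' @return A raw `movie_stack`.
#' @export
synth_background <- function(n_frames, config = instrument_config(), seed = NULL) {
  stopifnot(n_frames >= 2)
  gen <- function() {
    f <- array(rnorm(n_frames * prod(config$fov), mean = config$baseline_intensity,
                     sd = config$pixel_noise_sigma),
               dim = c(n_frames, config$fov))
    movie_stack(f, config$frame_rate, config$pixel_size)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Event dynamics parameters
#'
#' Distribution parameters of the five landing-event classes. Durations are
#' frame counts; velocities are in nm/ms and are converted to px/frame by the
#' instrument configuration. The wobbler speed sd follows the declared
#' parameter summary (3.5 nm/ms).
#'
#' @return A named list of parameters.
#' @export
event_dynamics_params <- function() {
  list(
    unbinder_tu_mean = 10, unbinder_tu_sd = 5, unbinder_tu_range = c(0, 20),
    roller_tr_range = c(4L, 7L),        # uniform over {4..7} frames
    roller_v_range = c(1.7, 18.6),      # nm/ms, uniform [1.7, 18.6)
    roller_p_unbind = 0.75,
    wobbler_tw_range = c(2L, 14L),      # uniform over {2..14} frames
    wobbler_v_mean = 8.5, wobbler_v_sd = 3.5,  # nm/ms, truncated at 0
    wobbler_p_unbind = 0.5,
    neighbor_n_range = c(1L, 19L)       # uniform over {1..19}
  )
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  u <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(u, mean, sd)
}

# class-specific dynamics: trajectory during motion, unbinding frame
draw_dynamics <- function(label, x0, y0, t0, config, params) {
  out <- list(t_unbind = Inf, traj = NULL, x_final = x0, y_final = y0,
              params = list())
  if (label == "unbinder") {
    t_u <- round(rtrunc_norm(1, params$unbinder_tu_mean, params$unbinder_tu_sd,
                             params$unbinder_tu_range[1], params$unbinder_tu_range[2]))
    out$t_unbind <- t0 + t_u
    out$params <- list(t_u = t_u)
  } else if (label == "roller") {
    t_r <- sample(params$roller_tr_range[1]:params$roller_tr_range[2], 1)
    v_r <- runif(1, params$roller_v_range[1], params$roller_v_range[2])
    vpx <- nm_ms_to_px_frame(v_r, config)
    theta <- runif(1, 0, 2 * pi)
    k <- seq_len(t_r) - 1
    traj <- cbind(t = t0 + k, x = x0 + k * vpx * cos(theta),
                  y = y0 + k * vpx * sin(theta))
    unbinds <- runif(1) < params$roller_p_unbind
    out$traj <- traj
    out$x_final <- traj[t_r, "x"]
    out$y_final <- traj[t_r, "y"]
    out$t_unbind <- if (unbinds) t0 + t_r else Inf
    out$params <- list(t_r = t_r, v_r = v_r, theta = theta, unbinds = unbinds)
  } else if (label == "wobbler") {
    t_w <- sample(params$wobbler_tw_range[1]:params$wobbler_tw_range[2], 1)
    sp <- pmax(rtrunc_norm(t_w, params$wobbler_v_mean, params$wobbler_v_sd, 0, Inf), 0)
    vpx <- nm_ms_to_px_frame(sp, config)
    th <- runif(t_w, 0, 2 * pi)
    dx <- c(0, cumsum(vpx * cos(th)))[seq_len(t_w)]
    dy <- c(0, cumsum(vpx * sin(th)))[seq_len(t_w)]
    traj <- cbind(t = t0 + seq_len(t_w) - 1, x = x0 + dx, y = y0 + dy)
    unbinds <- runif(1) < params$wobbler_p_unbind
    out$traj <- traj
    out$x_final <- traj[t_w, "x"]
    out$y_final <- traj[t_w, "y"]
    out$t_unbind <- if (unbinds) t0 + t_w else Inf
    out$params <- list(t_w = t_w, v_w = sp, unbinds = unbinds)
  }
  out
}

#' Sample a ground-truth landing event
#'
#' Draws one `event_spec` of the requested class with all stochastic fields
#' taken from the class's dynamics distributions (see
#' [event_dynamics_params()]): unbinders stay bound for
#' `t_u ~ N(10, 5)` frames truncated to `[0, 20]`; rollers move in one fixed
#' direction for 4-7 frames at 1.7-18.6 nm/ms and then unbind with
#' probability 0.75; wobblers random-walk for 2-14 frames with per-frame
#' speed `N(8.5, 3.5)` nm/ms truncated at 0 and unbind with probability 0.5;
#' neighbor events add 1-19 stationary binders inside the thumbnail window.
#'
#' @param label one of [event_classes()].
#' @param mass_sampler function `n -> masses` in kDa (default: the skewed
#'   training distribution, see [default_mass_sampler()]).
#' @param window thumbnail length in ratiometric frames.
#' @param config an [instrument_config()].
#' @param seed optional integer seed; `NULL` uses the ambient RNG stream.
#' @param n_avg ratiometric substack length (frames).
#' @param center `(x, y)` pixel around which the event lands (sub-pixel
#'   jitter of +-0.5 px is added).
#' @param params dynamics parameters, see [event_dynamics_params()].
#' @return An `event_spec`.
#' @export
sample_event_spec <- function(label, mass_sampler = default_mass_sampler,
                              window = 40L, config = instrument_config(),
                              seed = NULL, n_avg = 10L,
                              center = c(11, 11),
                              params = event_dynamics_params()) {
  if (!label %in% EVENT_CLASSES)
    stop("unknown event class: ", label)
  stopifnot(window >= 2)
  gen <- function() {
    mass <- mass_sampler(1)
    x0 <- center[1] + runif(1, -0.5, 0.5)
    y0 <- center[2] + runif(1, -0.5, 0.5)
    t0 <- n_avg + window / 2 + 1  # landing transition centred in the window
    dyn <- draw_dynamics(label, x0, y0, t0, config, params)
    neighbors <- NULL
    if (label == "neighbor") {
      n_n <- sample(params$neighbor_n_range[1]:params$neighbor_n_range[2], 1)
      neighbors <- data.frame(
        mass = mass_sampler(n_n),
        x = x0 + runif(n_n, -8.5, 8.5),
        y = y0 + runif(n_n, -8.5, 8.5),
        t0 = t0 + sample((-window / 2):(window / 2 - 1), n_n, replace = TRUE)
      )
      neighbors$t0 <- pmax(neighbors$t0, 1)
    }
    structure(list(label = label, mass = mass, x0 = x0, y0 = y0, t0 = t0,
                   t_unbind = dyn$t_unbind, traj = dyn$traj,
                   x_final = dyn$x_final, y_final = dyn$y_final,
                   neighbors = neighbors, params = dyn$params),
              class = "event_spec")
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Default training mass distribution
#'
#' Masses span 30-800 kDa with a deliberate bias toward the low-SNR 30-100
#' kDa range (half the probability mass), compensating for the larger
#' prediction uncertainty there.
#'
#' @param n number of draws.
#' @return Numeric vector of masses in kDa.
#' @export
default_mass_sampler <- function(n) {
  lo <- runif(n) < 0.5
  ifelse(lo, runif(n, 30, 100), runif(n, 100, 800))
}

#' Recover the class label implied by an event's ground-truth fields
#'
#' Used to check label/field consistency: the label of a well-formed
#' `event_spec` is a function of its trajectory, unbinding frame and
#' neighbor list.
#'
#' @param spec an `event_spec`.
#' @return One of [event_classes()].
#' @export
infer_label <- function(spec) {
  if (!is.null(spec$neighbors)) return("neighbor")
  if (!is.null(spec$traj)) {
    # directed motion: >= 4 frames of identical, equally spaced steps;
    # anything else (including 2-3 frame walks) is a random walk
    if (nrow(spec$traj) >= 4) {
      dx <- diff(spec$traj[, "x"]); dy <- diff(spec$traj[, "y"])
      if (sd(dx) < 1e-9 && sd(dy) < 1e-9) return("roller")
    }
    return("wobbler")
  }
  if (is.finite(spec$t_unbind)) return("unbinder")
  "binder"
}

# per-frame injection schedule for one particle: frames, positions, amplitudes
particle_schedule <- function(t0, t_unbind, traj, x_final, y_final, amp, T) {
  t_end <- min(t_unbind - 1, T)
  if (t_end < t0) return(NULL)
  tt <- t0:t_end
  xx <- rep(x_final, length(tt))
  yy <- rep(y_final, length(tt))
  if (!is.null(traj)) {
    m <- match(tt, traj[, "t"])
    has <- !is.na(m)
    xx[has] <- traj[m[has], "x"]
    yy[has] <- traj[m[has], "y"]
  }
  list(t = as.integer(tt), x = xx, y = yy, amp = rep(amp, length(tt)))
}

inject_into <- function(frames, spec, psf, cal, baseline, sign = -1) {
  d <- dim(frames)
  sched <- particle_schedule(spec$t0, spec$t_unbind, spec$traj,
                             spec$x_final, spec$y_final,
                             sign * mass_to_contrast(spec$mass, cal) * baseline,
                             d[1])
  if (!is.null(sched))
    cpp_inject_ip(frames, d[1], d[2], d[3], sched$t, sched$x, sched$y,
                  sched$amp, psf$grid, psf$upsample, psf$origin[1],
                  psf$origin[2], psf$half_width)
  if (!is.null(spec$neighbors)) {
    for (i in seq_len(nrow(spec$neighbors))) {
      nb <- spec$neighbors[i, ]
      s <- particle_schedule(nb$t0, Inf, NULL, nb$x, nb$y,
                             sign * mass_to_contrast(nb$mass, cal) * baseline,
                             d[1])
      if (!is.null(s))
        cpp_inject_ip(frames, d[1], d[2], d[3], s$t, s$x, s$y, s$amp,
                      psf$grid, psf$upsample, psf$origin[1], psf$origin[2],
                      psf$half_width)
    }
  }
  invisible(frames)
}

#' Inject a ground-truth event into a raw movie
#'
#' Adds, for every frame in `[t0, t_unbind)`, the signed PSF-shaped intensity
#' `sign * contrast(mass) * baseline * PSF` at the event's per-frame
#' sub-pixel position; neighbor particles are injected the same way. The
#' default sign is negative: a landing particle darkens the ratiometric
#' quotient. Injection is purely additive, so injecting the same event with
#' `sign` flipped restores the background bit-exactly.
#'
#' @param movie a raw `movie_stack`.
#' @param spec an `event_spec` (or list of them).
#' @param psf a `psf_template`.
#' @param cal an [calibration()].
#' @param sign +1 or -1 contrast sign convention.
#' @param baseline raw baseline intensity; defaults to the movie-wide median.
#' @return The movie with the event(s) added.
#' @export
inject_event <- function(movie, spec, psf, cal, sign = -1, baseline = NULL) {
  stopifnot(inherits(movie, "movie_stack"))
  if (movie$ratiometric) stop("events are injected into raw movies only")
  if (inherits(spec, "event_spec")) spec <- list(spec)
  if (is.null(baseline)) baseline <- median(movie$frames[1, , ])
  frames <- movie$frames + 0  # force a private copy, then fill in place
  for (s in spec) inject_into(frames, s, psf, cal, baseline, sign)
  movie$frames <- frames
  movie
}

#' Generate a balanced labeled thumbnail training set
#'
#' For every event a fresh synthetic buffer patch is generated, one event of
#' the requested class injected at the intensity level, the patch processed
#' ratiometrically at `n_avg`, and a `(n_frames x 17 x 17)` thumbnail
#' extracted centred on the landing position with the landing transition at
#' the temporal midpoint. Thumbnails containing non-finite values are
#' removed. Events are simulated on small local patches (21 x 21 px), which
#' is exact for thumbnail purposes because injection is local.
#'
#' @param n_events total number of events (balanced across classes).
#' @param mass_sampler function `n -> masses` (kDa).
#' @param n_avg ratiometric substack length (frames).
#' @param n_frames thumbnail length (ratiometric frames).
#' @param config an [instrument_config()] (noise, frame rate, pixel size; the
#'   field of view is replaced by the local patch).
#' @param psf a `psf_template`.
#' @param cal an [calibration()].
#' @param split_frac fraction assigned to the training split.
#' @param seed master seed; every event gets an independent derived stream.
#' @return A `thumbnail_set`: list with `thumbnails [n_frames, 17, 17, N]`,
#'   `labels` (factor), `masses`, `split` ("train"/"val"), `n_avg`, `n_frames`.
#' @export
generate_training_set <- function(n_events, mass_sampler = default_mass_sampler,
                                  n_avg = 10L, n_frames = 40L,
                                  config = instrument_config(),
                                  psf = analytical_psf(), cal = calibration(),
                                  split_frac = 0.8, seed = 1L) {
  stopifnot(n_events >= 5)
  classes <- rep(EVENT_CLASSES, length.out = 5 * ceiling(n_events / 5))[seq_len(n_events)]
  patch_cfg <- config
  patch_cfg$fov <- c(21L, 21L)
  T_raw <- n_frames + 2L * n_avg
  seeds <- derive_seeds(seed, n_events + 1L)
  thumbs <- array(NA_real_, dim = c(n_frames, 17, 17, n_events))
  masses <- numeric(n_events)
  for (i in seq_len(n_events)) {
    with_seed(seeds[i], {
      spec <- sample_event_spec(classes[i], mass_sampler, window = n_frames,
                                config = patch_cfg, n_avg = n_avg,
                                center = c(11, 11))
      bg <- synth_background(T_raw, patch_cfg)
      mv <- inject_event(bg, spec, psf, cal, baseline = patch_cfg$baseline_intensity)
      rat <- ratiometric_stack(mv, n_avg)
      th <- extract_thumbnail(rat, spec$x0, spec$y0, spec$t0 - n_avg, n_frames)
      thumbs[, , , i] <- th$values
      masses[i] <- spec$mass
    })
  }
  ok <- apply(is.finite(thumbs), 4, all)
  thumbs <- thumbs[, , , ok, drop = FALSE]
  labels <- factor(classes[ok], levels = EVENT_CLASSES)
  masses <- masses[ok]
  n <- sum(ok)
  split <- rep("val", n)
  split[with_seed(seeds[n_events + 1L], sample.int(n, round(split_frac * n)))] <- "train"
  structure(list(thumbnails = thumbs, labels = labels, masses = masses,
                 split = split, n_avg = n_avg, n_frames = n_frames),
            class = "thumbnail_set")
}

#' @export
print.thumbnail_set <- function(x, ...) {
  cat(sprintf("Thumbnail set: %d events (%d train / %d val), %d x 17 x 17\n",
              length(x$labels), sum(x$split == "train"), sum(x$split == "val"),
              x$n_frames))
  print(table(x$labels))
  invisible(x)
}

#' Simulate a full landing assay movie
#'
#' Landing times follow a Poisson process at `event_rate_density` events per
#' um^2 per second; positions are uniform over the field of view; species and
#' event classes are drawn from the stated mixtures. Neighboring events are
#' not a valid mixture class here: in an assay, crowding arises naturally
#' from the event density.
#'
#' @param event_rate_density events per um^2 per second.
#' @param duration assay duration in seconds.
#' @param species data.frame with columns `mass` (kDa) and `abundance`
#'   (summing to 1).
#' @param class_mix named probabilities over binder/unbinder/roller/wobbler.
#' @param config an [instrument_config()].
#' @param psf a `psf_template`.
#' @param cal an [calibration()].
#' @param n_avg ratiometric substack length, used to validate the duration.
#' @param seed optional integer seed.
#' @return List with `movie` (raw `movie_stack`) and `truth` (data.frame of
#'   ground-truth events: label, mass, x0, y0, t0, t_unbind).
#' @export
simulate_assay <- function(event_rate_density, duration,
                           species = data.frame(mass = c(180, 360),
                                                abundance = c(0.5, 0.5)),
                           class_mix = c(binder = 1),
                           config = instrument_config(),
                           psf = analytical_psf(), cal = calibration(),
                           n_avg = 10L, seed = NULL) {
  stopifnot(event_rate_density >= 0, abs(sum(species$abundance) - 1) < 1e-8)
  if (!all(names(class_mix) %in% setdiff(EVENT_CLASSES, "neighbor")))
    stop("assay class_mix must use binder/unbinder/roller/wobbler")
  T_raw <- round(duration * config$frame_rate)
  if (T_raw < 2 * n_avg)
    stop("duration shorter than one ratiometric window (2 * n_avg frames)")
  gen <- function() {
    area <- prod(config$fov) * (config$pixel_size / 1000)^2  # um^2
    n <- rpois(1, event_rate_density * area * duration)
    H <- config$fov[1]; W <- config$fov[2]
    truth <- data.frame(event_id = integer(0), label = character(0),
                        mass_kda = numeric(0), x0_px = numeric(0),
                        y0_px = numeric(0), t0_frame = integer(0),
                        t_unbind_frame = numeric(0))
    bg <- synth_background(T_raw, config)
    if (n > 0) {
      labs <- sample(names(class_mix), n, replace = TRUE, prob = class_mix)
      sp_i <- sample.int(nrow(species), n, replace = TRUE, prob = species$abundance)
      specs <- vector("list", n)
      for (i in seq_len(n)) {
        x0 <- runif(1, 1, W); y0 <- runif(1, 1, H)
        t0 <- sample.int(T_raw, 1)
        dyn <- draw_dynamics(labs[i], x0, y0, t0, config, event_dynamics_params())
        specs[[i]] <- structure(
          list(label = labs[i], mass = species$mass[sp_i[i]], x0 = x0, y0 = y0,
               t0 = t0, t_unbind = dyn$t_unbind, traj = dyn$traj,
               x_final = dyn$x_final, y_final = dyn$y_final,
               neighbors = NULL, params = dyn$params),
          class = "event_spec")
      }
      frames <- bg$frames + 0
      for (s in specs)
        inject_into(frames, s, psf, cal, config$baseline_intensity)
      bg$frames <- frames
      truth <- data.frame(
        event_id = seq_len(n),
        label = labs,
        mass_kda = vapply(specs, function(s) s$mass, 0),
        x0_px = vapply(specs, function(s) s$x0, 0),
        y0_px = vapply(specs, function(s) s$y0, 0),
        t0_frame = vapply(specs, function(s) s$t0, 0),
        t_unbind_frame = vapply(specs, function(s) s$t_unbind, 0)
      )
    }
    list(movie = bg, truth = truth)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}
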