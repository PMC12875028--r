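#' Read and write movie stacks
#'
#' Movies are stored as multi-page 32-bit float TIFF; acquisition metadata
#' (frame rate, pixel size, ratiometric flag, n_avg) travels in a JSON
#' sidecar file `<path>.meta.json`. Reading a movie without a sidecar falls
#' back to the default acquisition metadata (726 fps) with a warning. Raw
#' intensities are rescaled by `scale` on write (TIFF float round-trips
#' losslessly, so `read_movie(write_movie(m))` is exact).
#'
#' @param movie a `movie_stack`.
#' @param path file path (`.tif`/`.tiff`).
#' @param scale divisor applied on write and re-multiplied on read, to keep
#'   arbitrary-count data in a viewer-friendly range (stored in the sidecar).
#' @return `read_movie` returns a `movie_stack`.
#' @export
write_movie <- function(movie, path, scale = NULL) {
  stopifnot(inherits(movie, "movie_stack"))
  d <- dim(movie$frames)
  if (is.null(scale)) scale <- max(abs(movie$frames), 1)
  pages <- lapply(seq_len(d[1]), function(t) movie$frames[t, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(frame_rate = movie$frame_rate, pixel_size = movie$pixel_size,
               ratiometric = movie$ratiometric,
               n_avg = if (is.na(movie$n_avg)) NULL else movie$n_avg,
               scale = scale, n_frames = d[1])
  meta <- meta[!vapply(meta, is.null, TRUE)]
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_movie
#' @export
read_movie <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2)
    stop("expected a multi-frame stack, got a single 2D image: ", path)
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    warning("no metadata sidecar for ", path, "; assuming 726 fps defaults")
    meta <- list(frame_rate = 726, pixel_size = 84.4, ratiometric = FALSE,
                 n_avg = NA, scale = 1)
  }
  d <- dim(pages[[1]])
  frames <- array(0, dim = c(length(pages), d[1], d[2]))
  for (t in seq_along(pages)) frames[t, , ] <- pages[[t]] * meta$scale
  movie_stack(frames, frame_rate = meta$frame_rate,
              pixel_size = meta$pixel_size,
              ratiometric = isTRUE(meta$ratiometric),
              n_avg = if (length(meta$n_avg) != 1 || is.na(meta$n_avg))
                        NA_integer_ else as.integer(meta$n_avg))
}

EVENT_CSV_REQUIRED <- c("event_id", "x", "y", "t", "contrast", "mass")

#' Read and write event tables
#'
#' Events travel as plain CSV with full floating-point precision; columns
#' beyond the required schema (`event_id, x, y, t, contrast, mass`) are
#' preserved untouched.
#'
#' @param events data.frame of detected events.
#' @param path CSV path.
#' @return `read_events` returns the event data.frame.
#' @export
write_events <- function(events, path) {
  write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- read.csv(path, check.names = FALSE)
  missing <- setdiff(EVENT_CSV_REQUIRED, names(ev))
  if (length(missing) > 0)
    stop("event table ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  ev
}

#' Read a YAML run configuration
#'
#' Validates the schema (unknown top-level keys are rejected) and builds the
#' package objects: instrument config, calibration, PSF, detection config
#' and a master seed.
#'
#' @param path YAML file.
#' @return List with `instrument`, `calibration`, `psf`, `detection`,
#'   `seed`, `output_dir` and the raw config under `raw`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  known <- c("instrument", "calibration", "psf", "detection", "train",
             "scenario", "seed", "output_dir")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  build <- function(ctor, args, allowed) {
    if (is.null(args)) return(ctor())
    bad <- setdiff(names(args), allowed)
    if (length(bad) > 0)
      stop("unknown config key(s): ", paste(bad, collapse = ", "))
    do.call(ctor, args)
  }
  inst <- build(instrument_config, raw$instrument,
                names(formals(instrument_config)))
  cal <- build(calibration, raw$calibration, names(formals(calibration)))
  psf <- if (!is.null(raw$psf$file)) read_psf(raw$psf$file)
         else build(analytical_psf, raw$psf, names(formals(analytical_psf)))
  det <- build(detection_config, raw$detection, names(formals(detection_config)))
  list(instrument = inst, calibration = cal, psf = psf, detection = det,
       seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed),
       output_dir = if (is.null(raw$output_dir)) "." else raw$output_dir,
       raw = raw)
}

#' Write a reproducibility manifest
#'
#' Every scenario/CLI run emits a JSON manifest recording the package
#' version, seed, configuration hash and parameters, sufficient to
#' regenerate the outputs.
#'
#' @param path output JSON path.
#' @param command the operation name.
#' @param seed the master seed used.
#' @param params named list of parameters.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, command, seed, params = list()) {
  manifest <- list(
    package = "mpevents",
    version = as.character(utils::packageVersion("mpevents")),
    command = command, seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    params = params,
    config_hash = sum(utf8ToInt(paste(deparse(params), collapse = ""))))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
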