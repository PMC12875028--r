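# Shared fixtures: built once per test run, in code.
fx <- new.env(parent = emptyenv())

fx_psf <- function() {
  if (is.null(fx$psf)) fx$psf <- analytical_psf()
  fx$psf
}

fx_cal <- function() calibration()

# small-patch instrument config for single-event simulations
fx_patch_cfg <- function(noise = NULL) {
  cfg <- instrument_config(fov = c(25L, 25L))
  if (!is.null(noise)) cfg$pixel_noise_sigma <- noise
  cfg
}

# one clean injected binder on a noiseless patch, plus its ratiometric stack
fx_clean_binder <- function(mass = 180, seed = 5) {
  if (is.null(fx$clean_binder)) {
    cfg <- fx_patch_cfg(noise = 0)
    spec <- sample_event_spec("binder", function(n) rep(mass, n),
                              config = cfg, seed = seed, center = c(13, 13))
    bg <- synth_background(60, cfg, seed = 1)
    mv <- inject_event(bg, spec, fx_psf(), fx_cal(), baseline = 1000)
    fx$clean_binder <- list(spec = spec, bg = bg, movie = mv,
                            rat = ratiometric_stack(mv, 10))
  }
  fx$clean_binder
}
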