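# The study model shared by the acceptance blocks: the reduced training
# profile (2,500 events with masses >= 100 kDa, 10 epochs of the reference
# recipe). Trained once per test run and cached, together with its dataset
# and the calibrated instrument configuration.
fx_calibrated_cfg <- function() {
  if (is.null(fx$cal_cfg))
    fx$cal_cfg <- calibrate_noise(target_rp = 11, n = 400, seed = 101)
  fx$cal_cfg
}

fx_study <- function() {
  if (is.null(fx$study)) {
    set <- generate_training_set(
      2500, mass_sampler = function(n) runif(n, 100, 800),
      config = fx_calibrated_cfg(), psf = fx_psf(), cal = fx_cal(),
      seed = 2024)
    model <- build_model(model_spec(n_frames = 40, base_width = 8), seed = 7)
    model <- train_model(model, set, train_config(epochs = 10, seed = 7))
    fx$study <- list(model = model, set = set)
  }
  fx$study
}
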