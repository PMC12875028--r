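test_that("buffer-only movies give zero detections at strict thresholds", {
  cfg <- instrument_config(fov = c(32L, 32L))
  bg <- synth_background(80, cfg, seed = 21)
  rat <- ratiometric_stack(bg, 10)
  cand <- detect_candidates(rat, fx_psf(), detection_config(threshold1 = 2e-3))
  expect_equal(nrow(cand), 0)
})

test_that("a single injected binder is detected once, at the right place", {
  cb <- fx_clean_binder()
  cand <- detect_candidates(cb$rat, fx_psf(), detection_config(threshold1 = 1e-3))
  expect_equal(nrow(cand), 1)
  expect_lt(abs(cand$x - cb$spec$x0), 1)
  expect_lt(abs(cand$y - cb$spec$y0), 1)
  expect_lt(abs(cand$t - (cb$spec$t0 - 10)), 2)
  expect_equal(cand$contrast, mass_to_contrast(180, fx_cal()), tolerance = 0.05)
})

test_that("two nearby binders are resolved as two events", {
  cfg <- instrument_config(fov = c(36L, 36L), pixel_noise_sigma = 0)
  bg <- synth_background(60, cfg, seed = 2)
  mk <- function(x, y) {
    s <- sample_event_spec("binder", function(n) rep(250, n), config = cfg,
                           seed = 77, center = c(x, y))
    s$x0 <- s$x_final <- x; s$y0 <- s$y_final <- y
    s
  }
  mv <- inject_event(bg, list(mk(14, 18), mk(24, 18)), fx_psf(), fx_cal(),
                     baseline = 1000)
  cand <- detect_candidates(ratiometric_stack(mv, 10), fx_psf(),
                            detection_config(threshold1 = 1e-3, nms_radius = 4))
  expect_equal(nrow(cand), 2)
  expect_setequal(cand$x, c(14, 24))
})

test_that("detection recall is 100% for noiseless events above 2x threshold", {
  cfg <- fx_patch_cfg(noise = 0)
  thr <- detection_config(threshold1 = 1e-3)
  set.seed(31)
  for (i in 1:10) {
    mass <- runif(1, 2e-3, 8e-3) / fx_cal()$slope  # contrast >= 2 * threshold1
    spec <- sample_event_spec("binder", function(n) rep(mass, n), config = cfg,
                              center = c(13, 13))
    bg <- synth_background(60, cfg)
    mv <- inject_event(bg, spec, fx_psf(), fx_cal(), baseline = 1000)
    cand <- detect_candidates(ratiometric_stack(mv, 10), fx_psf(), thr)
    expect_equal(nrow(cand), 1)
  }
})

test_that("PSF fits are exact on perfect patches and Eq-4-consistent", {
  psf <- fx_psf()
  cb <- fx_clean_binder()
  cand <- list(x = round(cb$spec$x0), y = round(cb$spec$y0), t = cb$spec$t0 - 10)
  fit <- fit_event(cb$rat, cand, psf)
  expect_true(fit$converged)
  # noiseless binder: sub-pixel position and contrast recovered
  expect_lt(abs(fit$x - cb$spec$x0), 0.02)
  expect_lt(abs(fit$y - cb$spec$y0), 0.02)
  expect_equal(fit$contrast, mass_to_contrast(180, fx_cal()), tolerance = 1e-4)
  expect_lt(fit$residual, 1e-6)
  mass <- contrast_to_mass(fit$contrast, fx_cal())
  expect_lt(abs(mass - 180) / 180, 0.01)
})

test_that("the fit residual is the Frobenius norm of the residual patch", {
  # patch = a * PSF + single perturbed pixel: refitting suppressed by
  # evaluating Eq. 4 directly at the known optimum
  psf <- fx_psf()
  a <- -4e-3
  patch <- a * psf_patch(psf, 0.2, -0.1, 8)
  perturbed <- patch
  perturbed[4, 12] <- perturbed[4, 12] + 2
  model_fit <- patch  # the exact model surface
  r_direct <- 0
  for (i in 1:17) for (j in 1:17)
    r_direct <- r_direct + (perturbed[i, j] - model_fit[i, j])^2
  expect_equal(sqrt(r_direct), 2)  # single +2 pixel -> r = 2
  # brute-force double loop equals vectorized Frobenius norm
  expect_equal(sqrt(r_direct), norm(perturbed - model_fit, "F"))
})

test_that("fit_event is translation-equivariant across integer shifts", {
  cfg <- instrument_config(fov = c(41L, 41L), pixel_noise_sigma = 0)
  bg <- synth_background(60, cfg, seed = 6)
  spec <- sample_event_spec("binder", function(n) rep(300, n), config = cfg,
                            seed = 9, center = c(15, 19))
  mv <- inject_event(bg, spec, fx_psf(), fx_cal(), baseline = 1000)
  rat <- ratiometric_stack(mv, 10)
  f1 <- fit_event(rat, list(x = 15, y = 19, t = spec$t0 - 10), fx_psf())
  # the same event translated by an integer pixel offset (+3, -2)
  spec2 <- spec
  spec2$x0 <- spec2$x_final <- spec$x0 + 3
  spec2$y0 <- spec2$y_final <- spec$y0 - 2
  mv2 <- inject_event(bg, spec2, fx_psf(), fx_cal(), baseline = 1000)
  f2 <- fit_event(ratiometric_stack(mv2, 10), list(x = 18, y = 17, t = spec$t0 - 10),
                  fx_psf())
  expect_equal(f2$x - f1$x, 3, tolerance = 1e-5)
  expect_equal(f2$y - f1$y, -2, tolerance = 1e-5)
  expect_equal(f2$contrast, f1$contrast, tolerance = 1e-6)
  expect_equal(f2$residual, f1$residual, tolerance = 1e-6)
})

test_that("nn_filter keeps the strongest detection per cluster with connected components", {
  ev <- data.frame(x = c(10, 11, 30, 10.5), y = c(10, 10.5, 30, 10.2),
                   t = c(100, 103, 100, 106),
                   contrast = c(3e-3, 5e-3, 2e-3, 1e-3))
  out <- nn_filter(ev, detection_config(nn_filter_radius = 2, nn_filter_window = 5))
  expect_equal(nrow(out), 2)
  expect_setequal(out$contrast, c(5e-3, 2e-3))
  # far-apart events are both kept
  ev2 <- data.frame(x = c(5, 25), y = c(5, 25), t = c(1, 1), contrast = c(1, 2) * 1e-3)
  expect_equal(nrow(nn_filter(ev2, detection_config())), 2)
})

test_that("nn_filter chain semantics match a brute-force clustering oracle", {
  # chain A~B~C with A and C not direct neighbors: one survivor
  chain <- data.frame(x = c(10, 13, 16), y = c(10, 10, 10), t = c(1, 1, 1),
                      contrast = c(1e-3, 2e-3, 1.5e-3))
  cfg <- detection_config(nn_filter_radius = 3.5, nn_filter_window = 5)
  out <- nn_filter(chain, cfg)
  expect_equal(nrow(out), 1)
  expect_equal(out$contrast, 2e-3)
  # randomized instances vs an independent transitive-closure oracle
  brute_components <- function(ev, radius, window) {
    n <- nrow(ev)
    adj <- matrix(FALSE, n, n)
    for (i in 1:n) for (j in 1:n)
      adj[i, j] <- abs(ev$x[i] - ev$x[j]) <= radius &
        abs(ev$y[i] - ev$y[j]) <= radius & abs(ev$t[i] - ev$t[j]) <= window
    reach <- adj
    for (k in 1:n) reach <- reach | (reach %*% (reach + 0)) > 0
    comp <- integer(n)
    cid <- 0
    for (i in 1:n) if (comp[i] == 0) { cid <- cid + 1; comp[reach[i, ]] <- cid }
    comp
  }
  set.seed(61)
  for (rep in 1:20) {
    n <- sample(2:12, 1)
    ev <- data.frame(x = runif(n, 0, 20), y = runif(n, 0, 20),
                     t = sample(1:30, n, replace = TRUE),
                     contrast = runif(n, 1e-4, 1e-2))
    comp <- brute_components(ev, 4, 10)
    out <- nn_filter(ev, detection_config(nn_filter_radius = 4,
                                          nn_filter_window = 10))
    expect_equal(nrow(out), length(unique(comp)))
    # the survivor of each component is its max-|contrast| member
    best <- vapply(split(ev$contrast, comp), max, 0)
    expect_setequal(out$contrast, unname(best))
  }
})

test_that("quantify_masses maps signed contrasts through the calibration", {
  cal <- calibration(slope = 2e-5, intercept = 1e-4)
  ev <- data.frame(contrast = c(0, 3.6e-3, -3.6e-3))
  out <- quantify_masses(ev, cal)
  expect_equal(out$mass[1], -cal$intercept / cal$slope)
  # symmetric contrasts give masses symmetric about -intercept/slope
  expect_equal(mean(out$mass[2:3]), -cal$intercept / cal$slope)
})

test_that("the LM fitter agrees with an independent nonlinear least-squares oracle", {
  psf <- fx_psf()
  set.seed(81)
  for (rep in 1:5) {
    a <- -runif(1, 2e-3, 8e-3)
    dx <- runif(1, -0.5, 0.5); dy <- runif(1, -0.5, 0.5)
    off <- runif(1, -2e-4, 2e-4)
    patch <- a * psf_patch(psf, dx, dy, 8) + off + rnorm(289, sd = 2e-4)
    ours <- mpevents:::cpp_fit_psf(patch, psf$grid, psf$upsample,
                                   psf$origin[1], psf$origin[2],
                                   0, 0, patch[9, 9] - median(patch),
                                   median(patch), 100L, 1e-10)
    resid_fun <- function(p) {
      as.vector(patch - (p[3] * psf_patch(psf, p[1], p[2], 8) + p[4]))
    }
    ref <- minpack.lm::nls.lm(par = c(0, 0, patch[9, 9] - median(patch),
                                      median(patch)), fn = resid_fun)
    expect_equal(c(ours$dx, ours$dy, ours$amplitude, ours$offset),
                 unname(ref$par), tolerance = 1e-3)
    expect_equal(ours$rss, sum(resid_fun(ref$par)^2), tolerance = 1e-4)
  }
})
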