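test_that("synthetic backgrounds have the configured noise and are seed-reproducible", {
  cfg <- instrument_config(fov = c(32L, 32L), pixel_noise_sigma = 0)
  bg <- synth_background(5, cfg, seed = 1)
  expect_true(all(bg$frames == cfg$baseline_intensity))
  cfg$pixel_noise_sigma <- 1.5
  b1 <- synth_background(100, cfg, seed = 7)
  b2 <- synth_background(100, cfg, seed = 7)
  expect_identical(b1$frames, b2$frames)
  # sample sd over ~10^5 pixels within 2% (Monte-Carlo estimate)
  expect_equal(sd(b1$frames), 1.5, tolerance = 0.02)
  expect_equal(mean(b1$frames), cfg$baseline_intensity, tolerance = 0.01)
})

test_that("event-class samplers follow the declared dynamics distributions", {
  cfg <- fx_patch_cfg()
  b <- sample_event_spec("binder", seed = 1, config = cfg)
  expect_identical(b$t_unbind, Inf)
  expect_null(b$traj)
  expect_null(b$neighbors)
  expect_error(sample_event_spec("glider", config = cfg), "unknown event class")

  # unbinder durations: truncated normal(10, 5) on [0, 20]
  set.seed(11)
  tu <- replicate(10000, sample_event_spec("unbinder", config = cfg)$params$t_u)
  expect_true(all(tu >= 0 & tu <= 20))
  expect_gt(mean(tu), 9.3)   # Monte-Carlo band for the truncated mean
  expect_lt(mean(tu), 10.7)

  # rollers: v_r uniform [1.7, 18.6), duration {4..7}, unbind prob 0.75
  set.seed(12)
  rollers <- lapply(1:10000, function(i) sample_event_spec("roller", config = cfg)$params)
  vr <- vapply(rollers, `[[`, 0, "v_r")
  tr <- vapply(rollers, `[[`, 0, "t_r")
  unb <- vapply(rollers, `[[`, TRUE, "unbinds")
  expect_true(all(vr >= 1.7 & vr < 18.6))
  expect_setequal(unique(tr), 4:7)
  expect_gt(mean(unb), 0.73)
  expect_lt(mean(unb), 0.77)

  # wobblers: duration {2..14}, speeds >= 0, unbind prob 0.5
  set.seed(13)
  wob <- lapply(1:4000, function(i) sample_event_spec("wobbler", config = cfg)$params)
  tw <- vapply(wob, `[[`, 0, "t_w")
  expect_setequal(unique(tw), 2:14)
  expect_true(all(unlist(lapply(wob, `[[`, "v_w")) >= 0))
  expect_equal(mean(vapply(wob, `[[`, TRUE, "unbinds")), 0.5, tolerance = 0.03)

  # neighbors: 1..19 extra binders inside the thumbnail footprint
  set.seed(14)
  nn <- vapply(1:4000, function(i)
    nrow(sample_event_spec("neighbor", config = cfg)$neighbors), 0L)
  expect_setequal(unique(nn), 1:19)
  expect_equal(mean(nn), 10, tolerance = 0.3)
})

test_that("event labels are recoverable from spec fields alone", {
  cfg <- fx_patch_cfg()
  set.seed(20)
  for (lab in event_classes()) {
    for (i in 1:20) {
      spec <- sample_event_spec(lab, config = cfg)
      expect_identical(infer_label(spec), lab)
    }
  }
})

test_that("velocity conversion matches hand computation", {
  cfg <- instrument_config(frame_rate = 726, pixel_size = 84.4)
  # 8.5 nm/ms * (1000/726) ms/frame / 84.4 nm/px
  expect_equal(nm_ms_to_px_frame(8.5, cfg), 8.5 * (1000 / 726) / 84.4)
  cfg2 <- instrument_config(frame_rate = 500, pixel_size = 100)
  expect_equal(nm_ms_to_px_frame(10, cfg2), 0.2)
})

test_that("injection is additive, reversible, and has the documented amplitude", {
  cb <- fx_clean_binder()
  spec <- cb$spec; cal <- fx_cal()
  # frame before landing untouched
  expect_identical(cb$movie$frames[spec$t0 - 1, , ], cb$bg$frames[spec$t0 - 1, , ])
  # extremum deviation = contrast * baseline * PSF(subpixel offset)
  dev <- cb$movie$frames[spec$t0, , ] - cb$bg$frames[spec$t0, , ]
  ix <- round(spec$x0); iy <- round(spec$y0)
  expected <- -mass_to_contrast(180, cal) * 1000 *
    psf_eval(fx_psf(), ix - spec$x0, iy - spec$y0)
  expect_equal(dev[iy, ix], expected, tolerance = 1e-6 * abs(expected))
  # removing the event (opposite sign) restores the background bit-exactly
  restored <- inject_event(cb$movie, spec, fx_psf(), cal, sign = +1,
                           baseline = 1000)
  expect_identical(restored$frames, cb$bg$frames)
})

test_that("unbinder signal vanishes after t_u frames", {
  cfg <- fx_patch_cfg(noise = 0)
  set.seed(33)
  spec <- sample_event_spec("unbinder", function(n) rep(300, n), config = cfg,
                            center = c(13, 13))
  spec$t_unbind <- spec$t0 + 5
  bg <- synth_background(60, cfg, seed = 2)
  mv <- inject_event(bg, spec, fx_psf(), fx_cal(), baseline = 1000)
  expect_identical(mv$frames[spec$t0 + 5, , ], bg$frames[spec$t0 + 5, , ])
  expect_identical(mv$frames[60, , ], bg$frames[60, , ])
  expect_false(identical(mv$frames[spec$t0 + 4, , ], bg$frames[spec$t0 + 4, , ]))
})

test_that("roller extrema advance at the trajectory speed (centroid oracle)", {
  cfg <- fx_patch_cfg(noise = 0)
  set.seed(51)
  spec <- sample_event_spec("roller", function(n) rep(500, n), config = cfg,
                            center = c(13, 13))
  spec$params$unbinds <- FALSE
  spec$t_unbind <- Inf
  bg <- synth_background(60, cfg, seed = 3)
  mv <- inject_event(bg, spec, fx_psf(), fx_cal(), baseline = 1000)
  centroid <- function(k) {
    fr <- mv$frames[spec$traj[k, "t"], , ] - bg$frames[spec$traj[k, "t"], , ]
    idx <- which(fr == min(fr), arr.ind = TRUE)[1, ]
    w <- -fr[(idx[1] - 3):(idx[1] + 3), (idx[2] - 3):(idx[2] + 3)]
    w[w < 0] <- 0
    c(sum((idx[2] - 3):(idx[2] + 3) * colSums(w)) / sum(w),
      sum((idx[1] - 3):(idx[1] + 3) * rowSums(w)) / sum(w))
  }
  vpx <- nm_ms_to_px_frame(spec$params$v_r, cfg)
  for (k in seq_len(nrow(spec$traj) - 1)) {
    # frame-to-frame displacement of the extremum equals the speed (+- 0.1 px)
    step <- centroid(k + 1) - centroid(k)
    expect_equal(sqrt(sum(step^2)), vpx, tolerance = 0.1 / max(vpx, 0.1))
  }
})

test_that("out-of-bounds trajectories are rejected with the frame named", {
  cfg <- fx_patch_cfg(noise = 0)
  spec <- sample_event_spec("binder", seed = 1, config = cfg, center = c(13, 13))
  spec$x0 <- spec$x_final <- 40  # outside the 25 px patch
  bg <- synth_background(60, cfg, seed = 1)
  expect_error(inject_event(bg, spec, fx_psf(), fx_cal()), "field of view")
})

test_that("ratiometric frame noise follows the substack averaging law", {
  # sd(rat) ~ sigma * sqrt(2 / n_avg) / baseline
  cfg <- instrument_config(fov = c(24L, 24L), pixel_noise_sigma = 2)
  bg <- synth_background(400, cfg, seed = 9)
  for (n_avg in c(5L, 10L)) {
    rat <- ratiometric_stack(bg, n_avg)
    # use every (2 n_avg)-th frame so windows do not overlap
    pick <- seq(1, dim(rat$frames)[1], by = 2 * n_avg)
    meas <- sd(rat$frames[pick, , ])
    theory <- 2 * sqrt(2 / n_avg) / cfg$baseline_intensity
    expect_equal(meas, theory, tolerance = 0.05)
  }
})

test_that("training sets are balanced, split 80:20 and NaN-clean", {
  set <- generate_training_set(100, seed = 3)
  expect_equal(dim(set$thumbnails), c(40, 17, 17, 100))
  expect_true(all(is.finite(set$thumbnails)))
  expect_equal(as.vector(table(set$labels)), rep(20, 5))
  expect_equal(sum(set$split == "train"), 80)
  expect_true(all(set$masses >= 30 & set$masses < 800))
  # reproducible from the master seed
  set2 <- generate_training_set(100, seed = 3)
  expect_identical(set$thumbnails, set2$thumbnails)
  expect_identical(set$split, set2$split)
})

test_that("assay event counts follow the Poisson law and species mixture", {
  cfg <- instrument_config(fov = c(32L, 32L), pixel_noise_sigma = 0.7)
  area <- prod(cfg$fov) * (cfg$pixel_size / 1000)^2
  duration <- 1.0
  dens <- 40
  lambda <- dens * area * duration
  counts <- vapply(1:12, function(s)
    nrow(simulate_assay(dens, duration, config = cfg, seed = s)$truth), 0)
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / 12))
  # two species 1:1: per-species counts inside the binomial 99% interval
  sim <- simulate_assay(60, duration, config = cfg, seed = 99)
  n <- nrow(sim$truth)
  n180 <- sum(sim$truth$mass_kda == 180)
  expect_gt(n180, qbinom(0.005, n, 0.5))
  expect_lt(n180, qbinom(0.995, n, 0.5))
  # density 0: no events, ratiometric movie is 1 up to noise
  empty <- simulate_assay(0, 0.2, config = cfg, seed = 1)
  expect_equal(nrow(empty$truth), 0)
  rat <- ratiometric_stack(empty$movie, 10)
  expect_equal(mean(rat$frames), 1, tolerance = 1e-3)
  expect_error(simulate_assay(1, 0.01, config = cfg, seed = 1),
               "duration shorter")
  expect_error(simulate_assay(1, 1, class_mix = c(neighbor = 1), config = cfg),
               "class_mix")
})
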