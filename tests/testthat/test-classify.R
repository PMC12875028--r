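# A tiny-width variant keeps these structural tests fast; the architecture
# (stem + 3/4/6/3 bottleneck stages + 2-layer head) is identical at any width.
tiny_spec <- function() model_spec(n_frames = 40, base_width = 2, hidden = 16)

test_that("model construction is deterministic and shape-checked", {
  m1 <- build_model(tiny_spec(), seed = 3)
  m2 <- build_model(tiny_spec(), seed = 3)
  m3 <- build_model(tiny_spec(), seed = 4)
  info <- mpevents:::cpp_net_info(m1$ptr)
  expect_equal(info$n_blocks, 16)  # 3 + 4 + 6 + 3 bottleneck blocks
  set.seed(1)
  probe <- array(rnorm(40 * 17 * 17 * 3), dim = c(40, 17, 17, 3))
  s1 <- predict_scores(m1, probe)
  s2 <- predict_scores(m2, probe)
  s3 <- predict_scores(m3, probe)
  expect_identical(s1$scores, s2$scores)
  expect_false(identical(s1$scores, s3$scores))
  # zero input: finite logits
  zeros <- array(0, dim = c(40, 17, 17, 2)) + rnorm(40 * 17 * 17 * 2, sd = 1e-6)
  expect_true(all(is.finite(predict_scores(m1, zeros)$scores)))
  # frame-count mismatch names the expected dimensions
  bad <- array(rnorm(20 * 17 * 17), dim = c(20, 17, 17, 1))
  expect_error(predict_scores(m1, bad), "expects 40")
})

test_that("parameter count is stable and width-dependent as documented", {
  expect_equal(n_params(build_model(tiny_spec(), seed = 1)),
               n_params(build_model(tiny_spec(), seed = 99)))
  # the default 8-wide, 40-frame variant has a fixed parameter count
  expect_equal(n_params(build_model(model_spec(40, 8), seed = 1)), 794221)
})

test_that("scores are element-wise sigmoids of logits, batch-order preserved", {
  m <- build_model(tiny_spec(), seed = 5)
  set.seed(2)
  one <- array(rnorm(40 * 17 * 17), dim = c(40, 17, 17, 1))
  ten <- array(rep(one, 10), dim = c(40, 17, 17, 10))
  pr <- predict_scores(m, ten)
  expect_true(all(pr$scores > 0 & pr$scores < 1))
  # a duplicated thumbnail gives identical score rows (stateless inference)
  expect_equal(apply(pr$scores, 2, function(col) max(col) - min(col)),
               setNames(rep(0, 5), event_classes()))
  # scores are NOT softmax-normalized: rows need not sum to 1
  expect_false(isTRUE(all.equal(rowSums(pr$scores), rep(1, 10))))
  # sigmoid(0) = 0.5 and the saturation limit
  expect_equal(1 / (1 + exp(0)), 0.5)
  expect_equal(1 / (1 + exp(-30)), 1, tolerance = 1e-12)
})

test_that("the training loop memorizes a tiny labeled set", {
  set.seed(6)
  n <- 40
  thumbs <- array(rnorm(40 * 17 * 17 * n, sd = 0.5), dim = c(40, 17, 17, n))
  labels <- factor(rep(event_classes(), length.out = n), levels = event_classes())
  # plant a strong class-specific pattern so memorization is achievable
  for (i in seq_len(n)) {
    ci <- as.integer(labels[i])
    thumbs[, ci * 2, ci * 3, i] <- thumbs[, ci * 2, ci * 3, i] + 6
  }
  dataset <- structure(list(thumbnails = thumbs, labels = labels,
                            masses = rep(300, n),
                            split = rep(c("train", "val"), c(30, 10)),
                            n_avg = 10L, n_frames = 40L),
                       class = "thumbnail_set")
  m <- build_model(tiny_spec(), seed = 2)
  cfg <- train_config(epochs = 40, seed = 3, scheduler = FALSE,
                      snapshot_best = FALSE, augment = FALSE)
  m <- train_model(m, dataset, cfg)
  expect_gte(max(m$history$train_acc), 0.95)
  # history is complete and finite
  expect_equal(nrow(m$history), 40)
  expect_true(all(is.finite(m$history$train_loss)))
})

test_that("training is reproducible from fixed seeds", {
  set.seed(8)
  n <- 30
  thumbs <- array(rnorm(40 * 17 * 17 * n), dim = c(40, 17, 17, n))
  labels <- factor(rep(event_classes(), length.out = n), levels = event_classes())
  dataset <- structure(list(thumbnails = thumbs, labels = labels,
                            masses = rep(300, n),
                            split = rep(c("train", "val"), c(20, 10)),
                            n_avg = 10L, n_frames = 40L),
                       class = "thumbnail_set")
  run <- function() {
    m <- build_model(tiny_spec(), seed = 11)
    train_model(m, dataset, train_config(epochs = 3, seed = 12))$history
  }
  expect_identical(run(), run())
})

test_that("F1-optimal threshold selection matches a brute-force sweep", {
  # perfectly separated scores: F1 = 1 at any threshold in the gap
  thr <- select_threshold(c(0.9, 0.8, 0.4, 0.3), c(1, 1, 0, 0))
  expect_equal(attr(thr, "f1"), 1.0)
  expect_true(thr > 0.4 && thr <= 0.8)
  # brute-force oracle over randomized instances
  set.seed(9)
  for (rep in 1:20) {
    n <- sample(10:60, 1)
    s <- round(runif(n), 2)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    brute <- max(vapply(unique(s), function(t)
      precision_recall_f1(s, y, t)$f1, 0))
    thr <- select_threshold(s, y)
    expect_equal(attr(thr, "f1"), brute, tolerance = 1e-12)
  }
  expect_error(select_threshold(runif(5), rep(1, 5)), "both classes")
  # the operating point arithmetic: precision 0.61, recall 0.23 -> F1 0.334
  p <- 0.61; r <- 0.23
  expect_equal(2 * p * r / (p + r), 0.334, tolerance = 5e-4)
})

test_that("event filtering partitions by binder score with monotone retention", {
  ev <- data.frame(event_id = 1:6, binder_score = c(0.99, 0.8, 0.5, 0.3, NA, 0.97))
  all_in <- filter_events(ev, 0)
  expect_equal(nrow(all_in$retained), 5)  # NA scores are never retained
  none <- filter_events(ev, 1.01)
  expect_equal(nrow(none$retained), 0)
  expect_equal(nrow(none$discarded), 6)
  # counts preserved and retained flag set
  mid <- filter_events(ev, 0.75)
  expect_equal(nrow(mid$retained) + nrow(mid$discarded), 6)
  expect_true(all(mid$retained$retained))
  expect_true(all(!mid$discarded$retained))
  # raising the threshold never grows the retained set
  sizes <- vapply(seq(0, 1, by = 0.1), function(t)
    nrow(filter_events(ev, t)$retained), 0)
  expect_true(all(diff(sizes) <= 0))
})

test_that("model checkpoints round-trip through save/load", {
  m <- build_model(tiny_spec(), seed = 21)
  path <- tempfile(fileext = ".ckpt")
  save_model(m, path)
  m2 <- load_model(path)
  set.seed(3)
  probe <- array(rnorm(40 * 17 * 17 * 2), dim = c(40, 17, 17, 2))
  expect_identical(predict_scores(m, probe)$scores,
                   predict_scores(m2, probe)$scores)
  saveRDS(list(a = 1), path)
  expect_error(load_model(path), "checkpoint")
  unlink(path)
})

test_that("the 80-frame (160 ms) variant accepts its own input length", {
  m80 <- build_model(model_spec(n_frames = 80, base_width = 2, hidden = 16),
                     seed = 13)
  set.seed(14)
  x <- array(rnorm(80 * 17 * 17 * 2), dim = c(80, 17, 17, 2))
  pr <- predict_scores(m80, x)
  expect_equal(dim(pr$scores), c(2, 5))
  expect_true(all(is.finite(pr$scores)))
  # the two variants reject each other's frame counts
  x40 <- array(rnorm(40 * 17 * 17), dim = c(40, 17, 17, 1))
  expect_error(predict_scores(m80, x40), "expects 80")
})
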