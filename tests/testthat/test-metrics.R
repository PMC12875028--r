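test_that("confusion matrices count correctly and define accuracy", {
  cls <- event_classes()
  all_right <- confusion_matrix(cls, cls)
  expect_equal(diag(all_right), setNames(rep(1L, 5), cls))
  expect_equal(attr(all_right, "accuracy"), 1)
  swapped <- confusion_matrix(c("binder", "unbinder"), c("unbinder", "binder"))
  expect_equal(attr(swapped, "accuracy"), 0)
  expect_equal(swapped["binder", "unbinder"], 1L)
  expect_error(confusion_matrix("binder", "spinner"), "unknown label")
  expect_error(confusion_matrix(cls, cls[1:3]), "equal length")
  # random predictions on a balanced 5-class set: accuracy ~ 0.2 (binomial)
  set.seed(8)
  n <- 10000
  truth <- sample(cls, n, replace = TRUE)
  pred <- sample(cls, n, replace = TRUE)
  acc <- attr(confusion_matrix(truth, pred), "accuracy")
  expect_lt(abs(acc - 0.2), 3 * sqrt(0.2 * 0.8 / n))
  # accuracy = 1 - Hamming error rate
  expect_equal(acc, 1 - mean(truth != pred))
})

test_that("ROC/AUC agree with hand values and the pairwise oracle", {
  # perfectly separating scores
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1.0)
  # worked example: AUC = P(score_pos > score_neg) over the 4 label pairs
  expect_equal(roc_auc(c(0.9, 0.7, 0.6, 0.2), c(1, 0, 1, 0))$auc, 0.75)
  expect_error(roc_auc(runif(5), rep(1, 5)), "both classes")
  # curve is monotone nondecreasing in both coordinates
  set.seed(17)
  r <- roc_auc(rnorm(200), rbinom(200, 1, 0.4))
  expect_true(all(diff(r$curve$fpr) >= 0))
  expect_true(all(diff(r$curve$tpr) >= 0))
  # label-independent scores: AUC ~ 0.5
  set.seed(18)
  r2 <- roc_auc(rnorm(10000), rbinom(10000, 1, 0.5))
  expect_lt(abs(r2$auc - 0.5), 0.02)
})

test_that("AUC equals the exact pairwise statistic on random instances with ties", {
  pairwise_auc <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    mean(cmp)
  }
  set.seed(23)
  for (rep in 1:25) {
    n <- sample(10:200, 1)
    s <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # forces ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(roc_auc(s, y)$auc, pairwise_auc(s, y), tolerance = 1e-12)
  }
})

test_that("precision/recall/F1 arithmetic matches the definitions", {
  # recall = TP / (TP + FN)
  r <- precision_recall_f1(c(1, 1, 1, 0), c(1, 1, 1, 1), threshold = 0.5)
  expect_equal(r$recall, 0.75)
  # precision = recall = 0.5 -> F1 = 0.5
  r2 <- precision_recall_f1(c(0.9, 0.9, 0.1, 0.1), c(1, 0, 1, 0), 0.5)
  expect_equal(r2$precision, 0.5)
  expect_equal(r2$recall, 0.5)
  expect_equal(r2$f1, 0.5)
  # counts built to the low-mass operating point: TP 61, FP 39, FN 204
  s <- c(rep(0.99, 61), rep(0.99, 39), rep(0.1, 204), rep(0.1, 100))
  y <- c(rep(1, 61), rep(0, 39), rep(1, 204), rep(0, 100))
  r3 <- precision_recall_f1(s, y, 0.5)
  expect_equal(r3$precision, 0.61)
  expect_equal(r3$recall, 61 / 265, tolerance = 1e-9)
  # nothing retained: precision undefined sentinel, F1 = 0
  r4 <- precision_recall_f1(c(0.1, 0.2), c(1, 0), 0.9)
  expect_true(is.na(r4$precision))
  expect_equal(r4$f1, 0)
})

test_that("mass histograms bin negatives, conserve counts and mirror symmetric input", {
  h <- mass_histogram(c(101, 102, 103), bin_width = 10)
  expect_equal(sum(h$counts > 0), 1)
  expect_equal(h$n, 3)
  sym <- c(-295, -175, -55, 55, 175, 295)
  hs <- mass_histogram(sym, bin_width = 20, range = c(-310, 310))
  expect_equal(hs$counts, rev(hs$counts))
  expect_equal(mass_histogram(numeric(0))$n, 0)
  # Gaussian sample: bin counts inside Poisson 99% bands of the density oracle
  set.seed(31)
  m <- rnorm(10000, 500, 10)
  hg <- mass_histogram(m, bin_width = 5, range = c(450, 550))
  expected <- 10000 * (pnorm(hg$breaks[-1], 500, 10) -
                       pnorm(head(hg$breaks, -1), 500, 10))
  inside <- hg$counts >= qpois(0.005, expected) &
            hg$counts <= qpois(0.995, expected)
  expect_gt(mean(inside), 0.9)
})

test_that("Gaussian peak fits recover FWHM and resolving power in closed form", {
  # exact Gaussian counts: mean 360, sigma chosen so FWHM = 36, m/dm = 10
  sigma <- 36 / (2 * sqrt(2 * log(2)))
  expect_equal(sigma, 15.2888, tolerance = 1e-4)
  mids <- seq(250, 470, by = 5)
  counts <- round(5000 * exp(-(mids - 360)^2 / (2 * sigma^2)))
  h <- structure(list(breaks = c(mids - 2.5, max(mids) + 2.5), mids = mids,
                      counts = counts, bin_width = 5, n = sum(counts)),
                 class = "mass_histogram")
  pk <- fit_peak(h, c(270, 450))
  expect_equal(pk$mean, 360, tolerance = 0.01)
  expect_equal(pk$fwhm, 36, tolerance = 0.05)
  expect_equal(pk$resolving_power, 10, tolerance = 0.01)
  # resolving power 10 at 180 kDa means FWHM 18 kDa
  expect_equal(180 / 10, 18)
  # sampled Gaussian: FWHM within 5% of truth
  set.seed(41)
  pk2 <- fit_peak(rnorm(5000, 180, 18 / 2.3548), c(120, 240), bin_width = 2)
  expect_equal(pk2$fwhm, 18, tolerance = 0.05 * 18)
  expect_error(fit_peak(rnorm(30, 100, 5), c(80, 120)), "events in the peak")
})

test_that("resolving power is invariant under mass-axis rescaling", {
  set.seed(43)
  m <- rnorm(4000, 180, 8)
  p1 <- fit_peak(m, c(140, 220), bin_width = 2)
  p2 <- fit_peak(10 * m, 10 * c(140, 220), bin_width = 20)
  expect_equal(p1$resolving_power, p2$resolving_power, tolerance = 0.02)
})

test_that("valley-to-peak ratios follow the definition and the mixture oracle", {
  # synthetic histogram with peak heights 100 and 80, valley minimum 8
  mids <- seq(5, 295, by = 10)
  counts <- rep(0L, length(mids))
  counts[mids > 50 & mids < 250] <- 30L
  counts[mids == 95] <- 100L
  counts[mids == 205] <- 80L
  counts[mids == 155] <- 8L
  h <- structure(list(breaks = c(mids - 5, 300), mids = mids, counts = counts,
                      bin_width = 10, n = sum(counts)),
                 class = "mass_histogram")
  v <- valley_to_peak(h, c(50, 140), c(160, 260), smoothing = 0)
  expect_equal(v$vpr, 0.10, tolerance = 1e-9)
  expect_false(v$resolved_10)  # criterion is strict: drops *below* 10%
  expect_true(v$resolved_30)

  # two equal unit Gaussians: VPR from the closed-form mixture at the midpoint
  two_gauss <- function(sep_fwhm) {
    fwhm <- 20; sigma <- fwhm / 2.3548
    mu1 <- 100; mu2 <- mu1 + sep_fwhm * fwhm
    mids <- seq(40, 260, by = 1)
    dens <- dnorm(mids, mu1, sigma) + dnorm(mids, mu2, sigma)
    counts <- round(1e5 * dens)
    h <- structure(list(breaks = c(mids - 0.5, max(mids) + 0.5), mids = mids,
                        counts = counts, bin_width = 1, n = sum(counts)),
                   class = "mass_histogram")
    valley_to_peak(h, c(mu1 - 15, mu1 + 8), c(mu2 - 8, mu2 + 15), smoothing = 0)
  }
  v2 <- two_gauss(2)
  mid_oracle <- (dnorm(0, 0, 20 / 2.3548) + dnorm(40, 0, 20 / 2.3548))
  peak_oracle <- dnorm(0, 0, 20 / 2.3548) + dnorm(40, 0, 20 / 2.3548) # at peak:
  # density at a peak centre = phi(0) + phi(sep)
  sigma <- 20 / 2.3548
  oracle_vpr <- (2 * dnorm(20, 0, sigma)) / (dnorm(0, 0, sigma) + dnorm(40, 0, sigma))
  expect_equal(v2$vpr, oracle_vpr, tolerance = 0.02)
  # widely separated peaks: negligible valley
  expect_lt(two_gauss(5)$vpr, 0.001)
  # VPR decreases monotonically with separation
  vprs <- vapply(c(1.2, 1.6, 2, 2.5, 3), function(s) two_gauss(s)$vpr, 0)
  expect_true(all(diff(vprs) < 0))
})

test_that("mass_error_summary matches events to truth and reports all classes", {
  truth <- data.frame(label = c("binder", "binder", "unbinder"),
                      mass_kda = c(180, 180, 180),
                      x0_px = c(10, 30, 50), y0_px = c(10, 30, 50),
                      t0_frame = c(40, 80, 120))
  events <- data.frame(x = c(10.3, 30.1), y = c(9.8, 30.0), t = c(30, 71),
                       mass = c(178, 120), residual = c(0.01, 0.2))
  s <- mass_error_summary(events, truth, tolerance = 0.05, n_avg = 10)
  expect_equal(s$binder, 0.5)              # one within 5%, one at 33% error
  expect_equal(s$pooled_suboptimal, 0)     # unbinder unmatched -> error 100%
  expect_equal(sum(!s$table$matched), 1)
  expect_equal(nrow(s$unmatched_detections), 0)
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(71)
  for (rep in 1:5) {
    s <- runif(150)
    y <- rbinom(150, 1, 0.5)
    ours <- roc_auc(s, y)$auc
    ref <- as.numeric(suppressMessages(pROC::auc(pROC::roc(y, s, quiet = TRUE, direction = "<"))))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})
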