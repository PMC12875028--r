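#' Confusion matrix over the five event classes
#'
#' @param true_labels,predicted_labels equal-length vectors of class labels
#'   (factors or characters over [event_classes()], or a common label set).
#' @param classes the label universe (rows = true, columns = predicted).
#' @return Integer matrix with attribute `accuracy` (= trace / total).
#' @export
confusion_matrix <- function(true_labels, predicted_labels,
                             classes = event_classes()) {
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors must have equal length")
  tl <- as.character(true_labels); pl <- as.character(predicted_labels)
  bad <- setdiff(unique(c(tl, pl)), classes)
  if (length(bad) > 0) stop("unknown label value(s): ", paste(bad, collapse = ", "))
  m <- table(factor(tl, levels = classes), factor(pl, levels = classes))
  m <- matrix(as.integer(m), nrow = length(classes),
              dimnames = list(true = classes, predicted = classes))
  attr(m, "accuracy") <- sum(diag(m)) / max(1, sum(m))
  m
}

#' ROC curve and area under the curve
#'
#' True and false positive rates `TPR = TP/(TP+FN)`, `FPR = FP/(FP+TN)` at
#' every unique score threshold; the AUC is computed by the trapezoid rule
#' and equals the pairwise probability `P(score_pos > score_neg) + 0.5 *
#' P(tie)`.
#'
#' @param scores numeric classification scores (higher = more positive).
#' @param binary_labels binary ground truth (1/TRUE = positive).
#' @return List with `curve` (data.frame threshold/fpr/tpr) and `auc`.
#' @export
roc_auc <- function(scores, binary_labels) {
  y <- as.integer(as.logical(binary_labels))
  if (length(unique(y)) < 2) stop("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- y[o]
  npos <- sum(y); nneg <- length(y) - npos
  idx <- which(!duplicated(s, fromLast = TRUE))
  tpr <- cumsum(y)[idx] / npos
  fpr <- cumsum(1 - y)[idx] / nneg
  curve <- data.frame(threshold = c(Inf, s[idx]), fpr = c(0, fpr),
                      tpr = c(0, tpr))
  auc <- sum(diff(curve$fpr) * (head(curve$tpr, -1) + tail(curve$tpr, -1)) / 2)
  list(curve = curve, auc = auc)
}

#' Precision, recall and F1 at a fixed threshold
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)` and `F1 = 2 P R/(P + R)`.
#' When nothing is retained (`TP + FP = 0`) precision is `NA` and F1 is 0.
#'
#' @param scores numeric scores.
#' @param binary_labels binary ground truth.
#' @param threshold retain `score >= threshold`.
#' @return Named list `precision`, `recall`, `f1`, and the four counts.
#' @export
precision_recall_f1 <- function(scores, binary_labels, threshold) {
  y <- as.logical(binary_labels)
  pos <- scores >= threshold
  tp <- sum(pos & y); fp <- sum(pos & !y)
  fn <- sum(!pos & y); tn <- sum(!pos & !y)
  precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) 0
        else 2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1,
       tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Fixed-width mass histogram
#'
#' Bins event masses (negative apparent masses from unbinding artifacts
#' included) on a fixed grid aligned to multiples of `bin_width`.
#'
#' @param masses numeric masses (kDa).
#' @param bin_width bin width (kDa).
#' @param range optional `c(lo, hi)` mass range; defaults to the data range.
#' @return A `mass_histogram`: list with `breaks`, `mids`, `counts`,
#'   `bin_width`.
#' @export
mass_histogram <- function(masses, bin_width = 5, range = NULL) {
  stopifnot(bin_width > 0)
  masses <- masses[is.finite(masses)]
  if (is.null(range)) {
    if (length(masses) == 0) range <- c(0, bin_width)
    else range <- range(masses)
  }
  lo <- floor(range[1] / bin_width) * bin_width
  hi <- ceiling(range[2] / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  inside <- masses >= lo & masses <= hi
  counts <- if (any(inside))
    as.integer(table(cut(masses[inside], breaks, include.lowest = TRUE,
                         right = FALSE)))
  else integer(length(breaks) - 1)
  structure(list(breaks = breaks, mids = breaks[-1] - bin_width / 2,
                 counts = counts, bin_width = bin_width, n = sum(counts)),
            class = "mass_histogram")
}

#' Gaussian peak fit and resolving power
#'
#' Fits `A * exp(-(m - mu)^2 / (2 sigma^2))` to the histogram counts inside
#' `peak_window` by least squares. The full width at half maximum is
#' `FWHM = 2 sqrt(2 ln 2) sigma` and the resolving power `mu / FWHM`, the
#' standard mass-spectrometry-style definition `m / delta_m`.
#'
#' @param x a `mass_histogram`, or a numeric vector of masses (then binned
#'   with `bin_width`).
#' @param peak_window `c(lo, hi)` mass window containing one clear peak.
#' @param bin_width bin width used when `x` is a mass vector.
#' @param min_counts minimum number of events required inside the window.
#' @return A `peak_stats` list: `mean`, `sigma`, `fwhm`, `resolving_power`,
#'   `amplitude`, `counts`, `window`.
#' @export
fit_peak <- function(x, peak_window, bin_width = 5, min_counts = 50) {
  h <- if (inherits(x, "mass_histogram")) x else
    mass_histogram(x, bin_width, range = peak_window)
  sel <- h$mids >= peak_window[1] & h$mids <= peak_window[2]
  if (!any(sel)) stop("peak window contains no histogram bins")
  mids <- h$mids[sel]; counts <- h$counts[sel]
  n_in <- sum(counts)
  if (n_in < min_counts)
    stop("only ", n_in, " events in the peak window (need >= ", min_counts, ")")
  if (max(counts) <= 0 || which.max(counts) %in% c(0L))
    stop("no maximum inside the peak window")
  # moment-based start values, then Gauss-Newton via nls
  mu0 <- sum(mids * counts) / sum(counts)
  s0 <- sqrt(max(sum((mids - mu0)^2 * counts) / sum(counts), h$bin_width^2 / 12))
  a0 <- max(counts)
  df <- data.frame(m = mids, c = counts)
  fit <- try(nls(c ~ A * exp(-(m - mu)^2 / (2 * s^2)), data = df,
                 start = list(A = a0, mu = mu0, s = s0),
                 control = list(maxiter = 200, warnOnly = FALSE)),
             silent = TRUE)
  if (inherits(fit, "try-error")) {
    # fall back to a direct optimizer before declaring non-convergence
    obj <- function(p) sum((counts - p[1] * exp(-(mids - p[2])^2 / (2 * p[3]^2)))^2)
    op <- optim(c(a0, mu0, s0), obj)
    if (op$convergence != 0) stop("Gaussian peak fit did not converge")
    cf <- c(A = op$par[1], mu = op$par[2], s = abs(op$par[3]))
  } else cf <- coef(fit)
  sigma <- abs(unname(cf["s"]))
  fwhm <- 2 * sqrt(2 * log(2)) * sigma
  structure(list(mean = unname(cf["mu"]), sigma = sigma, fwhm = fwhm,
                 resolving_power = unname(cf["mu"]) / fwhm,
                 amplitude = unname(cf["A"]), counts = n_in,
                 window = peak_window),
            class = "peak_stats")
}

#' @export
print.peak_stats <- function(x, ...) {
  cat(sprintf("Peak %.1f kDa, FWHM %.1f kDa, resolving power %.2f (%d events)\n",
              x$mean, x$fwhm, x$resolving_power, x$counts))
  invisible(x)
}

# Gaussian-kernel smoothing of histogram counts, bandwidth in bins
smooth_counts <- function(counts, bandwidth = 1) {
  if (bandwidth <= 0) return(counts)
  k <- dnorm(seq(-ceiling(4 * bandwidth), ceiling(4 * bandwidth)), sd = bandwidth)
  k <- k / sum(k)
  n <- length(counts)
  padded <- c(rep(counts[1], length(k) %/% 2), counts,
              rep(counts[n], length(k) %/% 2))
  as.numeric(stats::filter(padded, k, sides = 2))[
    (length(k) %/% 2 + 1):(length(k) %/% 2 + n)]
}

#' Valley-to-peak ratio of two partially resolved peaks
#'
#' The VPR is the minimum of the (smoothed) histogram between the two peak
#' maxima divided by the height of the smaller peak; peaks are "resolved"
#' under the 10% (or 30%) criterion when the valley drops below that
#' fraction of the smaller peak.
#'
#' @param hist a `mass_histogram`.
#' @param peak1_window,peak2_window `c(lo, hi)` windows of the two peaks.
#' @param smoothing Gaussian smoothing bandwidth in bins (0 = none).
#' @return A `valley_stats` list: peak positions/heights, `valley`, `vpr`,
#'   `resolved_10`, `resolved_30`; `vpr` is `NA` when no interior minimum
#'   exists.
#' @export
valley_to_peak <- function(hist, peak1_window, peak2_window, smoothing = 1) {
  stopifnot(inherits(hist, "mass_histogram"))
  sm <- smooth_counts(hist$counts, smoothing)
  pick <- function(w) {
    sel <- which(hist$mids >= w[1] & hist$mids <= w[2])
    if (length(sel) == 0) stop("peak window outside histogram")
    i <- sel[which.max(sm[sel])]
    c(idx = i, height = sm[i], m = hist$mids[i])
  }
  p1 <- pick(peak1_window); p2 <- pick(peak2_window)
  if (p1["m"] > p2["m"]) { tmp <- p1; p1 <- p2; p2 <- tmp }
  between <- (p1["idx"] + 1):(p2["idx"] - 1)
  if (p2["idx"] - p1["idx"] < 2)
    return(structure(list(m1 = p1[["m"]], m2 = p2[["m"]], h1 = p1[["height"]],
                          h2 = p2[["height"]], valley = NA_real_,
                          vpr = NA_real_, resolved_10 = FALSE,
                          resolved_30 = FALSE), class = "valley_stats"))
  v <- min(sm[between])
  vpr <- v / min(p1[["height"]], p2[["height"]])
  structure(list(m1 = p1[["m"]], m2 = p2[["m"]], h1 = p1[["height"]],
                 h2 = p2[["height"]], valley = v, vpr = vpr,
                 resolved_10 = vpr < 0.10, resolved_30 = vpr < 0.30),
            class = "valley_stats")
}

#' @export
print.valley_stats <- function(x, ...) {
  cat(sprintf("Peaks %.0f / %.0f kDa: VPR %.3f (resolved: 30%% %s, 10%% %s)\n",
              x$m1, x$m2, x$vpr, x$resolved_30, x$resolved_10))
  invisible(x)
}

#' Per-class mass-error summary against ground truth
#'
#' Matches detected events to simulated ground truth by position and time,
#' then reports per class the fraction of events whose relative mass error
#' `|fitted - true| / true` is below `tolerance`. Unmatched ground-truth
#' events are reported separately (as errors of 100%, i.e. fitted mass 0,
#' they never count as within tolerance); unmatched detections are returned,
#' never silently dropped.
#'
#' @param events data.frame with `x`, `y`, `t`, `mass`.
#' @param truth data.frame with `label`, `mass_kda`, `x0_px`, `y0_px`,
#'   `t0_frame` (raw frame; converted with `n_avg`).
#' @param tolerance relative mass-error tolerance (default 5%).
#' @param match_radius spatial matching radius (px).
#' @param match_window temporal matching window (ratiometric frames).
#' @param n_avg ratiometric substack length.
#' @return List with `per_class` (data.frame class/n/matched/frac_within),
#'   `pooled_suboptimal` fraction, `table` (per-event join) and
#'   `unmatched_detections`.
#' @export
mass_error_summary <- function(events, truth, tolerance = 0.05,
                               match_radius = 2, match_window = NULL,
                               n_avg = 10L) {
  if (is.null(match_window)) match_window <- 2L * n_avg
  k0 <- truth$t0_frame - n_avg  # expected ratiometric peak frame
  matched_event <- rep(NA_integer_, nrow(truth))
  used <- rep(FALSE, nrow(events))
  for (i in seq_len(nrow(truth))) {
    if (nrow(events) == 0) break
    d_ok <- abs(events$x - truth$x0_px[i]) <= match_radius &
      abs(events$y - truth$y0_px[i]) <= match_radius &
      abs(events$t - k0[i]) <= match_window & !used
    if (any(d_ok)) {
      cand <- which(d_ok)
      j <- cand[which.min(abs(events$t[cand] - k0[i]))]
      matched_event[i] <- j
      used[j] <- TRUE
    }
  }
  fitted <- ifelse(is.na(matched_event), 0, events$mass[matched_event])
  rel_err <- abs(fitted - truth$mass_kda) / truth$mass_kda
  tab <- data.frame(label = truth$label, true_mass = truth$mass_kda,
                    fitted_mass = fitted, rel_error = rel_err,
                    matched = !is.na(matched_event),
                    residual = ifelse(is.na(matched_event), NA_real_,
                                      events$residual[matched_event]))
  agg <- do.call(rbind, lapply(split(tab, tab$label), function(g) {
    data.frame(label = g$label[1], n = nrow(g), matched = sum(g$matched),
               frac_within = mean(g$rel_error < tolerance))
  }))
  rownames(agg) <- NULL
  sub <- tab$label != "binder"
  list(per_class = agg,
       pooled_suboptimal = if (any(sub)) mean(tab$rel_error[sub] < tolerance)
                           else NA_real_,
       binder = if (any(!sub)) mean(tab$rel_error[!sub] < tolerance) else NA_real_,
       table = tab,
       unmatched_detections = events[!used, , drop = FALSE])
}
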