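#' Overlayed mass histograms before and after event filtering
#'
#' Standard MP-style figure: the unfiltered mass distribution (including the
#' negative-mass unbinding side) with the retained-event distribution
#' overlaid.
#'
#' @param masses_before all fitted masses (kDa).
#' @param masses_after retained (filtered) masses.
#' @param bin_width histogram bin width (kDa).
#' @param xlim optional mass-axis limits.
#' @param main plot title.
#' @return Invisibly, the two `mass_histogram`s.
#' @export
plot_mass_histogram <- function(masses_before, masses_after = NULL,
                                bin_width = 5, xlim = NULL,
                                main = "Mass histogram") {
  masses_before <- masses_before[is.finite(masses_before)]
  if (is.null(xlim)) xlim <- range(masses_before)
  rng <- xlim
  hb <- mass_histogram(masses_before, bin_width, range = rng)
  graphics::plot(hb$mids, hb$counts, type = "s", col = "firebrick", lwd = 2,
                 xlab = "mass (kDa)", ylab = "counts", main = main,
                 xlim = xlim)
  ha <- NULL
  if (!is.null(masses_after) && length(masses_after) > 0) {
    ha <- mass_histogram(masses_after[is.finite(masses_after)], bin_width,
                         range = rng)
    graphics::lines(ha$mids, ha$counts, type = "s", col = "black", lwd = 2)
    graphics::legend("topright", legend = c("before filtering", "after filtering"),
                     col = c("firebrick", "black"), lwd = 2, bty = "n")
  }
  invisible(list(before = hb, after = ha))
}

#' Plot a training history
#'
#' @param history data.frame from a trained model (`model$history`).
#' @return Invisibly, `history`.
#' @export
plot_training_history <- function(history) {
  graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(mfrow = c(1, 1)))
  graphics::plot(history$epoch, history$train_loss, type = "b", pch = 16,
                 xlab = "epoch", ylab = "loss", main = "Loss",
                 ylim = range(c(history$train_loss, history$val_loss), na.rm = TRUE))
  graphics::lines(history$epoch, history$val_loss, type = "b", pch = 1, col = 2)
  graphics::plot(history$epoch, history$train_acc, type = "b", pch = 16,
                 xlab = "epoch", ylab = "accuracy", main = "Accuracy",
                 ylim = c(0, 1))
  graphics::lines(history$epoch, history$val_acc, type = "b", pch = 1, col = 2)
  graphics::legend("bottomright", legend = c("train", "validation"),
                   col = c(1, 2), pch = c(16, 1), bty = "n")
  invisible(history)
}
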