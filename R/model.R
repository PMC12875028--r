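#' Model specification for the 3D residual classifier
#'
#' The network follows the 50-layer 3D residual layout: a `7 x 3 x 3` stem
#' convolution with batch normalization, ReLU and `3^3` max pooling, four
#' residual stages of 3, 4, 6 and 3 bottleneck blocks (each three 3D
#' convolutions with batch normalization, ReLU at the block end, projection
#' shortcut with downsampling on the first block of each stage), then global
#' average pooling and two fully connected layers reducing to 5 class
#' outputs. `base_width` sets the channel width of the first stage (the
#' canonical layout uses 64; the package default of 8 keeps the identical
#' topology at CPU-friendly cost -- width enters compute quadratically while
#' the spatiotemporal receptive fields are unchanged). Because the 17 x 17
#' input is small, the stem uses spatial stride 1; stage downsampling uses
#' stride 2 in all three dimensions.
#'
#' @param n_frames thumbnail length (40 for 40 ms integration at 726 fps,
#'   80 for 160 ms).
#' @param base_width channel width of stage 1.
#' @param n_classes number of output classes.
#' @param hidden width of the penultimate fully connected layer.
#' @return A `model_spec`.
#' @export
model_spec <- function(n_frames = 40L, base_width = 8L, n_classes = 5L,
                       hidden = 256L) {
  stopifnot(n_frames >= 8, base_width >= 1, n_classes >= 2, hidden >= 1)
  structure(list(n_frames = as.integer(n_frames),
                 base_width = as.integer(base_width),
                 n_classes = as.integer(n_classes),
                 hidden = as.integer(hidden)),
            class = "model_spec")
}

#' Build a randomly initialized 3D residual classifier
#'
#' Weights are He-initialized from a deterministic stream: the same seed
#' always yields the same initial parameters (and hence identical logits on
#' a fixed probe batch).
#'
#' @param spec a [model_spec()].
#' @param seed integer initialization seed.
#' @return An `r3d_model` handle.
#' @export
build_model <- function(spec = model_spec(), seed = 1L) {
  ptr <- cpp_net_new(spec$n_frames, spec$base_width, spec$n_classes,
                     as.integer(seed), spec$hidden)
  structure(list(ptr = ptr, spec = spec, seed = as.integer(seed),
                 trained = FALSE, history = NULL),
            class = "r3d_model")
}

#' @export
print.r3d_model <- function(x, ...) {
  info <- cpp_net_info(x$ptr)
  cat(sprintf(
    "3D residual classifier: %d-frame input, base width %d, %d bottleneck blocks, %s parameters%s\n",
    info$n_frames, info$base_width, info$n_blocks,
    format(info$n_params, big.mark = ","),
    if (x$trained) " (trained)" else " (untrained)"))
  invisible(x)
}

#' Number of trainable parameters
#' @param model an `r3d_model`.
#' @return Integer parameter count.
#' @export
n_params <- function(model) cpp_net_nparams(model$ptr)

#' Training configuration
#'
#' The reference recipe: cross-entropy loss, plain stochastic gradient
#' descent at learning rate 0.1, batch size 10 with random shuffling,
#' gradient clipping to a maximum global norm of 0.5, a reduce-on-plateau
#' schedule (factor 0.1 after 5 epochs without validation-loss improvement)
#' and 20 epochs, keeping the snapshot with the best validation accuracy.
#'
#' @param epochs number of epochs.
#' @param batch_size minibatch size.
#' @param lr initial learning rate.
#' @param clip maximum gradient norm (0 disables clipping).
#' @param patience plateau patience in epochs.
#' @param factor learning-rate reduction factor.
#' @param seed shuffling seed.
#' @param scheduler enable the plateau scheduler.
#' @param snapshot_best restore the best-validation-accuracy snapshot.
#' @param augment randomly flip/rotate the spatial plane of each training
#'   thumbnail (dihedral group). The simulated event distribution is exactly
#'   invariant under these transforms (positions are jittered uniformly and
#'   motion directions are isotropic), so augmentation enlarges the effective
#'   training set without changing the data distribution.
#' @return A `train_config`.
#' @export
train_config <- function(epochs = 20L, batch_size = 10L, lr = 0.1,
                         clip = 0.5, patience = 5L, factor = 0.1, seed = 1L,
                         scheduler = TRUE, snapshot_best = TRUE,
                         augment = TRUE) {
  stopifnot(epochs >= 1, batch_size >= 1, lr > 0, clip >= 0, patience >= 1,
            factor > 0, factor < 1)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, clip = clip, patience = as.integer(patience),
                 factor = factor, seed = as.integer(seed),
                 scheduler = scheduler, snapshot_best = snapshot_best,
                 augment = isTRUE(augment)),
            class = "train_config")
}

#' Train the classifier on a labeled thumbnail set
#'
#' Thumbnails are z-score standardized per thumbnail, split per the set's
#' train/validation assignment, and the model is trained with the recipe in
#' `cfg`. The per-epoch history (train/validation loss and accuracy,
#' learning rate) is attached to the returned model.
#'
#' @param model an `r3d_model`.
#' @param dataset a `thumbnail_set` from [generate_training_set()].
#' @param cfg a [train_config()].
#' @param verbose print per-epoch progress.
#' @return The trained model (history in `model$history`).
#' @export
train_model <- function(model, dataset, cfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "r3d_model"), inherits(dataset, "thumbnail_set"))
  if (dataset$n_frames != model$spec$n_frames)
    stop("dataset thumbnails have ", dataset$n_frames,
         " frames but the model expects ", model$spec$n_frames)
  tr <- dataset$split == "train"
  va <- dataset$split == "val"
  if (!any(tr) || !any(va)) stop("both train and validation splits must be non-empty")
  X <- standardize_array(dataset$thumbnails)
  y <- as.integer(dataset$labels) - 1L
  hist <- cpp_net_train(model$ptr,
                        X[, , , tr, drop = FALSE], y[tr], sum(tr),
                        X[, , , va, drop = FALSE], y[va], sum(va),
                        cfg$epochs, cfg$batch_size, cfg$lr, cfg$clip,
                        cfg$patience, cfg$factor, cfg$seed,
                        cfg$snapshot_best, cfg$scheduler, verbose, cfg$augment)
  model$trained <- TRUE
  model$history <- data.frame(epoch = seq_along(hist$train_loss),
                              train_loss = hist$train_loss,
                              train_acc = hist$train_acc,
                              val_loss = hist$val_loss,
                              val_acc = hist$val_acc,
                              lr = hist$lr)
  model$best_epoch <- hist$best_epoch
  model$best_val_acc <- hist$best_val_acc
  model
}

#' Class scores for a batch of thumbnails
#'
#' Runs the network in evaluation mode and passes the logits through an
#' element-wise sigmoid: scores lie in (0, 1) per class and are not
#' softmax-normalized, so each class score can be thresholded one-vs-rest.
#' The predicted class is the argmax. Thumbnails are standardized unless
#' `standardized = TRUE`.
#'
#' @param model a trained `r3d_model`.
#' @param thumbnails array `[n_frames, 17, 17, N]` (or `[n_frames, 17, 17]`
#'   for a single thumbnail), or a `thumbnail_set`.
#' @param standardized set `TRUE` if thumbnails are already z-scored.
#' @return List with `scores` (N x 5 matrix, columns named by class) and
#'   `predicted` (factor).
#' @export
predict_scores <- function(model, thumbnails, standardized = FALSE) {
  stopifnot(inherits(model, "r3d_model"))
  if (inherits(thumbnails, "thumbnail_set")) thumbnails <- thumbnails$thumbnails
  if (inherits(thumbnails, "mp_thumbnail")) thumbnails <- thumbnails$values
  d <- dim(thumbnails)
  if (length(d) == 3) {
    thumbnails <- array(thumbnails, dim = c(d, 1))
    d <- dim(thumbnails)
  }
  if (d[1] != model$spec$n_frames)
    stop("thumbnails have ", d[1], " frames but the model expects ",
         model$spec$n_frames)
  if (!standardized) thumbnails <- standardize_array(thumbnails)
  logits <- cpp_net_forward(model$ptr, thumbnails, d[1], d[4])
  scores <- 1 / (1 + exp(-logits))
  colnames(scores) <- EVENT_CLASSES[seq_len(ncol(scores))]
  list(scores = scores,
       predicted = factor(EVENT_CLASSES[max.col(logits, ties.method = "first")],
                          levels = EVENT_CLASSES))
}

#' F1-optimal decision threshold for binder selection
#'
#' Sweeps all unique score values as candidate thresholds and returns the
#' one maximizing `F1 = 2 * precision * recall / (precision + recall)` with
#' `precision = TP/(TP+FP)` and `recall = TP/(TP+FN)`. Ties break toward the
#' highest threshold.
#'
#' @param scores numeric scores (e.g. binder scores).
#' @param labels binary indicator (1/TRUE = positive class).
#' @param return_all return the full sweep table instead of the scalar.
#' @return The threshold (attribute `f1` holds the achieved F1), or the
#'   sweep data.frame if `return_all`.
#' @export
select_threshold <- function(scores, labels, return_all = FALSE) {
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2)
    stop("both classes must be present to select a threshold")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  tp <- cumsum(l)
  fp <- cumsum(1 - l)
  npos <- sum(l)
  # threshold at each unique score: all items with score >= threshold retained,
  # i.e. the last occurrence of each distinct value in the descending sort
  idx <- which(!duplicated(s, fromLast = TRUE))
  prec <- tp[idx] / (tp[idx] + fp[idx])
  rec <- tp[idx] / npos
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  tab <- data.frame(threshold = s[idx], precision = prec, recall = rec, f1 = f1)
  if (return_all) return(tab)
  best <- which(f1 == max(f1))[1]  # first = highest threshold among ties
  out <- tab$threshold[best]
  attr(out, "f1") <- tab$f1[best]
  out
}

#' Partition detected events by binder score
#'
#' @param events data.frame with a `binder_score` column.
#' @param binder_threshold retain events with `binder_score >= threshold`.
#' @return List with `retained` and `discarded` data.frames; both carry the
#'   `retained` flag column.
#' @export
filter_events <- function(events, binder_threshold) {
  stopifnot("binder_score" %in% names(events))
  keep <- !is.na(events$binder_score) & events$binder_score >= binder_threshold
  events$retained <- keep
  list(retained = events[keep, , drop = FALSE],
       discarded = events[!keep, , drop = FALSE])
}

#' Score detected events with the classifier
#'
#' Extracts a thumbnail for every detected event, standardizes it and adds
#' the five class scores plus `binder_score` and `predicted` columns. Events
#' whose thumbnail window does not fit inside the movie (too close to an
#' edge or to the stack boundary) receive `NA` scores and are flagged
#' `scoreable = FALSE`.
#'
#' @param events data.frame from [detect_events()].
#' @param rat a ratiometric `movie_stack`.
#' @param model a trained `r3d_model`.
#' @return `events` with score columns appended.
#' @export
classify_events <- function(events, rat, model) {
  n <- nrow(events)
  nf <- model$spec$n_frames
  score_cols <- paste0("score_", EVENT_CLASSES)
  if (n == 0) {
    events[score_cols] <- numeric(0)
    events$binder_score <- numeric(0)
    events$predicted <- character(0)
    events$scoreable <- logical(0)
    return(events)
  }
  thumbs <- array(0, dim = c(nf, 17, 17, n))
  ok <- logical(n)
  for (i in seq_len(n)) {
    th <- try(extract_thumbnail(rat, events$x[i], events$y[i], events$t[i], nf),
              silent = TRUE)
    if (!inherits(th, "try-error") && all(is.finite(th$values)) &&
        var(as.vector(th$values)) > 0) {
      thumbs[, , , i] <- th$values
      ok[i] <- TRUE
    }
  }
  events[score_cols] <- NA_real_
  events$binder_score <- NA_real_
  events$predicted <- NA_character_
  events$scoreable <- ok
  if (any(ok)) {
    pr <- predict_scores(model, thumbs[, , , ok, drop = FALSE])
    events[ok, score_cols] <- pr$scores
    events$binder_score[ok] <- pr$scores[, "binder"]
    events$predicted[ok] <- as.character(pr$predicted)
  }
  events
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single file holding a header (architecture variant,
#' frame count, class names, training history) plus all weights and
#' batch-normalization statistics.
#'
#' @param model an `r3d_model`.
#' @param path file path.
#' @return `load_model` returns a rebuilt `r3d_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "r3d_model"))
  obj <- list(header = list(format = "mpevents-r3d", version = 1L,
                            spec = unclass(model$spec), seed = model$seed,
                            classes = EVENT_CLASSES, trained = model$trained,
                            best_epoch = model$best_epoch,
                            best_val_acc = model$best_val_acc),
              history = model$history,
              params = cpp_net_get_params(model$ptr))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$header$format) || obj$header$format != "mpevents-r3d")
    stop("not an mpevents model checkpoint: ", path)
  spec <- do.call(model_spec, obj$header$spec)
  model <- build_model(spec, obj$header$seed)
  cpp_net_set_params(model$ptr, obj$params)
  model$trained <- isTRUE(obj$header$trained)
  model$history <- obj$history
  model$best_epoch <- obj$header$best_epoch
  model$best_val_acc <- obj$header$best_val_acc
  model
}
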