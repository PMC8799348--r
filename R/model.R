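#' Fit a feature-fusion capsule network
#'
#' Trains the full classifier end-to-end on the train split of a windowed
#' sEMG dataset: windows are featurized into fused inputs (outer-product
#' feature maps plus stacked signal segments, Min-Max normalised per
#' channel), passed through the convolutional fusion front-end, the
#' multilevel convolution block, primary-capsule squashing and dynamic
#' routing, and the margin loss on action-capsule lengths is minimised with
#' Adam.  All randomness (weight initialisation, minibatch shuffling) is
#' governed by `seed`, so two runs with the same seed give identical
#' weights.
#'
#' @param dataset An `semg_dataset` from [generate_experiment()] (or any
#'   list with `windows`, `labels` and `split` of `"train"`/`"test"`).
#' @param squash Squash kind used throughout the network, see
#'   [apply_squash()]; default `"e_squash"`.
#' @param width_profile `"paper"`, `"test"` or `"tiny"`, see
#'   [fficaps_profile()].
#' @param epochs Training epochs (default 30).
#' @param batch_size Minibatch size; 32 matches the displacement protocol,
#'   16 the cross-subject protocol.
#' @param lr Adam learning rate (default 1e-3).
#' @param routing_iters Dynamic-routing iterations (default 3).
#' @param seed Integer seed for weights and shuffling.
#' @param spectral A [spectral_config()] for featurization.
#' @param fusion A [fusion_config()].
#' @param track_test Record test accuracy after every epoch (needs a test
#'   split).
#' @param verbose Print a per-epoch progress line.
#' @return An object of class `"fficaps"` with the trained weights, the
#'   per-epoch `history` (train loss and, optionally, test accuracy), the
#'   class levels and the fitting configuration.
#' @seealso [predict.fficaps()], [evaluate_fficaps()], [run_experiment()]
#' @export
fficaps <- function(dataset, squash = "e_squash", width_profile = "test",
                    epochs = 30L, batch_size = 32L, lr = 1e-3,
                    routing_iters = 3L, seed = 1L,
                    spectral = NULL, fusion = fusion_config(),
                    track_test = TRUE, verbose = FALSE) {
  stopifnot(batch_size >= 1L, epochs >= 1L)
  squash <- match.arg(squash, c("squash", "hsquash", "strict_squash",
                                "squash_4", "e_squash"))
  labels <- as.factor(dataset$labels)
  lev <- levels(labels)
  n_channels <- nrow(dataset$windows[[1L]]$data)
  fs <- dataset$windows[[1L]]$fs
  if (is.null(spectral)) spectral <- spectral_config(fs = fs)
  prof <- fficaps_profile(width_profile, n_class = length(lev),
                          n_channels = n_channels,
                          routing_iters = routing_iters)
  tr <- dataset$split == "train"
  te <- dataset$split == "test"
  fused <- featurize_windows(dataset$windows, spectral, fusion)
  Xtr <- .stack_fused(fused[tr])
  ytr <- as.integer(labels[tr])
  Xte <- if (any(te)) .stack_fused(fused[te]) else NULL
  yte <- if (any(te)) as.integer(labels[te]) else NULL

  wts <- fficaps_init(prof, seed = seed)
  model <- list(params = wts$params, plans = wts$plans, profile = prof,
                kind = squash)
  opt <- .adam_init(model$params, lr = lr)
  n <- length(ytr)
  hist <- list(loss = numeric(epochs),
               test_accuracy = if (track_test && !is.null(Xte))
                 numeric(epochs) else NULL)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0L)
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      fw <- .ff_forward(model, Xtr$f[idx, , drop = FALSE],
                        Xtr$s[idx, , drop = FALSE], keep = TRUE)
      lg <- .margin_loss_grad(fw$lengths, ytr[idx])
      if (!is.finite(lg$loss))
        stop(sprintf("training diverged (non-finite loss at epoch %d)", ep))
      grads <- .ff_backward(model, fw, lg$dlen)
      model$params <- .adam_step(model$params, grads, opt)
      losses <- c(losses, lg$loss)
    }
    hist$loss[ep] <- mean(losses)
    if (!is.null(hist$test_accuracy)) {
      pr <- .predict_batches(model, Xte$f, Xte$s)
      hist$test_accuracy[ep] <- mean(pr$class == yte)
    }
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f%s", ep, hist$loss[ep],
                      if (is.null(hist$test_accuracy)) "" else
                        sprintf("  test acc %.3f", hist$test_accuracy[ep])))
  }
  structure(list(
    params = model$params, plans = model$plans, profile = prof,
    squash = squash, levels = lev, history = hist,
    config = list(epochs = epochs, batch_size = batch_size, lr = lr,
                  seed = seed, width_profile = width_profile,
                  routing_iters = routing_iters),
    spectral = spectral, fusion = fusion,
    dataset_config = dataset$config), class = "fficaps")
}

# minibatched prediction to bound memory
.predict_batches <- function(model, Xf, Xs, chunk = 128L) {
  n <- nrow(Xf)
  cls <- integer(n)
  lens <- matrix(0, n, model$profile$n_class)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    fw <- .ff_forward(model, Xf[idx, , drop = FALSE],
                      Xs[idx, , drop = FALSE], keep = FALSE)
    lens[idx, ] <- fw$lengths
    cls[idx] <- max.col(fw$lengths, ties.method = "first")
  }
  list(class = cls, lengths = lens)
}

#' Predict gestures for new windows
#'
#' @param object A fitted [fficaps()] model.
#' @param newdata An `semg_dataset`, a list of windows, or a list of fused
#'   inputs from [featurize_windows()].
#' @param type `"class"` for predicted gesture labels, `"lengths"` for the
#'   matrix of action-capsule lengths (one row per window, one column per
#'   gesture).
#' @param ... Unused.
#' @return Factor of predicted gestures, or a numeric matrix of capsule
#'   lengths in `[0, 1)`.
#' @export
predict.fficaps <- function(object, newdata, type = c("class", "lengths"),
                            ...) {
  type <- match.arg(type)
  windows <- if (inherits(newdata, "semg_dataset")) newdata$windows
             else newdata
  fused <- if (inherits(windows[[1L]], "fused_input")) windows
           else featurize_windows(windows, object$spectral, object$fusion)
  X <- .stack_fused(fused)
  model <- list(params = object$params, plans = object$plans,
                profile = object$profile, kind = object$squash)
  pr <- .predict_batches(model, X$f, X$s)
  if (type == "lengths") {
    colnames(pr$lengths) <- object$levels
    return(pr$lengths)
  }
  factor(object$levels[pr$class], levels = object$levels)
}

#' @export
print.fficaps <- function(x, ...) {
  cat("Feature-fusion capsule network (FFiCAPS)\n")
  cat(sprintf("  classes: %s\n", paste(x$levels, collapse = ", ")))
  cat(sprintf("  width profile: %s (C = %d, %d primary capsules)\n",
              x$config$width_profile, x$profile$C, x$profile$n_primary))
  cat(sprintf("  squash: %s, routing iterations: %d\n",
              x$squash, x$profile$routing_iters))
  cat(sprintf("  trained %d epochs (batch %d, lr %g, seed %d), final loss %.4f\n",
              x$config$epochs, x$config$batch_size, x$config$lr,
              x$config$seed, utils::tail(x$history$loss, 1L)))
  if (!is.null(x$history$test_accuracy))
    cat(sprintf("  final test accuracy: %.1f%%\n",
                100 * utils::tail(x$history$test_accuracy, 1L)))
  invisible(x)
}

#' @export
summary.fficaps <- function(object, ...) {
  np <- sum(vapply(object$params, length, integer(1L)))
  out <- list(model = object, n_parameters = np,
              final_loss = utils::tail(object$history$loss, 1L),
              final_test_accuracy =
                if (is.null(object$history$test_accuracy)) NA_real_
                else utils::tail(object$history$test_accuracy, 1L))
  class(out) <- "summary.fficaps"
  out
}

#' @export
print.summary.fficaps <- function(x, ...) {
  print(x$model)
  cat(sprintf("  learnable parameters: %d\n", x$n_parameters))
  invisible(x)
}

#' @export
coef.fficaps <- function(object, ...) object$params

#' Plot training curves
#'
#' Training loss per epoch and, when recorded, test accuracy per epoch.
#'
#' @param x A fitted [fficaps()] model.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.fficaps <- function(x, ...) {
  has_acc <- !is.null(x$history$test_accuracy)
  if (has_acc) {
    op <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(op))
  }
  graphics::plot(seq_along(x$history$loss), x$history$loss, type = "l",
                 xlab = "epoch", ylab = "train margin loss", ...)
  if (has_acc)
    graphics::plot(seq_along(x$history$test_accuracy),
                   100 * x$history$test_accuracy, type = "l",
                   xlab = "epoch", ylab = "test accuracy (%)", ...)
  invisible(x)
}

#' Save / load a fitted model
#'
#' The checkpoint holds the weight tensors plus an architecture descriptor
#' (width, squash kind, routing iterations, class levels).
#'
#' @param object A fitted [fficaps()] model.
#' @param path File path.
#' @return `path` (save) or the model (load).
#' @export
save_fficaps <- function(object, path) {
  stopifnot(inherits(object, "fficaps"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_fficaps
#' @export
load_fficaps <- function(path) {
  obj <- readRDS(path)
  stopifnot(inherits(obj, "fficaps"))
  obj
}

# ---- Adam -----------------------------------------------------------------

.adam_init <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(params, function(p) p * 0)
  st$v <- lapply(params, function(p) p * 0)
  st$t <- 0L
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st
}

.adam_step <- function(params, grads, st) {
  st$t <- st$t + 1L
  b1 <- st$beta1; b2 <- st$beta2
  corr1 <- 1 - b1^st$t
  corr2 <- 1 - b2^st$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g * g
    mhat <- st$m[[nm]] / corr1
    vhat <- st$v[[nm]] / corr2
    params[[nm]] <- params[[nm]] - st$lr * mhat / (sqrt(vhat) + st$eps)
  }
  params
}
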