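# Training: pixel-wise losses, Adam, and a plateau-halving learning-rate
# schedule monitored on validation loss.

#' Binary cross-entropy loss
#'
#' Mean pixel-wise cross-entropy between a probability map and a binary
#' target, with predictions clamped to `[eps, 1 - eps]` for log stability.
#'
#' @param pred numeric array of predicted probabilities in (0, 1).
#' @param target binary array of the same shape.
#' @param eps clamp bound.
#' @return non-negative scalar.
#' @export
bce_loss <- function(pred, target, eps = 1e-7) {
  if (!identical(dim(pred), dim(target)) && length(pred) != length(target))
    stop("pred and target shapes differ")
  q <- pmin(pmax(pred, eps), 1 - eps)
  -mean(target * log(q) + (1 - target) * log(1 - q))
}

bce_grad <- function(pred, target, eps = 1e-7) {
  q <- pmin(pmax(pred, eps), 1 - eps)
  -(target / q - (1 - target) / (1 - q)) / length(pred)
}

#' Soft Dice loss
#'
#' `1 - Dice` computed on soft (probabilistic) counts with additive
#' smoothing, so it is differentiable and defined for empty masks.
#'
#' @inheritParams bce_loss
#' @param smooth additive smoothing constant.
#' @return scalar in `[0, 1)`.
#' @export
dice_loss <- function(pred, target, smooth = 1) {
  num <- 2 * sum(pred * target) + smooth
  den <- sum(pred) + sum(target) + smooth
  1 - num / den
}

dice_grad <- function(pred, target, smooth = 1) {
  num <- 2 * sum(pred * target) + smooth
  den <- sum(pred) + sum(target) + smooth
  -(2 * target * den - num) / den^2
}

#' Focal loss
#'
#' Class-balanced focal loss for heavily imbalanced pixel labels, with the
#' usual defaults `gamma = 2`, `alpha = 0.25`.
#'
#' @inheritParams bce_loss
#' @param gamma focusing exponent.
#' @param alpha positive-class weight.
#' @return non-negative scalar.
#' @export
focal_loss <- function(pred, target, gamma = 2, alpha = 0.25, eps = 1e-7) {
  q <- pmin(pmax(pred, eps), 1 - eps)
  -mean(alpha * target * (1 - q)^gamma * log(q) +
          (1 - alpha) * (1 - target) * q^gamma * log(1 - q))
}

focal_grad <- function(pred, target, gamma = 2, alpha = 0.25, eps = 1e-7) {
  q <- pmin(pmax(pred, eps), 1 - eps)
  g <- alpha * target * (-gamma * (1 - q)^(gamma - 1) * log(q) + (1 - q)^gamma / q) +
    (1 - alpha) * (1 - target) * (gamma * q^(gamma - 1) * log(1 - q) - q^gamma / (1 - q))
  -g / length(pred)
}

loss_pair <- function(name) {
  switch(name,
         bce = list(fn = bce_loss, grad = bce_grad),
         dice = list(fn = dice_loss, grad = dice_grad),
         focal = list(fn = focal_loss, grad = focal_grad),
         stop("unknown loss: ", name))
}

#' Training configuration
#'
#' Defaults follow the reference training recipe: batch size 16, 40 epochs,
#' Adam starting at 1e-3, learning rate halved after 5 epochs without
#' validation-loss improvement and floored at 1e-5, binary cross-entropy
#' loss.
#'
#' @param batch_size samples per Adam update.
#' @param epochs maximum training epochs.
#' @param lr_init,lr_factor,lr_patience,lr_floor plateau schedule: initial
#'   learning rate, multiplicative factor, stagnant epochs before a cut,
#'   and the lower bound.
#' @param min_delta absolute validation-loss decrease that counts as
#'   improvement.
#' @param loss one of `"bce"`, `"dice"`, `"focal"`.
#' @param val_fraction fraction of training patches held out for
#'   validation when no validation set is supplied.
#' @param seed seed controlling shuffling and the holdout split.
#' @param stop_train_dice optional early-stopping target: training stops
#'   once the epoch's training Dice (at threshold 0.5) exceeds this value.
#' @param verbose print one line per epoch.
#' @return a `masegnet_train_config` list.
#' @export
train_config <- function(batch_size = 16L, epochs = 40L, lr_init = 1e-3,
                         lr_factor = 0.5, lr_patience = 5L, lr_floor = 1e-5,
                         min_delta = 1e-4, loss = c("bce", "dice", "focal"),
                         val_fraction = 0.1, seed = 42L,
                         stop_train_dice = NULL, verbose = FALSE) {
  loss <- match.arg(loss)
  if (lr_floor > lr_init) stop("lr_floor must not exceed lr_init")
  if (lr_patience < 1) stop("lr_patience must be at least 1")
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr_init = lr_init,
                 lr_factor = lr_factor, lr_patience = as.integer(lr_patience),
                 lr_floor = lr_floor, min_delta = min_delta, loss = loss,
                 val_fraction = val_fraction, seed = as.integer(seed),
                 stop_train_dice = stop_train_dice, verbose = isTRUE(verbose)),
            class = "masegnet_train_config")
}

#' Plateau learning-rate schedule
#'
#' State machine that halves the learning rate after `patience` consecutive
#' epochs without a strict validation-loss improvement (a decrease larger
#' than `min_delta` below the best loss seen), never dropping below
#' `floor`.  The first observed loss initialises the best value and counts
#' as a stagnant epoch, so a constant validation loss yields cuts after
#' every `patience` epochs.
#'
#' @param lr_init initial learning rate.
#' @param factor multiplicative decay applied at each cut.
#' @param patience stagnant epochs before a cut.
#' @param floor minimum learning rate.
#' @param min_delta improvement threshold.
#' @return scheduler state list; advance it with [lr_step()].
#' @export
lr_scheduler <- function(lr_init = 1e-3, factor = 0.5, patience = 5L,
                         floor = 1e-5, min_delta = 1e-4) {
  list(lr = lr_init, factor = factor, patience = as.integer(patience),
       floor = floor, min_delta = min_delta, best = NULL, wait = 0L)
}

#' @rdname lr_scheduler
#' @param state scheduler state.
#' @param val_loss validation loss observed for the epoch just finished.
#' @return updated state; `state$lr` is the rate for the next epoch.
#' @export
lr_step <- function(state, val_loss) {
  improved <- !is.null(state$best) && val_loss < state$best - state$min_delta
  if (is.null(state$best) || val_loss < state$best) state$best <- val_loss
  if (improved) {
    state$wait <- 0L
  } else {
    state$wait <- state$wait + 1L
    if (state$wait >= state$patience) {
      state$lr <- max(state$lr * state$factor, state$floor)
      state$wait <- 0L
    }
  }
  state
}

adam_init <- function(params) {
  zeros <- function(p) param_map(function(x) x * 0, p)
  list(m = zeros(params), v = zeros(params), t = 0L)
}

adam_update <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- param_map(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- param_map(function(v, g) beta2 * v + (1 - beta2) * g * g,
                       state$v, grads)
  c1 <- 1 / (1 - beta1^state$t)
  c2 <- 1 / (1 - beta2^state$t)
  params <- param_map(function(p, m, v) p - lr * (m * c1) / (sqrt(v * c2) + eps),
                      params, state$m, state$v)
  list(params = params, state = state)
}

as_stack <- function(x) {
  d <- dim(x)
  if (length(d) == 2L) d <- c(d, 1L)
  dim(x) <- d
  x
}

batch_tensor <- function(x, idx) {
  d <- dim(x)
  out <- x[, , idx, drop = FALSE]
  dim(out) <- c(d[1L], d[2L], length(idx), 1L)
  out
}

forward_in_batches <- function(model, x, batch_size = 16L) {
  n <- dim(x)[3L]
  out <- array(0, c(dim(x)[1L], dim(x)[2L], n))
  for (s in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    fw <- model_forward(model, batch_tensor(x, s))
    out[, , s] <- fw$out
  }
  out
}

#' Train a segmentation model
#'
#' Runs mini-batch Adam over image/mask patch pairs, monitors validation
#' loss for the plateau learning-rate schedule, and keeps the parameters of
#' the best-validation epoch.  Fully deterministic for a fixed seed and
#' platform.
#'
#' @param model a `masegnet_model` from [build_model()].
#' @param x,y training patches and binary masks, arrays `P x P x N`.
#' @param config a [train_config()].
#' @param x_val,y_val optional validation patches; when omitted,
#'   `val_fraction` of the training patches is held out (seeded).
#' @return list with `model` (best-validation parameters), `history`
#'   (one row per epoch: losses, accuracies, training Dice, learning
#'   rate), and `final_model` (last-epoch parameters).
#' @export
train_model <- function(model, x, y, config = train_config(),
                        x_val = NULL, y_val = NULL) {
  stopifnot(inherits(model, "masegnet_model"),
            inherits(config, "masegnet_train_config"))
  x <- as_stack(x); y <- as_stack(y)
  n <- dim(x)[3L]
  if (n == 0) stop("empty training set")
  if (dim(y)[3L] != n) stop("patch/mask counts differ")
  set.seed(config$seed)
  if (is.null(x_val)) {
    n_val <- max(1L, floor(config$val_fraction * n))
    if (n <= n_val) stop("too few patches to hold out a validation set")
    vi <- sample(n, n_val)
    x_val <- x[, , vi, drop = FALSE]; y_val <- y[, , vi, drop = FALSE]
    x <- x[, , -vi, drop = FALSE]; y <- y[, , -vi, drop = FALSE]
    n <- dim(x)[3L]
  } else {
    x_val <- as_stack(x_val); y_val <- as_stack(y_val)
  }
  lf <- loss_pair(config$loss)
  sched <- lr_scheduler(config$lr_init, config$lr_factor, config$lr_patience,
                        config$lr_floor, config$min_delta)
  adam <- adam_init(model$params)
  hist <- list()
  best_val <- Inf
  best_params <- model$params
  for (epoch in seq_len(config$epochs)) {
    ord <- sample(n)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- 0; ep_correct <- 0
    tp2 <- 0; psum <- 0; qsum <- 0
    for (bi in batches) {
      xb <- batch_tensor(x, bi)
      yb <- batch_tensor(y, bi)
      fw <- model_forward(model, xb, tape = TRUE)
      q <- fw$out
      ep_loss <- ep_loss + lf$fn(q, yb) * length(bi)
      qb <- q > 0.5
      ep_correct <- ep_correct + sum(qb == (yb > 0.5))
      tp2 <- tp2 + 2 * sum(qb & (yb > 0.5))
      psum <- psum + sum(qb); qsum <- qsum + sum(yb > 0.5)
      dq <- lf$grad(q, yb)
      dz <- dq * q * (1 - q)
      grads <- model_backward(model, fw$tape, dz)
      up <- adam_update(model$params, grads, adam, sched$lr)
      model$params <- up$params
      adam <- up$state
    }
    train_loss <- ep_loss / n
    train_acc <- ep_correct / (n * prod(dim(x)[1:2]))
    train_dice <- if (psum + qsum == 0) 1 else tp2 / (psum + qsum)
    qv <- forward_in_batches(model, x_val, config$batch_size)
    val_loss <- lf$fn(qv, y_val)
    val_acc <- mean((qv > 0.5) == (y_val > 0.5))
    lr_used <- sched$lr
    sched <- lr_step(sched, val_loss)
    hist[[epoch]] <- data.frame(epoch = epoch, loss = train_loss,
                                acc = train_acc, dice = train_dice,
                                val_loss = val_loss, val_acc = val_acc,
                                lr = lr_used)
    if (config$verbose)
      message(sprintf(
        "epoch %3d  loss %.4f  acc %.4f  dice %.3f  val_loss %.4f  lr %g",
        epoch, train_loss, train_acc, train_dice, val_loss, lr_used))
    if (val_loss < best_val) {
      best_val <- val_loss
      best_params <- model$params
    }
    if (!is.null(config$stop_train_dice) &&
        train_dice > config$stop_train_dice) break
  }
  final <- model
  model$params <- best_params
  list(model = model, history = do.call(rbind, hist), final_model = final)
}

#' Patch-wise whole-image prediction
#'
#' Tiles a preprocessed image into non-overlapping patches, runs the model
#' on each, and stitches the per-patch probability maps back onto the image
#' grid.
#'
#' @param model a trained `masegnet_model`.
#' @param image numeric matrix (preprocessed grayscale image).
#' @param patch_size tile side in pixels.
#' @param batch_size patches per forward pass.
#' @return probability matrix with the tiled extent of `image`.
#' @export
predict_map <- function(model, image, patch_size = 64L, batch_size = 16L) {
  ps <- extract_patches(image, patch_size)
  stack <- array(unlist(ps$patches, use.names = FALSE),
                 c(patch_size, patch_size, length(ps$patches)))
  probs <- forward_in_batches(model, stack, batch_size)
  ps$patches <- lapply(seq_len(dim(probs)[3L]), function(i) probs[, , i])
  stitch_patches(ps)
}

#' Save / load a trained model
#'
#' The model (weights + configuration) is serialised with `saveRDS`; a JSON
#' sidecar `<path>.json` records the architecture configuration for
#' provenance.
#'
#' @param model a `masegnet_model`.
#' @param path destination file.
#' @return `path`, invisibly (`save_model`); the model (`load_model`).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "masegnet_model"))
  saveRDS(model, path)
  jsonlite::write_json(unclass(model$config), paste0(path, ".json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "masegnet_model")) stop("not a saved masegnet model")
  model
}
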