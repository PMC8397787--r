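#' Training configuration
#'
#' Defaults follow the full-scale protocol: SGD with Nesterov momentum
#' 0.9, weight decay 1e-4, initial learning rate 0.001 reduced by 30%
#' (multiplied by 0.7) at epochs 15, 30 and 45, mini-batches of 24, 100
#' epochs, five-fold patient-wise cross-validation. Desk-scale runs
#' typically override `initial_lr`, `epochs` and `folds`.
#'
#' @param initial_lr Initial learning rate.
#' @param lr_drop_epochs Epochs (0-based) at which the rate drops.
#' @param lr_drop_factor Multiplicative drop factor in `(0, 1)`.
#' @param weight_decay L2 weight decay on convolution weights.
#' @param momentum Momentum coefficient.
#' @param nesterov Use the Nesterov momentum update.
#' @param epochs Number of training epochs.
#' @param batch_size Mini-batch size.
#' @param folds Number of patient-wise cross-validation folds (1 = single
#'   run with an explicit validation set).
#' @param max_steps Optional cap on total optimizer steps (for matched
#'   step-budget comparisons); `Inf` by default.
#' @return A `train_config` list.
#' @export
train_config <- function(initial_lr = 0.001, lr_drop_epochs = c(15, 30, 45),
                         lr_drop_factor = 0.7, weight_decay = 1e-4,
                         momentum = 0.9, nesterov = TRUE, epochs = 100,
                         batch_size = 24, folds = 5, max_steps = Inf) {
  stopifnot(initial_lr > 0, lr_drop_factor > 0, lr_drop_factor < 1,
            weight_decay >= 0, momentum >= 0, epochs >= 0, batch_size >= 1,
            folds >= 1, max_steps > 0)
  structure(list(initial_lr = initial_lr, lr_drop_epochs = lr_drop_epochs,
                 lr_drop_factor = lr_drop_factor, weight_decay = weight_decay,
                 momentum = momentum, nesterov = nesterov, epochs = epochs,
                 batch_size = batch_size, folds = folds,
                 max_steps = max_steps), class = "train_config")
}

#' Learning rate at a given epoch
#'
#' Step schedule: the initial rate multiplied by the drop factor once for
#' every scheduled drop epoch less than or equal to the current epoch
#' (0-based).
#'
#' @param config A [train_config()].
#' @param epoch 0-based epoch index.
#' @return The learning rate.
#' @export
#' @examples
#' lr_at_epoch(train_config(), 15)  # 0.001 * 0.7
lr_at_epoch <- function(config, epoch) {
  stopifnot(epoch >= 0)
  config$initial_lr * config$lr_drop_factor^sum(config$lr_drop_epochs <= epoch)
}

#' Stochastic augmentation configuration
#'
#' Left-right flipping, random resize-cropping with area ratio in
#' `[0.7, 1.0]`, and brightness/contrast scaling in `[0.9, 1.1]`.
#'
#' @param hflip Enable random horizontal flips (probability 0.5).
#' @param resize_crop_ratio Area-ratio range of the random crop.
#' @param brightness_ratio Brightness scale range.
#' @param contrast_ratio Contrast scale range.
#' @return An `augment_config` list.
#' @export
augment_config <- function(hflip = TRUE, resize_crop_ratio = c(0.7, 1.0),
                           brightness_ratio = c(0.9, 1.1),
                           contrast_ratio = c(0.9, 1.1)) {
  ok <- function(r) length(r) == 2 && r[1] <= r[2]
  stopifnot(ok(resize_crop_ratio), ok(brightness_ratio), ok(contrast_ratio))
  structure(list(hflip = hflip, resize_crop_ratio = resize_crop_ratio,
                 brightness_ratio = brightness_ratio,
                 contrast_ratio = contrast_ratio), class = "augment_config")
}

#' Apply stochastic augmentation to one image
#'
#' Independent random horizontal flip, random-area crop (uniform area
#' ratio within the configured range, aspect preserved, uniform position)
#' resized back to the input size, then brightness and contrast scaling.
#' Deterministic per seed; output size equals input size; values are
#' clipped to `[0, 255]`.
#'
#' @param image `H x W x 3` array in `[0, 255]`.
#' @param config An [augment_config()].
#' @param rng_seed Integer seed.
#' @return Augmented array of the same shape.
#' @export
augment <- function(image, config = augment_config(), rng_seed = 1L) {
  px <- as_pixels(image)
  d <- dim(px); H <- d[1]; W <- d[2]
  with_seed(rng_seed, {
    out <- px
    if (config$hflip && stats::runif(1) < 0.5)
      out <- out[, rev(seq_len(W)), , drop = FALSE]
    ar <- stats::runif(1, config$resize_crop_ratio[1], config$resize_crop_ratio[2])
    if (ar < 1) {
      s <- sqrt(ar)
      h <- max(2L, floor(s * H)); w <- max(2L, floor(s * W))
      r0 <- sample.int(H - h + 1L, 1L) - 1L
      c0 <- sample.int(W - w + 1L, 1L) - 1L
      crop <- out[r0 + seq_len(h), c0 + seq_len(w), , drop = FALSE]
      out <- array(0, c(H, W, 3))
      for (ch in 1:3) out[, , ch] <- resize_matrix(crop[, , ch], H, W)
    }
    bright <- stats::runif(1, config$brightness_ratio[1], config$brightness_ratio[2])
    contr <- stats::runif(1, config$contrast_ratio[1], config$contrast_ratio[2])
    out <- out * bright
    m <- mean(out)
    clamp((out - m) * contr + m, 0, 255)
  })
}

#' Patient-wise k-fold partition
#'
#' Partitions the *patients* of a manifest into `k` folds and derives
#' image-level (train, validation) index pairs, so that no patient ever
#' contributes images to both sides of any fold and every image appears
#' in exactly one validation fold.
#'
#' @param manifest A `data.frame` with a `patient_id` column (rows =
#'   images).
#' @param k Number of folds.
#' @param rng_seed Integer seed.
#' @return List of `k` lists with integer `train` and `val` row indices.
#' @export
make_folds <- function(manifest, k = 5, rng_seed = 1L) {
  pats <- unique(manifest$patient_id)
  if (length(pats) < k)
    stop("need at least k = ", k, " patients; got ", length(pats))
  ord <- with_seed(derive_seed(rng_seed, "folds"), sample(length(pats)))
  grp <- rep_len(seq_len(k), length(pats))[order(ord)]
  lapply(seq_len(k), function(f) {
    val_p <- pats[grp == f]
    val <- which(manifest$patient_id %in% val_p)
    list(train = setdiff(seq_len(nrow(manifest)), val), val = val)
  })
}

# Stack a list of HxWx3 arrays into (H, W, 3, N).
stack_images <- function(imgs) {
  d <- dim(imgs[[1]])
  out <- array(0, c(d, length(imgs)))
  for (i in seq_along(imgs)) out[, , , i] <- imgs[[i]]
  out
}

# One epoch of SGD over (x, y); returns updated model and mean loss.
run_epoch <- function(model, x, y, cfg, lr, augment_cfg, roi_cfg, epoch_seed,
                      steps_left) {
  n <- length(y)
  ord <- with_seed(epoch_seed, sample(n))
  total <- 0; nb <- 0
  for (b in seq(1, n, by = cfg$batch_size)) {
    if (steps_left <= 0) break
    idx <- ord[b:min(b + cfg$batch_size - 1, n)]
    xb <- x[, , , idx, drop = FALSE]
    if (!is.null(augment_cfg)) {
      for (j in seq_along(idx))
        xb[, , , j] <- augment(xb[, , , j], augment_cfg,
                               derive_seed(epoch_seed, "augment", idx[j]))
    }
    xb <- normalize_batch(xb, roi_cfg)
    fw <- model_forward(model, xb, training = TRUE, keep_cache = TRUE)
    model <- fw$model
    loss <- cross_entropy_from_logp(fw$log_probs, y[idx])
    if (!is.finite(loss))
      stop("training diverged: non-finite loss at a mini-batch; ",
           "reduce the learning rate")
    dlogits <- fw$probs
    dlogits[cbind(y[idx], seq_along(idx))] <-
      dlogits[cbind(y[idx], seq_along(idx))] - 1
    dlogits <- dlogits / length(idx)
    grads <- model_backward(model, fw, dlogits)
    model <- sgd_step(model, grads, lr, cfg$momentum, cfg$weight_decay,
                      cfg$nesterov)
    total <- total + loss; nb <- nb + 1; steps_left <- steps_left - 1
  }
  list(model = model, loss = if (nb) total / nb else NA_real_,
       steps_used = nb)
}

normalize_batch <- function(x, roi_cfg) {
  for (ch in 1:3)
    x[, , ch, ] <- (x[, , ch, ] / 255 - roi_cfg$channel_mean[ch]) /
      roi_cfg$channel_std[ch]
  x
}

# Batched eval-mode scoring: returns N x num_classes probability matrix.
predict_scores <- function(model, x, roi_cfg = NULL, batch_size = 64L) {
  if (!is.null(roi_cfg)) x <- normalize_batch(x, roi_cfg)
  n <- dim(x)[4]
  out <- matrix(0, n, model$num_classes)
  for (b in seq(1, n, by = batch_size)) {
    idx <- b:min(b + batch_size - 1, n)
    fw <- model_forward(model, x[, , , idx, drop = FALSE], training = FALSE)
    out[idx, ] <- t(fw$probs)
  }
  colnames(out) <- model$class_names
  out
}

eval_macro_f1 <- function(model, x, y, roi_cfg) {
  probs <- predict_scores(model, x, roi_cfg)
  pred <- max.col(probs, ties.method = "first")
  cm <- confusion_matrix(y, pred, n_classes = model$num_classes)
  mm <- macro_metrics(cm)
  list(f1 = mm$f1, accuracy = mean(pred == y), probs = probs)
}

#' Train a classifier on labeled images
#'
#' Supervised training with cross-entropy on the head's log probabilities
#' and SGD with Nesterov momentum under the configured learning-rate
#' schedule. With `config$folds > 1`, patients are partitioned into folds
#' ([make_folds()]); each fold trains a model and the fold model with the
#' best validation macro-F1 is returned. With `folds = 1` an explicit
#' validation set may be supplied. Images enter as raw `[0, 255]` patches;
#' augmentation (if any) runs on the raw scale and channel normalization
#' is applied per batch.
#'
#' @param x `H x W x 3 x N` array of raw images in `[0, 255]` (or a list
#'   of `H x W x 3` arrays).
#' @param y Integer class labels in `1..num_classes`.
#' @param config A [train_config()].
#' @param augment_cfg An [augment_config()] or `NULL` to disable.
#' @param patient_id Per-image patient ids (required when `folds > 1`).
#' @param val Optional `list(x =, y =)` validation set (used when
#'   `folds = 1`).
#' @param roi_cfg A [roi_config()] supplying normalization statistics.
#' @param backbone Backbone name for [make_model()].
#' @param rng_seed Integer seed (weights, shuffling, augmentation).
#' @return List with `model` (best fold), `history` (per-epoch
#'   `data.frame`: fold, epoch, lr, loss, val_f1, val_accuracy),
#'   `best_fold`, and `val_f1`.
#' @export
train_model <- function(x, y, config = train_config(), augment_cfg = NULL,
                        patient_id = NULL, val = NULL,
                        roi_cfg = roi_config(), backbone = "tiny",
                        rng_seed = 1L) {
  if (is.list(x)) x <- stack_images(x)
  y <- as.integer(y)
  stopifnot(dim(x)[4] == length(y), all(y >= 1))
  folds <- if (config$folds > 1) {
    if (is.null(patient_id)) stop("patient_id is required for folds > 1")
    make_folds(data.frame(patient_id = patient_id), config$folds, rng_seed)
  } else list(list(train = seq_along(y), val = integer(0)))
  history <- list()
  best <- list(f1 = -Inf, model = NULL, fold = NA_integer_)
  for (f in seq_along(folds)) {
    model <- make_model(backbone, num_classes = max(5L, max(y)),
                        rng_seed = derive_seed(rng_seed, "init", f))
    vx <- NULL; vy <- NULL
    if (length(folds[[f]]$val)) {
      vx <- normalize_batch(x[, , , folds[[f]]$val, drop = FALSE], roi_cfg)
      vy <- y[folds[[f]]$val]
    } else if (!is.null(val)) {
      vx <- val$x
      if (is.list(vx)) vx <- stack_images(vx)
      vx <- normalize_batch(vx, roi_cfg)
      vy <- as.integer(val$y)
    }
    steps_left <- config$max_steps
    fold_hist <- NULL
    for (e in seq_len(config$epochs) - 1L) {
      if (steps_left <= 0) break
      lr <- lr_at_epoch(config, e)
      ep <- run_epoch(model, x[, , , folds[[f]]$train, drop = FALSE],
                      y[folds[[f]]$train], config, lr, augment_cfg, roi_cfg,
                      derive_seed(rng_seed, "epoch", f * 100000 + e),
                      steps_left)
      model <- ep$model
      steps_left <- steps_left - ep$steps_used
      vf <- if (!is.null(vx)) eval_macro_f1(model, vx, vy, roi_cfg = NULL)
      history[[length(history) + 1]] <- data.frame(
        fold = f, epoch = e, lr = lr, loss = ep$loss,
        val_f1 = if (is.null(vf)) NA_real_ else vf$f1,
        val_accuracy = if (is.null(vf)) NA_real_ else vf$accuracy)
    }
    final_f1 <- if (!is.null(vx)) eval_macro_f1(model, vx, vy, NULL)$f1 else NA
    if (is.na(final_f1) && is.null(best$model)) {
      best <- list(f1 = NA_real_, model = model, fold = f)
    } else if (!is.na(final_f1) && final_f1 > best$f1) {
      best <- list(f1 = final_f1, model = model, fold = f)
    }
  }
  list(model = best$model,
       history = if (length(history)) do.call(rbind, history) else
         data.frame(fold = integer(0), epoch = integer(0), lr = numeric(0),
                    loss = numeric(0), val_f1 = numeric(0),
                    val_accuracy = numeric(0)),
       best_fold = best$fold, val_f1 = best$f1)
}

#' Single-forward-pass inference
#'
#' Scores one image with exactly one deterministic evaluation-mode
#' forward pass: no test-time augmentation, no ensembling.
#'
#' @param model A trained `oral_model`.
#' @param image `H x W x 3` raw image in `[0, 255]` (already cropped and
#'   resized to the model's input side).
#' @param roi_cfg A [roi_config()] supplying normalization statistics,
#'   or `NULL` if `image` is already normalized.
#' @return A `class_scores` list with `log_probs` and `probs`.
#' @export
single_forward_inference <- function(model, image, roi_cfg = roi_config()) {
  px <- as_pixels(image)
  x <- array(px, c(dim(px), 1))
  if (!is.null(roi_cfg)) x <- normalize_batch(x, roi_cfg)
  fw <- model_forward(model, x, training = FALSE)
  structure(list(log_probs = as.vector(fw$log_probs),
                 probs = as.vector(fw$probs)),
            class = "class_scores")
}
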