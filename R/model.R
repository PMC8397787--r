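#' Construct a convolutional backbone
#'
#' The `tiny` backbone is a compact four-stage network (3x3 convolutions,
#' stride 2, ReLU; channels 8-16-32-64) with total spatial reduction
#' `r = 16`, so a 512x512 input yields a 32x32 feature map and a 64x64
#' input a 4x4 map. It is the desk-scale test vehicle for the whole
#' pipeline. `hrnet_w18` names the full-scale high-resolution network
#' used at clinical scale; its architecture and pretrained weights are not
#' bundled with this package, so requesting it raises an explicit error
#' rather than silently substituting a randomly initialized network.
#'
#' @param name `"tiny"` or `"hrnet_w18"`.
#' @param pretrained Logical; `tiny` has no pretrained weights.
#' @param rng_seed Seed for weight initialization.
#' @return List of backbone layers (internal structure).
#' @export
make_backbone <- function(name = c("tiny", "hrnet_w18"), pretrained = FALSE,
                          rng_seed = 1L) {
  name <- match.arg(name)
  if (name == "hrnet_w18")
    stop("hrnet_w18 is not bundled with this package (no architecture or ",
         "pretrained weights are shipped); use the 'tiny' backbone, or load ",
         "a full model checkpoint with load_model()")
  if (pretrained)
    stop("no pretrained weights are available for the 'tiny' backbone; ",
         "call with pretrained = FALSE")
  chans <- c(3, 8, 16, 32, 64)
  layers <- lapply(seq_len(4), function(i)
    new_conv_layer(chans[i], chans[i + 1], k = 3, stride = 2, pad = 1,
                   rng_seed = derive_seed(rng_seed, "backbone", i)))
  structure(list(layers = layers, reduction = 16L, out_channels = 64L,
                 name = name), class = "oral_backbone")
}

#' Build a full classification model
#'
#' Backbone plus the modified representation head: a 1x1 convolution
#' mapping the feature channels to the 5 classes, batch normalization,
#' global average pooling, and a log-softmax, so the pooled head output is
#' directly the vector of log class probabilities. The head convolution is
#' zero-initialized, making an untrained model predict the uniform
#' distribution (cross-entropy exactly `log(5)` on any data).
#'
#' @param backbone `"tiny"` (or an `oral_backbone`).
#' @param num_classes Number of classes (default 5).
#' @param rng_seed Seed for weight initialization.
#' @return An `oral_model`.
#' @export
#' @examples
#' m <- make_model(rng_seed = 1)
make_model <- function(backbone = "tiny", num_classes = 5L, rng_seed = 1L) {
  bb <- if (inherits(backbone, "oral_backbone")) backbone else
    make_backbone(backbone, rng_seed = rng_seed)
  head_conv <- new_conv_layer(bb$out_channels, num_classes, k = 1, stride = 1,
                              pad = 0, init = "zero")
  structure(list(backbone = bb, head_conv = head_conv,
                 head_bn = new_bn_layer(num_classes),
                 num_classes = num_classes, r = bb$reduction,
                 class_names = oral_classes()[seq_len(num_classes)]),
            class = "oral_model")
}

# Full forward pass. x: (H, W, 3, N) normalized input.
# Returns logits, log_probs, probs, prepool map, and caches for backward.
model_forward <- function(model, x, training = FALSE, keep_cache = FALSE) {
  if (!all(is.finite(x))) stop("non-finite values in model input")
  caches <- if (keep_cache) vector("list", length(model$backbone$layers))
  a <- x
  for (i in seq_along(model$backbone$layers)) {
    cf <- conv_forward(model$backbone$layers[[i]], a)
    pre <- cf$out
    a <- pmax(pre, 0)
    if (keep_cache) caches[[i]] <- list(conv = cf$cache, relu_mask = pre > 0)
  }
  hc <- conv_forward(model$head_conv, a)
  bf <- bn_forward(model$head_bn, hc$out, training = training)
  if (training) model$head_bn <- bf$bn
  gp <- gap_forward(bf$out)
  logits <- gp$out
  logp <- log_softmax(logits)
  list(model = model, logits = logits, log_probs = logp,
       probs = exp(logp), prepool = bf$out,
       caches = if (keep_cache)
         list(backbone = caches, head_conv = hc$cache, bn = bf$cache,
              gap = gp, features = a))
}

# Backward pass from dlogits; returns gradients mirroring the parameters.
model_backward <- function(model, fw, dlogits) {
  cc <- fw$caches
  dx <- gap_backward(dlogits, cc$gap)
  bnb <- bn_backward(model$head_bn, dx, cc$bn)
  hcb <- conv_backward(model$head_conv, bnb$dx, cc$head_conv)
  g <- list(head_conv = list(dW = hcb$dW, db = hcb$db),
            head_bn = list(dgamma = bnb$dgamma, dbeta = bnb$dbeta),
            backbone = vector("list", length(model$backbone$layers)))
  d <- hcb$dx
  for (i in rev(seq_along(model$backbone$layers))) {
    d <- d * cc$backbone[[i]]$relu_mask
    cb <- conv_backward(model$backbone$layers[[i]], d, cc$backbone[[i]]$conv)
    g$backbone[[i]] <- list(dW = cb$dW, db = cb$db)
    d <- cb$dx
  }
  g
}

# SGD with (optionally Nesterov) momentum and weight decay, PyTorch
# update convention: d = g + wd*w; v = mu*v + d; w = w - lr*(d + mu*v)
# (Nesterov) or w = w - lr*v (plain momentum).
sgd_update <- function(w, v, g, lr, mu, wd, nesterov) {
  d <- g + wd * w
  v <- mu * v + d
  step <- if (nesterov) d + mu * v else v
  list(w = w - lr * step, v = v)
}

sgd_step <- function(model, grads, lr, momentum = 0.9, weight_decay = 1e-4,
                     nesterov = TRUE) {
  for (i in seq_along(model$backbone$layers)) {
    L <- model$backbone$layers[[i]]
    u <- sgd_update(L$W, L$vW, grads$backbone[[i]]$dW, lr, momentum,
                    weight_decay, nesterov)
    L$W <- u$w; L$vW <- u$v
    u <- sgd_update(L$b, L$vb, grads$backbone[[i]]$db, lr, momentum, 0,
                    nesterov)
    L$b <- u$w; L$vb <- u$v
    model$backbone$layers[[i]] <- L
  }
  L <- model$head_conv
  u <- sgd_update(L$W, L$vW, grads$head_conv$dW, lr, momentum, weight_decay,
                  nesterov)
  L$W <- u$w; L$vW <- u$v
  u <- sgd_update(L$b, L$vb, grads$head_conv$db, lr, momentum, 0, nesterov)
  L$b <- u$w; L$vb <- u$v
  model$head_conv <- L
  B <- model$head_bn
  u <- sgd_update(B$gamma, B$vgamma, grads$head_bn$dgamma, lr, momentum, 0,
                  nesterov)
  B$gamma <- u$w; B$vgamma <- u$v
  u <- sgd_update(B$beta, B$vbeta, grads$head_bn$dbeta, lr, momentum, 0,
                  nesterov)
  B$beta <- u$w; B$vbeta <- u$v
  model$head_bn <- B
  model
}

#' Head parameters for [head_forward()]
#'
#' @param W `num_classes x C` 1x1-convolution weight matrix.
#' @param b Length-`num_classes` bias.
#' @param gamma,beta,mean,var Batch-normalization affine parameters and
#'   (running) statistics, one value per class channel.
#' @param eps Numerical floor inside the BN square root.
#' @return A `head_params` list.
#' @export
head_params <- function(W, b = numeric(nrow(W)), gamma = rep(1, nrow(W)),
                        beta = numeric(nrow(W)), mean = numeric(nrow(W)),
                        var = rep(1, nrow(W)), eps = 1e-5) {
  structure(list(W = W, b = b, gamma = gamma, beta = beta, mean = mean,
                 var = var, eps = eps), class = "head_params")
}

#' Modified representation head: 1x1 conv, BN, global pooling, log-softmax
#'
#' Applies the classification head to a spatial feature map: a 1x1
#' convolution to `num_classes` channels, batch normalization (evaluation
#' mode, using the supplied statistics), global average pooling, and a
#' log-softmax, so the pooled vector is directly the log class
#' probabilities. Because every step before the log-softmax is linear in
#' the feature map, the pooled pre-softmax value per class equals the
#' spatial mean of the per-position head response — the identity that
#' class activation mapping relies on.
#'
#' @param features `h x w x C` feature array (a single image's map).
#' @param head A [head_params()].
#' @return A `class_scores` list with `log_probs`, `probs`, and the
#'   pre-pooling `map` (`h x w x num_classes`).
#' @export
head_forward <- function(features, head) {
  if (!all(is.finite(features))) stop("non-finite values in features")
  d <- dim(features)
  x <- array(features, c(d[1], d[2], d[3], 1))
  xm <- aperm(x, c(3, 1, 2, 4))
  dim(xm) <- c(d[3], d[1] * d[2])
  resp <- head$W %*% xm + head$b
  resp <- (resp - head$mean) / sqrt(head$var + head$eps)
  resp <- resp * head$gamma + head$beta
  logits <- rowMeans(resp)
  logp <- as.vector(log_softmax(matrix(logits)))
  map <- aperm(array(resp, c(nrow(head$W), d[1], d[2])), c(2, 3, 1))
  structure(list(log_probs = logp, probs = exp(logp), map = map),
            class = "class_scores")
}

#' Numerically stable softmax
#'
#' `softmax(x)_j = exp(x_j) / sum_k exp(x_k)`, computed with
#' max-subtraction so that arbitrary logit magnitudes are safe. Invariant
#' under adding a constant to all logits.
#'
#' @param logits Numeric vector of finite values.
#' @return Probability vector of the same length.
#' @export
#' @examples
#' softmax(c(0, 0, 0, 0, 0))
softmax <- function(logits) {
  if (!all(is.finite(logits))) stop("logits must be finite")
  z <- exp(logits - max(logits))
  z / sum(z)
}

#' Decision rule: highest-probability class
#'
#' `c = argmax_j p_j`, with exact ties broken toward the lowest class
#' index. Because softmax is monotone, this equals the argmax of the
#' logits.
#'
#' @param scores A `class_scores` object or a probability vector.
#' @return List with `class_index` (1-based), `class_label` (when class
#'   names are known), and `confidence` (the maximum probability).
#' @export
predict_class <- function(scores) {
  p <- if (inherits(scores, "class_scores")) scores$probs else scores
  k <- which.max(p)  # which.max returns the first maximum: lowest index
  list(class_index = k,
       class_label = if (length(p) == 5L) oral_classes()[k] else NA_character_,
       confidence = p[k])
}

#' Save / load a model checkpoint
#'
#' Weights and configuration are serialized with R's native RDS format.
#'
#' @param model An `oral_model`.
#' @param path File path.
#' @return `load_model` returns the `oral_model`.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  m <- readRDS(path)
  if (!inherits(m, "oral_model")) stop("not an oral_model checkpoint: ", path)
  m
}
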