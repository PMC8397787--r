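test_that("softmax is uniform on equal logits, shift invariant, and stable", {
  expect_equal(softmax(rep(0, 5)), rep(0.2, 5))
  with_seed(1, for (i in 1:20) {
    z <- stats::rnorm(5, sd = 3)
    expect_equal(softmax(z), softmax(z + 17.3), tolerance = 1e-12)
    naive <- exp(z) / sum(exp(z))
    expect_lt(max(abs(softmax(z) - naive)), 1e-12)
    expect_equal(sum(softmax(z)), 1, tolerance = 1e-12)
  })
  # magnitudes that overflow the naive formula remain finite
  expect_true(all(is.finite(softmax(c(1000, 999, 0, -1000, 2)))))
  expect_error(softmax(c(1, NA, 3, 4, 5)), "finite")
})

test_that("prediction takes the argmax with lowest-index tie-breaking", {
  p <- predict_class(c(0.1, 0.6, 0.1, 0.1, 0.1))
  expect_equal(p$class_index, 2)
  expect_equal(p$confidence, 0.6)
  tie <- predict_class(c(0.25, 0.25, 0.25, 0.25, 0))
  expect_equal(tie$class_index, 1)
  with_seed(2, for (i in 1:2000) {
    z <- stats::rnorm(5, sd = 2)
    expect_equal(predict_class(softmax(z))$class_index, which.max(z))
  })
})

test_that("head pooling equals per-position response on constant features", {
  W <- with_seed(3, matrix(stats::rnorm(5 * 8), 5, 8))
  hp <- head_params(W, b = seq(0.1, 0.5, by = 0.1))
  f <- array(rep(with_seed(4, stats::rnorm(8)), each = 6 * 6), c(6, 6, 8))
  sc <- head_forward(f, hp)
  # map is spatially constant, and pooled value equals any single location
  expect_lt(max(abs(sweep(sc$map, 3, sc$map[1, 1, ]))), 1e-10)
  expect_equal(sum(sc$probs), 1, tolerance = 1e-9)
})

test_that("zero features with an identity head give uniform probabilities", {
  hp <- head_params(matrix(0, 5, 8))
  sc <- head_forward(array(0, c(4, 4, 8)), hp)
  expect_equal(sc$probs, rep(0.2, 5), tolerance = 1e-9)
})

test_that("pooled pre-softmax values equal the mean per-position response", {
  with_seed(5, {
    W <- matrix(stats::rnorm(5 * 16), 5, 16)
    hp <- head_params(W, b = stats::rnorm(5), gamma = stats::runif(5, 0.5, 2),
                      beta = stats::rnorm(5), mean = stats::rnorm(5, sd = 0.2),
                      var = stats::runif(5, 0.5, 2))
    f <- array(stats::rnorm(7 * 7 * 16), c(7, 7, 16))
    sc <- head_forward(f, hp)
    # brute force: head response at each position, then average
    brute <- matrix(0, 5, 49)
    k <- 0
    for (j in 1:7) for (i in 1:7) {
      k <- k + 1
      r <- W %*% f[i, j, ] + hp$b
      r <- (r - hp$mean) / sqrt(hp$var + hp$eps) * hp$gamma + hp$beta
      brute[, k] <- r
    }
    pooled <- rowMeans(brute)
    expect_lt(max(abs(exp(sc$log_probs) - softmax(pooled))), 1e-5)
    expect_lt(max(abs(apply(sc$map, 3, mean) - pooled)), 1e-5)
  })
})

test_that("tiny backbone reduces 16-fold and rejects unavailable variants", {
  m <- make_model(rng_seed = 1)
  x64 <- array(0.1, c(64, 64, 3, 1))
  fw <- oralscope:::model_forward(m, x64)
  expect_equal(dim(fw$prepool)[1:2], c(4L, 4L))
  x512 <- array(0.1, c(512, 512, 3, 1))
  fw512 <- oralscope:::model_forward(m, x512)
  expect_equal(dim(fw512$prepool)[1:2], c(32L, 32L))
  expect_error(make_backbone("hrnet_w18"), "not bundled")
  expect_error(make_backbone("tiny", pretrained = TRUE), "pretrained")
})

test_that("eval-mode forward passes are bitwise repeatable", {
  m <- random_head_model(7)
  x <- with_seed(8, array(stats::rnorm(32 * 32 * 3 * 2), c(32, 32, 3, 2)))
  a <- oralscope:::model_forward(m, x)
  b <- oralscope:::model_forward(m, x)
  expect_identical(a$probs, b$probs)
  expect_error(oralscope:::model_forward(m, x * NA), "non-finite")
})

test_that("analytic gradients match finite differences", {
  ns <- asNamespace("oralscope")
  model <- random_head_model(9)
  x <- with_seed(10, array(stats::rnorm(16 * 16 * 3 * 3), c(16, 16, 3, 3)))
  y <- c(1, 4, 2)
  loss_fn <- function(m) {
    fw <- ns$model_forward(m, x, training = TRUE)
    ns$cross_entropy_from_logp(fw$log_probs, y)
  }
  fw <- ns$model_forward(model, x, training = TRUE, keep_cache = TRUE)
  dlogits <- fw$probs
  dlogits[cbind(y, 1:3)] <- dlogits[cbind(y, 1:3)] - 1
  g <- ns$model_backward(fw$model, fw, dlogits / 3)
  eps <- 1e-5
  check_param <- function(w, set, ga) {
    idx <- with_seed(11, sample(length(w), min(4, length(w))))
    for (i in idx) {
      wp <- w; wp[i] <- wp[i] + eps
      wm <- w; wm[i] <- wm[i] - eps
      num <- (loss_fn(set(wp)) - loss_fn(set(wm))) / (2 * eps)
      expect_lt(abs(num - ga[i]), 1e-6 + 1e-4 * abs(num))
    }
  }
  check_param(model$backbone$layers[[1]]$W, function(w) {
    m <- model; m$backbone$layers[[1]]$W <- matrix(w, nrow = 8); m
  }, g$backbone[[1]]$dW)
  check_param(model$head_conv$W, function(w) {
    m <- model; m$head_conv$W <- matrix(w, nrow = 5); m
  }, g$head_conv$dW)
  check_param(model$head_bn$gamma, function(w) {
    m <- model; m$head_bn$gamma <- w; m
  }, g$head_bn$dgamma)
})
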