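# Minimal CNN engine: im2col convolutions, batch normalization, global
# average pooling, log-softmax, and SGD with Nesterov momentum. All heavy
# arithmetic is BLAS matrix multiplication; gather/scatter index tables
# are precomputed per input size and cached on the layer.
#
# Array layout: activations are (H, W, C, N); conv weights are
# (C_out, k*k*C_in) with the patch unrolled row-fastest, then column,
# then channel.

new_conv_layer <- function(in_ch, out_ch, k, stride, pad, init = c("he", "zero"),
                           rng_seed = 1L) {
  init <- match.arg(init)
  W <- if (init == "zero") matrix(0, out_ch, k * k * in_ch) else
    with_seed(rng_seed,
              matrix(stats::rnorm(out_ch * k * k * in_ch,
                                  sd = sqrt(2 / (k * k * in_ch))),
                     out_ch, k * k * in_ch))
  list(type = "conv", in_ch = in_ch, out_ch = out_ch, k = k,
       stride = stride, pad = pad, W = W, b = numeric(out_ch),
       vW = matrix(0, out_ch, k * k * in_ch), vb = numeric(out_ch),
       cache = new.env(parent = emptyenv()))
}

conv_indices <- function(layer, H, W, C) {
  key <- paste(H, W, C, sep = "x")
  hit <- layer$cache[[key]]
  if (!is.null(hit)) return(hit)
  k <- layer$k; s <- layer$stride; p <- layer$pad
  Hp <- H + 2L * p; Wp <- W + 2L * p
  Ho <- (Hp - k) %/% s + 1L; Wo <- (Wp - k) %/% s + 1L
  dr <- rep(0:(k - 1L), times = k * C)
  dc <- rep(rep(0:(k - 1L), each = k), times = C)
  ch <- rep(0:(C - 1L), each = k * k)
  A <- ch * Hp * Wp + dc * Hp + dr + 1L          # within-patch linear offset
  pr <- rep((seq_len(Ho) - 1L) * s, times = Wo)  # patch top-left, 0-based
  pc <- rep((seq_len(Wo) - 1L) * s, each = Ho)
  B <- pc * Hp + pr
  idx <- outer(as.integer(A), as.integer(B), "+")
  out <- list(idx = idx, flat = as.vector(idx), Hp = Hp, Wp = Wp,
              Ho = Ho, Wo = Wo, P = Ho * Wo, k2C = k * k * C)
  layer$cache[[key]] <- out
  out
}

conv_forward <- function(layer, x) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  ci <- conv_indices(layer, H, W, C)
  p <- layer$pad
  if (p > 0) {
    xp <- array(0, c(ci$Hp, ci$Wp, C, N))
    xp[p + seq_len(H), p + seq_len(W), , ] <- x
  } else xp <- x
  dim(xp) <- c(ci$Hp * ci$Wp * C, N)
  cols <- xp[ci$flat, , drop = FALSE]
  dim(cols) <- c(ci$k2C, ci$P * N)
  out <- layer$W %*% cols + layer$b
  dim(out) <- c(layer$out_ch, ci$Ho, ci$Wo, N)
  list(out = aperm(out, c(2, 3, 1, 4)),
       cache = list(cols = cols, ci = ci, H = H, W = W, C = C, N = N))
}

conv_backward <- function(layer, dout, cache) {
  ci <- cache$ci; N <- cache$N
  dm <- aperm(dout, c(3, 1, 2, 4))
  dim(dm) <- c(layer$out_ch, ci$P * N)
  db <- rowSums(dm)
  dW <- tcrossprod(dm, cache$cols)
  dcols <- crossprod(layer$W, dm)
  dim(dcols) <- c(ci$k2C * ci$P, N)
  acc <- rowsum(dcols, group = ci$flat)
  dXp <- matrix(0, ci$Hp * ci$Wp * cache$C, N)
  dXp[as.integer(rownames(acc)), ] <- acc
  dim(dXp) <- c(ci$Hp, ci$Wp, cache$C, N)
  p <- layer$pad
  dx <- if (p > 0)
    dXp[p + seq_len(cache$H), p + seq_len(cache$W), , , drop = FALSE] else dXp
  list(dx = dx, dW = dW, db = db)
}

new_bn_layer <- function(C, eps = 1e-5, momentum = 0.1) {
  list(type = "bn", C = C, eps = eps, momentum = momentum,
       gamma = rep(1, C), beta = numeric(C),
       running_mean = numeric(C), running_var = rep(1, C),
       vgamma = numeric(C), vbeta = numeric(C))
}

bn_forward <- function(bn, x, training) {
  d <- dim(x); n <- d[1] * d[2] * d[4]
  xm <- aperm(x, c(1, 2, 4, 3))
  dim(xm) <- c(n, d[3])
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    v <- pmax(v, 0)
    unb <- if (n > 1) n / (n - 1) else 1
    bn$running_mean <- (1 - bn$momentum) * bn$running_mean + bn$momentum * mu
    bn$running_var <- (1 - bn$momentum) * bn$running_var + bn$momentum * v * unb
  } else {
    mu <- bn$running_mean
    v <- bn$running_var
  }
  sd_ <- sqrt(v + bn$eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, sd_, "/")
  out <- sweep(sweep(xhat, 2, bn$gamma, "*"), 2, bn$beta, "+")
  dim(out) <- c(d[1], d[2], d[4], d[3])
  list(out = aperm(out, c(1, 2, 4, 3)), bn = bn,
       cache = list(xhat = xhat, sd = sd_, d = d, n = n))
}

bn_backward <- function(bn, dout, cache) {
  d <- cache$d; n <- cache$n
  dm <- aperm(dout, c(1, 2, 4, 3))
  dim(dm) <- c(n, d[3])
  dgamma <- colSums(dm * cache$xhat)
  dbeta <- colSums(dm)
  dxhat <- sweep(dm, 2, bn$gamma, "*")
  # dx = (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat)) / sd
  t1 <- sweep(dxhat, 2, colMeans(dxhat))
  t2 <- sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), "*")
  dxm <- sweep(t1 - t2, 2, cache$sd, "/")
  dim(dxm) <- c(d[1], d[2], d[4], d[3])
  list(dx = aperm(dxm, c(1, 2, 4, 3)), dgamma = dgamma, dbeta = dbeta)
}

gap_forward <- function(x) {
  d <- dim(x)
  xm <- aperm(x, c(3, 4, 1, 2))
  dim(xm) <- c(d[3] * d[4], d[1] * d[2])
  out <- matrix(rowMeans(xm), d[3], d[4])
  list(out = out, P = d[1] * d[2], d = d)
}

gap_backward <- function(dlogits, cache) {
  d <- cache$d
  # every spatial position receives dlogits[c, n] / P
  dx <- rep(as.vector(dlogits) / cache$P, each = d[1] * d[2])
  dim(dx) <- d
  dx
}

log_softmax <- function(logits) {
  m <- apply(logits, 2, max)
  z <- sweep(logits, 2, m)
  sweep(z, 2, log(colSums(exp(z))))
}

cross_entropy_from_logp <- function(logp, y) {
  -mean(logp[cbind(y, seq_along(y))])
}
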