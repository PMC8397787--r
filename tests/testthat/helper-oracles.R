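# Independent, deliberately slow oracles used to validate the vectorized
# implementations. These share no code with the package internals.

# Scalar-loop bilinear resize, half-pixel-center convention.
slow_bilinear_resize <- function(img, out_h, out_w) {
  d <- dim(img); H <- d[1]; W <- d[2]; C <- d[3]
  out <- array(0, c(out_h, out_w, C))
  for (i in seq_len(out_h)) {
    for (j in seq_len(out_w)) {
      sr <- min(max((i - 0.5) * H / out_h + 0.5, 1), H)
      sc <- min(max((j - 0.5) * W / out_w + 0.5, 1), W)
      r0 <- min(max(floor(sr), 1), H - 1); c0 <- min(max(floor(sc), 1), W - 1)
      if (H == 1) r0 <- 1
      if (W == 1) c0 <- 1
      fr <- sr - r0; fc <- sc - c0
      r1 <- min(r0 + 1, H); c1 <- min(c0 + 1, W)
      for (ch in seq_len(C)) {
        out[i, j, ch] <-
          img[r0, c0, ch] * (1 - fr) * (1 - fc) +
          img[r0, c1, ch] * (1 - fr) * fc +
          img[r1, c0, ch] * fr * (1 - fc) +
          img[r1, c1, ch] * fr * fc
      }
    }
  }
  out
}

# Scalar-loop inverse-rotation patch sampler.
slow_rotated_patch <- function(img, center, angle, size) {
  h <- size[1]; w <- size[2]
  a <- angle * pi / 180
  out <- array(0, c(h, w, dim(img)[3]))
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      dr <- i - (h + 1) / 2; dc <- j - (w + 1) / 2
      sr <- center[1] + cos(a) * dr + sin(a) * dc
      sc <- center[2] - sin(a) * dr + cos(a) * dc
      r0 <- floor(sr); c0 <- floor(sc)
      fr <- sr - r0; fc <- sc - c0
      H <- dim(img)[1]; W <- dim(img)[2]
      r1 <- min(r0 + 1, H); c1 <- min(c0 + 1, W)
      for (ch in seq_len(dim(img)[3])) {
        out[i, j, ch] <-
          img[r0, c0, ch] * (1 - fr) * (1 - fc) +
          img[r0, c1, ch] * (1 - fr) * fc +
          img[r1, c0, ch] * fr * (1 - fc) +
          img[r1, c1, ch] * fr * fc
      }
    }
  }
  out
}

# Brute-force largest in-bounds patch side by tracing the extreme sampling
# positions (the grid corners at +/-(s-1)/2) over a grid of angles and
# offset directions. This is the true sampling bound; the package's closed
# form uses the geometric square extent and is conservative by <= 2 px.
brute_force_max_side <- function(image_size, theta, offset_radius,
                                 n_angles = 41, n_dirs = 24) {
  H <- image_size[1]; W <- image_size[2]
  ctr <- c((H + 1) / 2, (W + 1) / 2)
  angles <- seq(-theta, theta, length.out = n_angles) * pi / 180
  dirs <- seq(0, 2 * pi, length.out = n_dirs + 1)[-(n_dirs + 1)]
  fits <- function(s) {
    half <- (s - 1) / 2
    corners <- rbind(c(-half, -half), c(-half, half), c(half, -half),
                     c(half, half))
    for (a in angles) {
      rot <- rbind(c(cos(a), sin(a)), c(-sin(a), cos(a)))
      rc <- corners %*% t(rot)
      for (d in dirs) {
        off <- offset_radius * c(cos(d), sin(d))
        rr <- ctr[1] + off[1] + rc[, 1]
        cc <- ctr[2] + off[2] + rc[, 2]
        if (min(rr) < 1 || max(rr) > H || min(cc) < 1 || max(cc) > W)
          return(FALSE)
      }
    }
    TRUE
  }
  s <- 0
  for (cand in seq_len(min(H, W))) if (fits(cand)) s <- cand
  s
}

# Pairwise counting confusion matrix.
oracle_confusion <- function(true, pred, C) {
  m <- matrix(0L, C, C)
  for (i in seq_along(true)) m[true[i], pred[i]] <- m[true[i], pred[i]] + 1L
  m
}

# Per-class rates from direct TP/FP/FN/TN enumeration over label pairs.
oracle_rates <- function(true, pred, i) {
  tp <- sum(true == i & pred == i)
  fp <- sum(true != i & pred == i)
  fn <- sum(true == i & pred != i)
  tn <- sum(true != i & pred != i)
  c(sensitivity = if (tp + fn > 0) tp / (tp + fn) else 0,
    specificity = if (tn + fp > 0) tn / (tn + fp) else 0,
    precision = if (tp + fp > 0) tp / (tp + fp) else 0)
}

# Formula-by-formula macro metrics from a confusion matrix.
oracle_macro <- function(cm) {
  C <- nrow(cm)
  total <- sum(cm)
  se <- sp <- pr <- numeric(C)
  for (i in seq_len(C)) {
    tp <- cm[i, i]; fn <- sum(cm[i, ]) - tp; fp <- sum(cm[, i]) - tp
    tn <- total - tp - fn - fp
    se[i] <- if (tp + fn > 0) tp / (tp + fn) else 0
    sp[i] <- if (tn + fp > 0) tn / (tn + fp) else 0
    pr[i] <- if (tp + fp > 0) tp / (tp + fp) else 0
  }
  SE <- mean(se); SP <- mean(sp); PR <- mean(pr)
  c(se = SE, sp = SP, pr = PR,
    f1 = if (SE + PR > 0) 2 * SE * PR / (SE + PR) else 0)
}

# AUC by explicit loop over all positive x negative pairs, half credit
# for ties.
oracle_auc <- function(scores_k, positive) {
  x <- scores_k[positive]; y <- scores_k[!positive]
  tot <- 0
  for (xi in x) for (yj in y)
    tot <- tot + (if (xi > yj) 1 else if (xi == yj) 0.5 else 0)
  tot / (length(x) * length(y))
}

# Stratified bootstrap percentile CI for the one-vs-rest AUC.
bootstrap_auc_ci <- function(scores_k, positive, reps = 2000, level = 0.95,
                             seed = 1) {
  set.seed(seed)
  ip <- which(positive); ineg <- which(!positive)
  aucs <- replicate(reps, {
    bp <- sample(ip, replace = TRUE); bn <- sample(ineg, replace = TRUE)
    s <- c(scores_k[bp], scores_k[bn])
    pos <- rep(c(TRUE, FALSE), c(length(bp), length(bn)))
    r <- rank(s)
    (sum(r[pos]) - length(bp) * (length(bp) + 1) / 2) /
      (length(bp) * length(bn))
  })
  stats::quantile(aucs, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
}
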