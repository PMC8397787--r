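#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

MOD31 <- 2147483647  # 2^31 - 1, keeps derived seeds valid R integers

#' Derive a reproducible sub-seed from a global seed and an operation tag
#'
#' Every stochastic operation in the package receives its own seed derived
#' from one global seed plus a stable string tag (and optional index), so a
#' whole pipeline is reproducible end-to-end from a single integer while
#' operations stay independent of call order.
#'
#' @param seed Integer global seed.
#' @param tag Character tag naming the operation (e.g. `"render"`).
#' @param index Optional non-negative integer distinguishing repeated uses.
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, "render", 3)
derive_seed <- function(seed, tag, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- 17
  for (code in utf8ToInt(tag)) h <- (h * 131 + code) %% MOD31
  s <- (abs(seed) %% MOD31) * 48271 %% MOD31
  s <- (s + h + (index %% MOD31) * 2654435 + 1) %% MOD31
  as.integer(if (s == 0) 1 else s)
}

#' Evaluate code under a seed without disturbing the caller's RNG stream
#'
#' Sets the seed, evaluates `code`, and restores the previous global RNG
#' state on exit.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Sample an image with bilinear interpolation at arbitrary coordinates
#'
#' Coordinates live in pixel-center space: pixel `(i, j)` has its center at
#' row `i`, column `j` (1-based). Coordinates are clamped to the image
#' bounds; callers that must not sample outside the frame (the no-padding
#' patch extractor) check bounds before calling.
#'
#' @param img Numeric array `H x W x C` (or an `H x W` matrix).
#' @param rows,cols Numeric vectors of equal length with sampling positions.
#' @return A `length(rows) x C` matrix of interpolated values.
#' @keywords internal
bilinear_sample <- function(img, rows, cols) {
  if (length(dim(img)) == 2L) dim(img) <- c(dim(img), 1L)
  d <- dim(img); H <- d[1]; W <- d[2]; C <- d[3]
  rows <- clamp(rows, 1, H); cols <- clamp(cols, 1, W)
  r0 <- pmin(floor(rows), H - 1L); r0 <- pmax(r0, 1)
  c0 <- pmin(floor(cols), W - 1L); c0 <- pmax(c0, 1)
  if (H == 1L) r0 <- rep(1, length(rows))
  if (W == 1L) c0 <- rep(1, length(cols))
  fr <- rows - r0; fc <- cols - c0
  r1 <- pmin(r0 + 1, H); c1 <- pmin(c0 + 1, W)
  w00 <- (1 - fr) * (1 - fc); w01 <- (1 - fr) * fc
  w10 <- fr * (1 - fc); w11 <- fr * fc
  i00 <- (c0 - 1) * H + r0; i01 <- (c1 - 1) * H + r0
  i10 <- (c0 - 1) * H + r1; i11 <- (c1 - 1) * H + r1
  out <- matrix(0, length(rows), C)
  for (ch in seq_len(C)) {
    off <- (ch - 1) * H * W
    out[, ch] <- img[i00 + off] * w00 + img[i01 + off] * w01 +
      img[i10 + off] * w10 + img[i11 + off] * w11
  }
  out
}

# Bilinear upsample of a matrix to target dims, half-pixel-center
# convention: output pixel j maps to input coordinate (j - 0.5)*scale + 0.5.
resize_matrix <- function(m, out_h, out_w) {
  H <- nrow(m); W <- ncol(m)
  rr <- (seq_len(out_h) - 0.5) * (H / out_h) + 0.5
  cc <- (seq_len(out_w) - 0.5) * (W / out_w) + 0.5
  grid_r <- rep(rr, times = out_w)
  grid_c <- rep(cc, each = out_h)
  matrix(bilinear_sample(m, grid_r, grid_c)[, 1], out_h, out_w)
}

# Smooth random field: coarse iid normals bilinearly upsampled to H x W.
# Assumes the caller seeded the RNG.
smooth_noise_field <- function(H, W, grid_h, grid_w, sd = 1) {
  g <- matrix(stats::rnorm(grid_h * grid_w, 0, sd), grid_h, grid_w)
  resize_matrix(g, H, W)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == floor(x)
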