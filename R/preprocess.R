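#' Region-of-interest preprocessing configuration
#'
#' Controls the centered-crop + normalize + resize chain applied to every
#' image before classification. The ROI must be larger than the central
#' cell of the 3x3 capture grid (`roi_fraction > 1/3`) so the crop keeps
#' the mucosa immediately surrounding the lesion, which carries
#' discriminative context. Channel statistics default to the conventional
#' ImageNet values because pretrained backbones expect them.
#'
#' @param roi_fraction Side of the centered crop as a fraction of each
#'   image side, in `(1/3, 1]`. Default 0.5.
#' @param output_side Output square side in pixels after resizing
#'   (default 512).
#' @param channel_mean,channel_std Length-3 per-channel statistics applied
#'   on the `[0, 1]` scale; all std values must be positive.
#' @return A `roi_config` list.
#' @export
#' @examples
#' roi_config(roi_fraction = 0.5, output_side = 64)
roi_config <- function(roi_fraction = 0.5, output_side = 512,
                       channel_mean = c(0.485, 0.456, 0.406),
                       channel_std = c(0.229, 0.224, 0.225)) {
  if (roi_fraction <= 1 / 3 || roi_fraction > 1)
    stop("roi_fraction must be in (1/3, 1]: the ROI must exceed the ",
         "central grid cell")
  if (output_side <= 0) stop("output_side must be positive")
  if (any(channel_std <= 0)) stop("channel_std must be positive")
  structure(list(roi_fraction = roi_fraction, output_side = output_side,
                 channel_mean = channel_mean, channel_std = channel_std),
            class = "roi_config")
}

as_pixels <- function(image) {
  if (inherits(image, "oral_sample")) image$pixels else image
}

#' Centered region-of-interest crop
#'
#' Extracts the axis-aligned centered sub-image of size
#' `floor(fraction * H) x floor(fraction * W)`; pixel values are copied
#' unchanged. With `roi_fraction = 1` the input is returned as is.
#'
#' @param image An `oral_sample` or an `H x W x 3` array.
#' @param config A [roi_config()] (only `roi_fraction` is used).
#' @return The cropped pixel array.
#' @export
#' @examples
#' img <- array(seq_len(48 * 64 * 3), c(48, 64, 3))
#' dim(crop_center_roi(img, roi_config(0.5)))
crop_center_roi <- function(image, config = roi_config()) {
  px <- as_pixels(image)
  d <- dim(px); H <- d[1]; W <- d[2]
  f <- config$roi_fraction
  h <- floor(f * H); w <- floor(f * W)
  if (h <= 1 || w <= 1)
    stop("degenerate crop (", h, "x", w, "); image too small for fraction ", f)
  r0 <- floor((H - h) / 2); c0 <- floor((W - w) / 2)
  px[r0 + seq_len(h), c0 + seq_len(w), , drop = FALSE]
}

#' Intensity normalization
#'
#' Maps 8-bit pixel values to `[0, 1]` and standardizes each channel:
#' `out = (in / 255 - mean_c) / std_c`.
#'
#' @param image `H x W x 3` array with values in `[0, 255]`.
#' @param config A [roi_config()] supplying `channel_mean`/`channel_std`.
#' @return Float array of the same shape.
#' @export
normalize_image <- function(image, config = roi_config()) {
  px <- as_pixels(image)
  if (min(px) < 0 || max(px) > 255) stop("pixel values must lie in [0, 255]")
  out <- px / 255
  for (ch in 1:3)
    out[, , ch] <- (out[, , ch] - config$channel_mean[ch]) / config$channel_std[ch]
  out
}

#' Invert [normalize_image()]
#'
#' @inheritParams normalize_image
#' @return Array on the original `[0, 255]` scale.
#' @export
denormalize_image <- function(image, config = roi_config()) {
  out <- image
  for (ch in 1:3)
    out[, , ch] <- (image[, , ch] * config$channel_std[ch] +
                      config$channel_mean[ch]) * 255
  out
}

#' Bilinear resize to a square
#'
#' Resizes an image to `side x side` with bilinear interpolation under the
#' half-pixel-center convention (output pixel `j` samples input coordinate
#' `(j - 0.5) * scale + 0.5`). Aspect ratio is not preserved, matching the
#' square network input.
#'
#' @param image `H x W x C` array (or `H x W` matrix).
#' @param side Output side in pixels.
#' @return `side x side x C` array (or matrix for matrix input).
#' @export
resize_image <- function(image, side) {
  if (side <= 0) stop("side must be positive")
  px <- as_pixels(image)
  was_matrix <- length(dim(px)) == 2L
  if (was_matrix) dim(px) <- c(dim(px), 1L)
  d <- dim(px)
  out <- array(0, c(side, side, d[3]))
  for (ch in seq_len(d[3]))
    out[, , ch] <- resize_matrix(px[, , ch], side, side)
  if (was_matrix) out[, , 1] else out
}

#' Full preprocessing chain
#'
#' Centered ROI crop, then resize to the configured square side. Set
#' `normalize = TRUE` to also apply channel standardization (for network
#' input); leave `FALSE` to keep the `[0, 255]` scale (for augmentation or
#' display).
#'
#' @inheritParams crop_center_roi
#' @param normalize Apply [normalize_image()] after resizing.
#' @return Processed array.
#' @export
preprocess_image <- function(image, config = roi_config(), normalize = FALSE) {
  out <- resize_image(crop_center_roi(image, config), config$output_side)
  if (normalize) normalize_image(clamp(out, 0, 255), config) else out
}

#' Random-positioning capture simulation
#'
#' Ablation baseline for the centered capture protocol: crops the image at
#' a uniformly random location (window size = `crop_fraction` of each
#' side) and resizes the crop to a square, emulating photographs taken
#' without the lesion-centering rule.
#'
#' @param image An `oral_sample` or `H x W x 3` array.
#' @param crop_fraction Window side as a fraction of each image side.
#' @param rng_seed Integer seed (same seed, same window).
#' @param output_side Output square side (default 512).
#' @return Array `output_side x output_side x 3` with attribute `window`
#'   `(row0, col0, h, w)` recording the crop placement.
#' @export
simulate_random_positioning <- function(image, crop_fraction, rng_seed,
                                        output_side = 512) {
  px <- as_pixels(image)
  d <- dim(px); H <- d[1]; W <- d[2]
  h <- floor(crop_fraction * H); w <- floor(crop_fraction * W)
  if (h < 2 || w < 2) stop("crop_fraction too small for image")
  off <- with_seed(rng_seed,
                   c(sample.int(H - h + 1L, 1L), sample.int(W - w + 1L, 1L)) - 1L)
  crop <- px[off[1] + seq_len(h), off[2] + seq_len(w), , drop = FALSE]
  out <- resize_image(crop, output_side)
  attr(out, "window") <- c(row0 = off[1], col0 = off[2], h = h, w = w)
  out
}
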