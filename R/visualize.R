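#' Class activation map
#'
#' Computes the spatial class-evidence map for one class: the model is
#' run up to (but not including) the global average-pooling layer, the
#' requested channel of the 5-channel post-BN response map (evaluation
#' mode) is taken as the raw activation map, and the map is upsampled by
#' the backbone's reduction factor (16 for the default backbone) with
#' bilinear interpolation to the input size. Because pooling is the only
#' step between this map and the class logit, the spatial mean of the raw
#' map equals the class's pre-softmax logit exactly.
#'
#' @param model A trained `oral_model`.
#' @param image `H x W x 3` raw image in `[0, 255]` at the model's input
#'   size (or already-normalized when `roi_cfg = NULL`).
#' @param class_index Class in `1..num_classes`.
#' @param roi_cfg [roi_config()] for normalization, or `NULL`.
#' @return An `activation_map`: list with `map` (upsampled to `H x W`),
#'   `raw` (pre-upsampling map), `class_index`, `logit`, `normalization`.
#' @export
compute_cam <- function(model, image, class_index, roi_cfg = roi_config()) {
  if (class_index < 1 || class_index > model$num_classes)
    stop("class_index must be in 1..", model$num_classes)
  px <- as_pixels(image)
  d <- dim(px)
  x <- array(px, c(d, 1))
  if (!is.null(roi_cfg)) x <- normalize_batch(x, roi_cfg)
  fw <- model_forward(model, x, training = FALSE)
  raw <- fw$prepool[, , class_index, 1]
  structure(list(map = resize_matrix(raw, d[1], d[2]), raw = raw,
                 class_index = class_index,
                 logit = fw$logits[class_index, 1],
                 normalization = "raw"),
            class = "activation_map")
}

# Fixed blue-cyan-yellow-red heatmap ramp.
cam_colormap <- function(n = 256) {
  ramp <- grDevices::colorRamp(c("#000080", "#0000ff", "#00ffff",
                                 "#ffff00", "#ff0000"))
  ramp(seq(0, 1, length.out = n)) # n x 3 in 0..255
}

#' Overlay an activation map on an image
#'
#' Min-max normalizes the map, passes it through a fixed heatmap
#' colormap, and alpha-blends it over the image. A constant map (no
#' activation contrast) is rendered as a zero map with a warning.
#'
#' @param image `H x W x 3` array in `[0, 255]`.
#' @param map An `activation_map` (or an `H x W` matrix).
#' @param alpha Heatmap opacity in `[0, 1]`: 0 returns the image, 1 the
#'   pure heatmap.
#' @return `H x W x 3` array in `[0, 255]`.
#' @export
overlay_heatmap <- function(image, map, alpha = 0.4) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  px <- as_pixels(image)
  m <- if (inherits(map, "activation_map")) map$map else map
  if (!all(dim(m) == dim(px)[1:2]))
    stop("map size does not match image size")
  rng <- range(m)
  if (diff(rng) <= 0) {
    warning("constant activation map; rendering a zero map")
    m01 <- matrix(0, nrow(m), ncol(m))
  } else m01 <- (m - rng[1]) / diff(rng)
  cmap <- cam_colormap()
  idx <- pmin(pmax(1L, as.integer(m01 * 255) + 1L), 256L)
  heat <- array(0, dim(px))
  for (ch in 1:3) heat[, , ch] <- matrix(cmap[idx, ch], nrow(m), ncol(m))
  clamp((1 - alpha) * px + alpha * heat, 0, 255)
}
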