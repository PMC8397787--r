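#' Rotation/offset-center resampling configuration
#'
#' Parameters of the training-set expansion scheme: every source image is
#' rotated by `{-theta, 0, +theta}` degrees and, for lesion classes, the
#' patch center is additionally moved to `Nt` points near the image center
#' (the first point is the center itself, the rest are uniform in a disc),
#' yielding `3 x Nt` patches per image. Normal images skip the offset
#' stage and contribute 3 rotation patches each. Class-specific `Nt`
#' values double as a class rebalancing knob. All patches are extracted by
#' inverse rotation mapping strictly inside the source frame: no pixel is
#' ever zero-padded or invented.
#'
#' @param theta Rotation step in degrees (default 15).
#' @param nt Named integer vector of offset-center counts per class.
#'   `normal` is forced to 1 (offsets disabled for normals).
#' @param patch_size Optional `(H, W)` patch size in pixels. `NULL`
#'   (default) resolves at use time to the largest square that stays
#'   in-bounds under the worst-case rotation and offset
#'   (see [max_valid_patch_side()]).
#' @param offset_radius Offset-disc radius in pixels. `NULL` resolves to
#'   0.05 of the patch side.
#' @return A `resampling_config` list.
#' @export
#' @examples
#' resampling_config(theta = 15)
resampling_config <- function(theta = 15,
                              nt = c(normal = 1, ulcer = 3, low_risk = 3,
                                     high_risk = 5, cancer = 15),
                              patch_size = NULL, offset_radius = NULL) {
  if (theta < 0) stop("theta must be >= 0")
  nt <- nt[oral_classes()]
  names(nt) <- oral_classes()
  nt["normal"] <- 1
  if (any(is.na(nt)) || any(nt < 1)) stop("nt must give an integer >= 1 per class")
  structure(list(theta = theta, nt = nt, patch_size = patch_size,
                 offset_radius = offset_radius),
            class = "resampling_config")
}

#' Rotation angles for the three-patch expansion
#'
#' @param theta Step in degrees (`>= 0`).
#' @return `c(-theta, 0, theta)`, collapsed to `0` when `theta = 0`.
#' @export
#' @examples
#' rotation_angles(15)
rotation_angles <- function(theta) {
  if (theta < 0) stop("theta must be >= 0")
  if (theta == 0) 0 else c(-theta, 0, theta)
}

#' Largest patch side that never samples outside the frame
#'
#' For a square patch of side `s` rotated by any angle of magnitude up to
#' `theta` about a center anywhere within `offset_radius` of the image
#' center, the rotated square's axis-aligned extent is
#' `s * (|cos theta| + |sin theta|)`; staying inside requires
#' `s * (cos theta + sin theta) + 2 * offset_radius <= min(H, W)`
#' (for `theta` in `[0, 45]` degrees the extent is monotone in the angle,
#' so the configured `theta` is the worst case).
#'
#' @param image_size `(H, W)` in pixels.
#' @param theta Maximum rotation magnitude, degrees.
#' @param offset_radius Maximum center offset, pixels.
#' @return Integer patch side.
#' @export
#' @examples
#' max_valid_patch_side(c(512, 512), 45, 0)  # floor(512 / sqrt(2))
max_valid_patch_side <- function(image_size, theta, offset_radius = 0) {
  stopifnot(all(image_size > 0), theta >= 0, offset_radius >= 0)
  a <- min(abs(theta), 45) * pi / 180  # extent is maximal at 45 degrees
  ext <- abs(cos(a)) + abs(sin(a))
  floor((min(image_size) - 2 * offset_radius) / ext)
}

# Resolve patch side and offset radius for a config on a given image size.
resolve_patch_geometry <- function(config, image_size) {
  off <- config$offset_radius
  side <- if (!is.null(config$patch_size)) min(config$patch_size)
  if (is.null(side) && is.null(off)) {
    # side = max_valid with off = 0.05 * side:
    # s*(cos+sin) + 0.1*s <= min(H,W)
    a <- min(abs(config$theta), 45) * pi / 180
    side <- floor(min(image_size) / (cos(a) + sin(a) + 0.1))
    off <- 0.05 * side
  } else if (is.null(side)) {
    side <- max_valid_patch_side(image_size, config$theta, off)
  } else if (is.null(off)) {
    off <- 0.05 * side
    max_side <- max_valid_patch_side(image_size, config$theta, off)
    if (side > max_side)
      stop("patch side ", side, " exceeds the no-padding bound ", max_side)
  }
  hw <- if (!is.null(config$patch_size)) config$patch_size else c(side, side)
  list(patch = hw, offset_radius = off)
}

#' Extract a rotated patch by inverse mapping, without padding
#'
#' Samples an `H x W` patch whose frame is rotated by `angle` degrees
#' about `center`, using bilinear interpolation of the source image. Every
#' sampling coordinate is checked against the source bounds first; an
#' out-of-bounds request is an error — the extractor never pads, so a
#' patch contains only genuine source pixels. At `angle = 0` and integer
#' geometry the result equals a plain crop exactly.
#'
#' @param image An `oral_sample` or `H x W x 3` array.
#' @param center `(row, col)` patch center in source pixels.
#' @param angle Rotation in degrees (counterclockwise image rotation).
#' @param size `(H, W)` patch size in pixels.
#' @return `H x W x 3` array.
#' @export
extract_rotated_patch <- function(image, center, angle, size) {
  px <- as_pixels(image)
  d <- dim(px); H <- d[1]; W <- d[2]
  h <- size[1]; w <- size[2]
  a <- angle * pi / 180
  dr <- rep(seq_len(h) - (h + 1) / 2, times = w)
  dc <- rep(seq_len(w) - (w + 1) / 2, each = h)
  # rotating the image by +angle about the center is equivalent to
  # sampling the source at center + R(-angle) (patch offset)
  src_r <- center[1] + cos(a) * dr + sin(a) * dc
  src_c <- center[2] - sin(a) * dr + cos(a) * dc
  eps <- 1e-6
  if (min(src_r) < 1 - eps || max(src_r) > H + eps ||
      min(src_c) < 1 - eps || max(src_c) > W + eps)
    stop(sprintf(paste0("patch (center %.1f,%.1f angle %.1f size %dx%d) ",
                        "samples outside the %dx%d source; refusing to pad"),
                 center[1], center[2], angle, h, w, H, W))
  vals <- bilinear_sample(px, src_r, src_c)
  array(vals, c(h, w, dim(px)[3]))
}

#' Draw offset centers in a disc around the lesion center
#'
#' The first returned center is always the input center; the remaining
#' `nt - 1` are uniform in the disc of radius `offset_radius`, emulating
#' the imprecision of hand-held lesion centering.
#'
#' @param center `(row, col)`.
#' @param nt Number of centers (`>= 1`).
#' @param offset_radius Disc radius in pixels.
#' @param rng_seed Integer seed.
#' @return `nt x 2` matrix of centers.
#' @export
sample_offset_centers <- function(center, nt, offset_radius, rng_seed) {
  stopifnot(is_count(nt), nt >= 1, offset_radius >= 0)
  if (nt == 1) return(matrix(center, 1, 2))
  with_seed(rng_seed, {
    r <- offset_radius * sqrt(stats::runif(nt - 1))
    ang <- stats::runif(nt - 1, 0, 2 * pi)
    rbind(center,
          cbind(center[1] + r * cos(ang), center[2] + r * sin(ang)),
          deparse.level = 0)
  })
}

# Patch descriptors (angle x center grid) for one source image.
resample_descriptors <- function(label, image_size, config, rng_seed) {
  geo <- resolve_patch_geometry(config, image_size)
  angles <- rotation_angles(config$theta)
  img_center <- (image_size + 1) / 2
  centers <- if (label == "normal") matrix(img_center, 1, 2) else
    sample_offset_centers(img_center, config$nt[[label]],
                          geo$offset_radius, rng_seed)
  grid <- expand.grid(angle = angles, center = seq_len(nrow(centers)))
  list(angles = grid$angle,
       centers = centers[grid$center, , drop = FALSE],
       patch = geo$patch)
}

#' Expand one labeled image into its resampling patch set
#'
#' Applies the full rotation/offset-center expansion to one image: normal
#' images yield the 3 rotation patches about the image center; lesion
#' images yield `3 x Nt(class)` patches over the offset centers. All
#' patches are extracted with [extract_rotated_patch()] and therefore
#' contain no padded pixels.
#'
#' @param sample An `oral_sample` (with pixels).
#' @param config A [resampling_config()].
#' @param rng_seed Integer seed for the offset draws.
#' @return An `oral_patchset`: list with `source_id`, `patches` (list of
#'   arrays), `angles`, `centers`.
#' @export
expand_case <- function(sample, config = resampling_config(), rng_seed = 1L) {
  stopifnot(inherits(sample, "oral_sample"))
  d <- dim(sample$pixels)[1:2]
  desc <- resample_descriptors(sample$label, d, config, rng_seed)
  patches <- lapply(seq_along(desc$angles), function(i)
    extract_rotated_patch(sample$pixels, desc$centers[i, ], desc$angles[i],
                          desc$patch))
  structure(list(source_id = sample$source_id, label = sample$label,
                 patches = patches, angles = desc$angles,
                 centers = desc$centers),
            class = "oral_patchset")
}

#' Expand a training manifest by rotation/offset-center resampling
#'
#' Applies the expansion bookkeeping to every training image in a
#' manifest: each source row becomes `3 x Nt(class)` patch rows (3 for
#' normals) carrying the rotation angle and patch center, so per-class
#' counts obey `expanded = base x 3 x Nt` exactly. Pixels are not touched
#' here; patches are materialized lazily with [extract_patch_row()].
#'
#' @param manifest An `oral_manifest`; if a `split` column is present only
#'   `split == "train"` rows are expanded.
#' @param config A [resampling_config()].
#' @param rng_seed Integer seed.
#' @return List with `manifest` (expanded patch-level `data.frame` with
#'   columns of the source rows plus `angle`, `patch_row`, `patch_col`,
#'   `patch_h`, `patch_w`) and `counts` (list with per-class `base` and
#'   `expanded` integer vectors).
#' @export
#' @examples
#' m <- generate_manifest(c(4, 2, 0, 0, 1), rng_seed = 1)
#' build_training_set(m, resampling_config(), rng_seed = 1)$counts$expanded
build_training_set <- function(manifest, config = resampling_config(),
                               rng_seed = 1L) {
  train <- if ("split" %in% names(manifest))
    manifest[manifest$split == "train", , drop = FALSE] else manifest
  canvas <- attr(manifest, "canvas") %||% c(768, 1024)
  base <- class_counts(train)
  if (nrow(train) == 0)
    return(list(manifest = train, counts = list(base = base, expanded = base)))
  pieces <- lapply(seq_len(nrow(train)), function(i) {
    row <- train[i, , drop = FALSE]
    desc <- resample_descriptors(row$label, canvas, config,
                                 derive_seed(rng_seed, "offsets", i))
    n <- length(desc$angles)
    out <- row[rep(1L, n), , drop = FALSE]
    out$angle <- desc$angles
    out$patch_row <- desc$centers[, 1]
    out$patch_col <- desc$centers[, 2]
    out$patch_h <- desc$patch[1]
    out$patch_w <- desc$patch[2]
    out
  })
  expanded <- do.call(rbind, pieces)
  rownames(expanded) <- NULL
  attr(expanded, "canvas") <- canvas
  list(manifest = expanded,
       counts = list(base = base, expanded = class_counts(expanded)))
}

#' Materialize the patch for one expanded-manifest row
#'
#' @param expanded Patch-level `data.frame` from [build_training_set()].
#' @param i Row index.
#' @param source An `oral_sample` for the row's source image; `NULL`
#'   renders it from the manifest columns.
#' @return `H x W x 3` pixel array.
#' @export
extract_patch_row <- function(expanded, i, source = NULL) {
  row <- expanded[i, ]
  if (is.null(source)) source <- render_manifest_image(expanded, i)
  extract_rotated_patch(source, c(row$patch_row, row$patch_col),
                        row$angle, c(row$patch_h, row$patch_w))
}

#' Random over-sampling baseline
#'
#' Duplicates minority-class rows uniformly at random (with replacement)
#' until every class matches the majority class count. All original rows
#' are kept, so the original multiset is preserved. This is the classic
#' class-balancing baseline that the rotation/offset resampling scheme is
#' compared against.
#'
#' @param manifest A manifest `data.frame` with a `label` column.
#' @param rng_seed Integer seed.
#' @return The balanced manifest.
#' @export
random_oversample <- function(manifest, rng_seed = 1L) {
  stopifnot(nrow(manifest) > 0)
  counts <- class_counts(manifest)
  present <- names(counts)[counts > 0]
  target <- max(counts)
  extra <- lapply(present, function(lab) {
    idx <- which(manifest$label == lab)
    need <- target - length(idx)
    if (need == 0) return(NULL)
    dup <- with_seed(derive_seed(rng_seed, paste0("oversample_", lab)),
                     sample(idx, need, replace = TRUE))
    manifest[dup, , drop = FALSE]
  })
  out <- rbind(manifest, do.call(rbind, extra))
  rownames(out) <- NULL
  attr(out, "canvas") <- attr(manifest, "canvas")
  out
}
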