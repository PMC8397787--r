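#' The five oral diagnostic classes
#'
#' Canonical lowercase tokens for the five-category clinical impression:
#' healthy mucosa, aphthous ulcer, low-risk (homogeneous) OPMD, high-risk
#' (nonhomogeneous) OPMD, and oral cancer. All label columns in manifests
#' use these tokens, in this order.
#'
#' @return Character vector of length 5.
#' @export
#' @examples
#' oral_classes()
oral_classes <- function() c("normal", "ulcer", "low_risk", "high_risk", "cancer")

canonical_label <- function(x) {
  key <- gsub("[^a-z]+", "_", tolower(trimws(as.character(x))))
  key <- gsub("_+", "_", gsub("^_|_$", "", key))
  map <- c(
    normal = "normal", healthy = "normal",
    ulcer = "ulcer", aphthous_ulcer = "ulcer",
    low_risk = "low_risk", low_risk_opmd = "low_risk", lowrisk = "low_risk",
    high_risk = "high_risk", high_risk_opmd = "high_risk", highrisk = "high_risk",
    cancer = "cancer", oral_cancer = "cancer", oscc = "cancer"
  )
  out <- unname(map[key])
  out
}

#' Describe one lesion to be rendered
#'
#' A lesion specification holds everything `render_oral_image()` needs:
#' the class, where the lesion sits, how big it is, and how irregular its
#' boundary is. `"normal"` means no lesion (diameter is forced to 0).
#'
#' @param class_label One of [oral_classes()].
#' @param center Numeric `(row, col)` of the lesion center in pixels.
#'   Ignored for `"normal"`.
#' @param diameter Lesion diameter in pixels (0 for `"normal"`).
#' @param irregularity Boundary irregularity in `[0, 1]`; `NULL` picks a
#'   class-typical default (ulcers are round, cancers ragged).
#' @return An object of class `lesion_spec`.
#' @export
#' @examples
#' lesion_spec("ulcer", center = c(384, 512), diameter = 160)
lesion_spec <- function(class_label, center = c(NA_real_, NA_real_),
                        diameter = 0, irregularity = NULL) {
  class_label <- canonical_label(class_label)
  if (is.na(class_label) || !class_label %in% oral_classes())
    stop("unknown class label; expected one of: ",
         paste(oral_classes(), collapse = ", "))
  if (class_label == "normal") diameter <- 0
  if (diameter < 0) stop("diameter must be >= 0")
  default_irr <- c(normal = 0, ulcer = 0.08, low_risk = 0.18,
                   high_risk = 0.35, cancer = 0.45)
  irregularity <- irregularity %||% unname(default_irr[class_label])
  if (irregularity < 0 || irregularity > 1)
    stop("irregularity must be in [0, 1]")
  structure(list(class_label = class_label,
                 center = as.numeric(center),
                 diameter = as.numeric(diameter),
                 irregularity = as.numeric(irregularity)),
            class = "lesion_spec")
}

# Per-class color anchors (RGB, 0-255). Chosen so the five classes have
# clearly distinct color/texture statistics: yellow ulcer core with a red
# halo, uniform pale low-risk patch, pale-with-red high-risk patch, dark
# nodular cancer, plain pink mucosa for normal.
lesion_palette <- function() {
  list(
    mucosa = c(205, 118, 122),
    ulcer_core = c(232, 214, 150),
    ulcer_halo = c(182, 62, 60),
    low_risk = c(234, 228, 214),
    high_risk_white = c(228, 219, 202),
    high_risk_red = c(172, 55, 52),
    cancer = c(128, 52, 54)
  )
}

# Textured pink mucosa background. RNG must be seeded by the caller.
render_background <- function(height, width) {
  pal <- lesion_palette()
  base <- pal$mucosa + stats::rnorm(3, 0, 6)
  ang <- stats::runif(1, 0, 2 * pi)
  amp <- stats::runif(1, 6, 14)
  rc <- matrix(seq(-1, 1, length.out = height), height, width)
  cc <- matrix(seq(-1, 1, length.out = width), height, width, byrow = TRUE)
  grad <- amp * (cos(ang) * rc + sin(ang) * cc)
  gh <- max(4L, round(height / 32)); gw <- max(4L, round(width / 32))
  mottle <- smooth_noise_field(height, width, gh, gw, sd = 6)
  lum <- grad + mottle
  img <- array(0, c(height, width, 3))
  for (ch in 1:3)
    img[, , ch] <- base[ch] + lum + stats::rnorm(height * width, 0, 2.5)
  img
}

# Soft irregular radial mask machinery shared by all lesion classes.
# Returns t = d / r(phi) (normalized radial coordinate), where r(phi)
# modulates the radius with low-order harmonics scaled by irregularity.
lesion_radial_field <- function(height, width, center, radius, irregularity) {
  dr <- matrix(seq_len(height) - center[1], height, width)
  dc <- matrix(seq_len(width) - center[2], height, width, byrow = TRUE)
  d <- sqrt(dr^2 + dc^2)
  phi <- atan2(dc, dr)
  ph <- stats::runif(3, 0, 2 * pi)
  mod <- 1 + irregularity * (0.45 * sin(2 * phi + ph[1]) +
                             0.30 * sin(3 * phi + ph[2]) +
                             0.20 * sin(5 * phi + ph[3]))
  d / pmax(radius * mod, 1e-6)
}

#' Render one synthetic oral-cavity image
#'
#' Draws a textured pink-mucosa background and, for lesion classes, a
#' procedural lesion with the class's clinical visual signature: aphthous
#' ulcers as a round yellow pseudomembrane core inside an erythematous
#' halo; low-risk OPMD as a uniform flat pale patch; high-risk OPMD as an
#' irregular pale patch with red components mixed in; cancer as a dark,
#' strongly textured nodular mass with shaded margins. These are
#' procedural caricatures tuned for class separability and geometry, not
#' photorealistic renderings.
#'
#' @param spec A [lesion_spec()].
#' @param height,width Canvas size in pixels; must have a 4:3 aspect ratio
#'   (`width / height = 4 / 3`).
#' @param rng_seed Integer seed; the same seed yields a bit-identical image.
#' @param patient_id,protocol,source_id Metadata carried into the sample.
#' @return An `oral_sample`: list with integer `pixels` (`H x W x 3` in
#'   `[0, 255]`), `label`, `patient_id`, `protocol`, `source_id`, and the
#'   rendered lesion geometry (`center`, `diameter`).
#' @export
#' @examples
#' s <- render_oral_image(lesion_spec("ulcer", c(96, 128), 48), 192, 256, 1)
#' dim(s$pixels)
render_oral_image <- function(spec, height, width, rng_seed,
                              patient_id = NA_character_,
                              protocol = "centered",
                              source_id = NA_character_) {
  stopifnot(inherits(spec, "lesion_spec"))
  if (abs(width / height - 4 / 3) > 1e-9)
    stop("canvas must have 4:3 aspect ratio; got ", width, "x", height)
  lab <- spec$class_label
  if (lab != "normal") {
    r <- spec$diameter / 2
    if (any(is.na(spec$center)))
      stop("lesion classes require a center; see place_lesion()")
    if (spec$center[1] - r < 1 || spec$center[1] + r > height ||
        spec$center[2] - r < 1 || spec$center[2] + r > width)
      stop(sprintf(
        "lesion (center %.1f,%.1f diameter %.1f) exceeds image bounds %dx%d",
        spec$center[1], spec$center[2], spec$diameter, height, width))
  }
  img <- with_seed(rng_seed, {
    bg <- render_background(height, width)
    if (lab == "normal") bg else {
      pal <- lesion_palette()
      R <- spec$diameter / 2
      t <- lesion_radial_field(height, width, spec$center, R, spec$irregularity)
      ew <- max(0.03, 2.5 / R)            # soft-edge width in t units
      m <- stats::plogis((1 - t) / ew)    # lesion support mask
      gh <- max(4L, round(height / 24)); gw <- max(4L, round(width / 24))
      layer <- array(0, c(height, width, 3))
      if (lab == "ulcer") {
        core <- stats::plogis((0.55 - t) / 0.06)
        for (ch in 1:3)
          layer[, , ch] <- pal$ulcer_core[ch] * core +
            pal$ulcer_halo[ch] * (1 - core)
      } else if (lab == "low_risk") {
        tex <- smooth_noise_field(height, width, gh, gw, sd = 4)
        for (ch in 1:3) layer[, , ch] <- pal$low_risk[ch] + tex
        m <- m * 0.9                      # thin, slightly translucent patch
      } else if (lab == "high_risk") {
        blotch <- smooth_noise_field(height, width, gh, gw, sd = 1)
        redm <- stats::plogis((blotch - 0.25) / 0.15)
        for (ch in 1:3)
          layer[, , ch] <- pal$high_risk_white[ch] * (1 - redm) +
            pal$high_risk_red[ch] * redm
      } else {                            # cancer
        bump <- smooth_noise_field(height, width,
                                   max(6L, round(height / 12)),
                                   max(6L, round(width / 12)), sd = 14)
        shade <- -35 * stats::plogis((t - 0.75) / 0.08)
        for (ch in 1:3) layer[, , ch] <- pal$cancer[ch] + bump + shade
      }
      for (ch in 1:3) bg[, , ch] <- bg[, , ch] * (1 - m) + layer[, , ch] * m
      bg
    }
  })
  structure(list(
    pixels = round(clamp(img, 0, 255)),
    label = lab, patient_id = patient_id, protocol = protocol,
    source_id = source_id, center = spec$center, diameter = spec$diameter
  ), class = "oral_sample")
}

#' Place a lesion under the centered or random capture protocol
#'
#' The centered protocol emulates framing the lesion inside the central
#' cell of the camera's 3x3 grid: the center is uniform over the central
#' ninth of the frame and the diameter must not exceed 0.9 of the central
#' cell side. The random protocol places the center uniformly anywhere
#' that keeps the lesion fully inside the frame.
#'
#' @param protocol `"centered"` or `"random"`.
#' @param image_size Integer `(H, W)`.
#' @param diameter Lesion diameter in pixels (0 allowed).
#' @param rng_seed Integer seed.
#' @return Numeric `(row, col)` center.
#' @export
#' @examples
#' place_lesion("centered", c(768, 1024), 120, 1)
place_lesion <- function(protocol = c("centered", "random"), image_size,
                         diameter, rng_seed) {
  protocol <- match.arg(protocol)
  H <- image_size[1]; W <- image_size[2]
  if (diameter >= min(H, W)) stop("diameter ", diameter,
                                  " does not fit image ", H, "x", W)
  with_seed(rng_seed, {
    if (protocol == "centered") {
      cell <- min(H, W) / 3
      if (diameter > 0.9 * cell)
        stop(sprintf(paste0("centered protocol requires diameter <= 0.9 x ",
                            "central cell side (%.1f); got %.1f"),
                     0.9 * cell, diameter))
      c(stats::runif(1, H / 3, 2 * H / 3), stats::runif(1, W / 3, 2 * W / 3))
    } else {
      r <- diameter / 2
      c(stats::runif(1, 1 + r, H - r), stats::runif(1, 1 + r, W - r))
    }
  })
}

# lambda of a zero-truncated Poisson whose mean is m (m >= 1).
ztp_lambda <- function(m) {
  if (m <= 1 + 1e-9) return(0)
  stats::uniroot(function(l) l / (1 - exp(-l)) - m,
                 lower = 1e-8, upper = max(2 * m, 10))$root
}

rztp <- function(n, lambda) {
  if (lambda <= 0) return(rep(1L, n))
  p0 <- exp(-lambda)
  stats::qpois(p0 + stats::runif(n) * (1 - p0), lambda)
}

#' Generate a synthetic dataset manifest
#'
#' Builds the bookkeeping for a synthetic oral dataset: per-class sample
#' counts, patient structure (normal subjects contribute several images
#' from different anatomic sites; lesion patients contribute about one
#' image each), the capture protocol, and per-sample lesion geometry and
#' render seeds so that images can be rendered reproducibly on demand with
#' [render_manifest_image()]. Per-patient image counts are drawn from a
#' zero-truncated Poisson matched to the requested mean.
#'
#' @param n_per_class Integer vector of 5 image counts, in
#'   [oral_classes()] order.
#' @param images_per_patient Numeric vector of 5 mean images/patient per
#'   class. Default matches a clinic-style dataset where healthy subjects
#'   average 3.28 images and cancer patients exactly 1.
#' @param protocol `"centered"` or `"random"` capture protocol.
#' @param canvas Integer `(H, W)` 4:3 canvas used when rendering.
#' @param diameter_frac Range of lesion diameter as a fraction of the
#'   central grid-cell side (`min(H, W) / 3`).
#' @param rng_seed Integer seed.
#' @return An `oral_manifest`: a `data.frame` with columns `sample_id`,
#'   `label`, `patient_id`, `protocol`, `center_row`, `center_col`,
#'   `diameter`, `irregularity`, `render_seed`, `path`, and attribute
#'   `canvas`.
#' @export
#' @examples
#' m <- generate_manifest(c(10, 5, 5, 5, 5), rng_seed = 1)
#' table(m$label)
generate_manifest <- function(n_per_class,
                              images_per_patient = c(3.28, 1.15, 1.40, 1.32, 1.00),
                              protocol = c("centered", "random"),
                              canvas = c(768, 1024),
                              diameter_frac = c(0.5, 0.9),
                              rng_seed = 1L) {
  protocol <- match.arg(protocol)
  stopifnot(length(n_per_class) == 5, all(vapply(n_per_class, is_count, TRUE)),
            length(images_per_patient) == 5, all(images_per_patient >= 1))
  H <- canvas[1]; W <- canvas[2]
  if (abs(W / H - 4 / 3) > 1e-9) stop("canvas must be 4:3")
  cell <- min(H, W) / 3
  classes <- oral_classes()
  rows <- list()
  for (k in seq_along(classes)) {
    n <- n_per_class[k]
    if (n == 0) next
    lab <- classes[k]
    lam <- ztp_lambda(images_per_patient[k])
    sizes <- with_seed(derive_seed(rng_seed, "patients", k), {
      s <- integer(0)
      while (sum(s) < n) s <- c(s, rztp(max(16L, ceiling(n / 2)), lam))
      cut <- which(cumsum(s) >= n)[1]
      s <- s[seq_len(cut)]
      s[cut] <- s[cut] - (sum(s) - n)
      s[s > 0]
    })
    pid <- rep(sprintf("%s_p%04d", lab, seq_along(sizes)), sizes)
    geom <- with_seed(derive_seed(rng_seed, "geometry", k), {
      d <- if (lab == "normal") rep(0, n) else
        stats::runif(n, diameter_frac[1], diameter_frac[2]) * cell
      seeds <- sample.int(MOD31 - 1L, n)
      list(d = d, seeds = seeds)
    })
    centers <- t(vapply(seq_len(n), function(i)
      place_lesion(protocol, c(H, W), geom$d[i],
                   derive_seed(rng_seed, paste0("place_", lab), i)),
      c(0, 0)))
    rows[[k]] <- data.frame(
      sample_id = sprintf("%s_%04d", lab, seq_len(n)),
      label = lab, patient_id = pid, protocol = protocol,
      center_row = centers[, 1], center_col = centers[, 2],
      diameter = geom$d,
      irregularity = lesion_spec(lab, diameter = 0)$irregularity,
      render_seed = geom$seeds, path = NA_character_,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows) %||% data.frame()
  rownames(out) <- NULL
  structure(out, canvas = c(H, W), class = c("oral_manifest", "data.frame"))
}

#' Render the image for one manifest row
#'
#' @param manifest An `oral_manifest`.
#' @param i Row index.
#' @return An `oral_sample` (see [render_oral_image()]).
#' @export
render_manifest_image <- function(manifest, i) {
  row <- manifest[i, ]
  canvas <- attr(manifest, "canvas") %||% c(768, 1024)
  spec <- lesion_spec(row$label, c(row$center_row, row$center_col),
                      row$diameter, row$irregularity)
  render_oral_image(spec, canvas[1], canvas[2], row$render_seed,
                    patient_id = row$patient_id, protocol = row$protocol,
                    source_id = row$sample_id)
}

#' Patient-disjoint train/test split
#'
#' Assigns every image to `train` or `test` such that no patient appears
#' on both sides. Per-class test sizes are taken either as a fraction or
#' as explicit counts; because assignment is at patient granularity, a
#' greedy fill plus a single-swap repair is used to hit explicit counts
#' exactly whenever a patient-granular solution exists.
#'
#' @param manifest An `oral_manifest`.
#' @param test_fraction Per-class test fraction (recycled to 5).
#' @param test_counts Optional integer vector of 5 explicit per-class test
#'   image counts (overrides `test_fraction`).
#' @param rng_seed Integer seed.
#' @return The manifest with a `split` column.
#' @export
split_by_patient <- function(manifest, test_fraction = 0.3,
                             test_counts = NULL, rng_seed = 1L) {
  stopifnot(is.data.frame(manifest), nrow(manifest) > 0)
  classes <- oral_classes()
  test_fraction <- rep_len(test_fraction, 5)
  manifest$split <- "train"
  for (k in seq_along(classes)) {
    idx <- which(manifest$label == classes[k])
    if (!length(idx)) next
    target <- if (!is.null(test_counts)) test_counts[k] else
      round(length(idx) * test_fraction[k])
    pats <- split(idx, manifest$patient_id[idx])
    ord <- with_seed(derive_seed(rng_seed, "split", k),
                     sample(length(pats)))
    pats <- pats[ord]
    sizes <- lengths(pats)
    take <- logical(length(pats)); got <- 0
    for (j in seq_along(pats)) {
      if (got + sizes[j] <= target) { take[j] <- TRUE; got <- got + sizes[j] }
    }
    if (got < target) {  # single-swap repair toward the exact count
      need <- target - got
      cand <- which(!take & sizes == need)
      if (length(cand)) { take[cand[1]] <- TRUE; got <- target }
      else {
        for (j in which(take)) {
          cand <- which(!take & sizes == sizes[j] + need)
          if (length(cand)) {
            take[j] <- FALSE; take[cand[1]] <- TRUE; got <- target; break
          }
        }
      }
    }
    manifest$split[unlist(pats[take])] <- "test"
  }
  manifest
}

#' Per-class image counts of a manifest
#'
#' @param manifest An `oral_manifest` (optionally with a `split` column).
#' @param split Optional split to restrict to (`"train"` or `"test"`).
#' @return Named integer vector over [oral_classes()].
#' @export
class_counts <- function(manifest, split = NULL) {
  if (!is.null(split) && "split" %in% names(manifest))
    manifest <- manifest[manifest$split == split, ]
  tab <- table(factor(manifest$label, levels = oral_classes()))
  stats::setNames(as.integer(tab), oral_classes())
}
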