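#' Read a dataset manifest from CSV
#'
#' The manifest format is a CSV with header columns `path`, `label`,
#' `patient_id`, and optionally `protocol` and `split`. Labels are mapped
#' case-insensitively onto the canonical tokens of [oral_classes()]
#' (`"Cancer"`, `"aphthous ulcer"`, `"low-risk OPMD"` etc. are accepted);
#' unknown labels are rejected with the offending row reported.
#'
#' @param path CSV file path.
#' @param check_paths Verify that every referenced image file exists.
#' @return An `oral_manifest` `data.frame`.
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("path", "label", "patient_id")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("manifest is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  lab <- canonical_label(df$label)
  if (anyNA(lab)) {
    bad <- which(is.na(lab))[1]
    stop("unknown label '", df$label[bad], "' in manifest row ", bad)
  }
  df$label <- lab
  if (!"protocol" %in% names(df)) df$protocol <- "centered"
  if (check_paths) {
    ok <- file.exists(df$path)
    if (!all(ok))
      stop("image file not found for manifest row ", which(!ok)[1], ": ",
           df$path[which(!ok)[1]])
  }
  structure(df, class = c("oral_manifest", "data.frame"))
}

#' Write a manifest to CSV
#'
#' @param manifest An `oral_manifest`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(as.data.frame(manifest), path, row.names = FALSE)
  invisible(path)
}

#' Read/write an image as PNG
#'
#' Images are exchanged as 8-bit PNG; in memory they are `H x W x 3`
#' arrays on the `[0, 255]` scale.
#'
#' @param path PNG file path.
#' @param image `H x W x 3` array in `[0, 255]`.
#' @return `read_image` returns the pixel array.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image not found: ", path)
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), c(dim(a), 3))
  round(a[, , 1:3, drop = FALSE] * 255)
}

#' @rdname read_image
#' @export
write_image <- function(image, path) {
  px <- as_pixels(image)
  png::writePNG(clamp(px, 0, 255) / 255, path)
  invisible(path)
}

# Small stable content hash (FNV-1a over the serialized object).
config_hash <- function(x) {
  bytes <- serialize(x, NULL, version = 2)
  h <- 2166136261
  for (b in as.integer(bytes[seq(1, length(bytes),
                                 by = max(1L, length(bytes) %/% 512))])) {
    h <- bitwXor(as.integer(h %% 2^31), b) * 16777619
    h <- h %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Write an evaluation/run report as JSON
#'
#' Produces a JSON report with stable key order containing the seed, a
#' configuration hash, counts and metrics. Reports written from the same
#' results and seed are byte-identical apart from the timestamp field.
#'
#' @param results Named list of result objects (coerced via
#'   `jsonlite`).
#' @param path Output path.
#' @param seed Seed recorded in the report.
#' @param config Optional configuration list (hashed and embedded).
#' @return The path, invisibly.
#' @export
write_report <- function(results, path, seed = NA_integer_, config = NULL) {
  payload <- list(
    package = "oralscope",
    version = as.character(utils::packageVersion("oralscope")),
    seed = seed,
    config_hash = if (!is.null(config)) config_hash(config) else NA_character_,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    results = results
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", force = TRUE)
  invisible(path)
}

#' Read a report written by [write_report()]
#'
#' @param path JSON report path.
#' @return The report as a list.
#' @export
read_report <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

#' Read/write a run configuration as YAML
#'
#' A run configuration nests the module configurations plus a global seed
#' and paths; every stochastic operation derives its own seed from the
#' global seed and a stable tag ([derive_seed()]), so a whole pipeline is
#' reproducible from this one file.
#'
#' @param path YAML file path.
#' @param config Named list.
#' @return `read_run_config` returns the list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  yaml::read_yaml(path)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Default run configuration
#'
#' @param seed Global seed.
#' @return Nested configuration list with all module defaults embedded.
#' @export
default_run_config <- function(seed = 1L) {
  list(
    seed = seed,
    synth = list(n_per_class = c(50, 50, 50, 50, 50),
                 images_per_patient = c(3.28, 1.15, 1.40, 1.32, 1.00),
                 protocol = "centered", canvas = c(768, 1024),
                 diameter_frac = c(0.5, 0.9)),
    preprocess = list(roi_fraction = 0.5, output_side = 512,
                      channel_mean = c(0.485, 0.456, 0.406),
                      channel_std = c(0.229, 0.224, 0.225)),
    resample = list(theta = 15,
                    nt = list(normal = 1, ulcer = 3, low_risk = 3,
                              high_risk = 5, cancer = 15)),
    train = unclass(train_config()),
    augment = unclass(augment_config())
  )
}
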