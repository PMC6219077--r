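#' Read a fundus image from disk
#'
#' Reads PNG/TIFF/JPEG pixels (any bit depth; rescaled to 0-255), an optional
#' field-of-view mask and optional per-sign ground-truth masks stored as
#' single-channel images where nonzero marks the lesion.
#'
#' @param path Image file.
#' @param mask_paths Optional named character vector of per-sign mask files
#'   (names among exudate/hemorrhage/microaneurysm).
#' @param fov_path Optional field-of-view mask file.
#' @param id Identifier; defaults to the file name.
#' @return A [fundus_image()].
#' @export
read_fundus_image <- function(path, mask_paths = NULL, fov_path = NULL,
                              id = NULL) {
  px <- read_image_array(path)
  read_mask <- function(p) {
    m <- read_image_array(p)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    m > 0
  }
  fundus_image(px,
               fov_mask = if (is.null(fov_path)) NULL else read_mask(fov_path),
               gt_masks = if (is.null(mask_paths)) NULL else
                 lapply(as.list(mask_paths), read_mask),
               id = id %||% tools::file_path_sans_ext(basename(path)))
}

read_image_array <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
              png = png::readPNG(path),
              tif = , tiff = tiff::readTIFF(path),
              EBImage::imageData(EBImage::readImage(path)))
  if (ext %in% c("png", "tif", "tiff")) {
    a <- a * 255 # these readers return [0,1]
  }
  if (length(dim(a)) == 3L && dim(a)[3] == 4L) a <- a[, , 1:3] # drop alpha
  a
}

#' Write a fundus image (and optionally its masks) as PNG
#'
#' @param image A [fundus_image()].
#' @param path Output PNG for the pixels.
#' @param mask_dir Optional directory for per-sign mask PNGs and the FOV.
#' @return `path`, invisibly.
#' @export
write_fundus_image <- function(image, path, mask_dir = NULL) {
  stopifnot(is_fundus_image(image))
  px <- image$pixels / 255
  if (dim(px)[3] == 1L) px <- px[, , 1]
  png::writePNG(pmin(pmax(px, 0), 1), path)
  if (!is.null(mask_dir)) {
    dir.create(mask_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(image$gt_masks)) {
      png::writePNG(image$gt_masks[[nm]] * 1,
                    file.path(mask_dir, sprintf("%s_%s.png", image$id, nm)))
    }
    if (!is.null(image$fov_mask)) {
      png::writePNG(image$fov_mask * 1,
                    file.path(mask_dir, sprintf("%s_fov.png", image$id)))
    }
  }
  invisible(path)
}

#' Write probability maps as 32-bit float TIFFs with a JSON sidecar
#'
#' One file per sign plus `no_sign`, and a `maps.json` sidecar recording
#' stride, patch size and a model checksum.
#'
#' @param maps A `probability_maps` object.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (e.g. the image id).
#' @param model Optional `lesion_cnn` used; hashed into the sidecar.
#' @return The sidecar path, invisibly.
#' @export
write_probability_maps <- function(maps, dir, prefix = "map", model = NULL) {
  stopifnot(inherits(maps, "probability_maps"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(maps$maps)) {
    tiff::writeTIFF(maps$maps[[nm]],
                    file.path(dir, sprintf("%s_%s.tif", prefix, nm)),
                    bits.per.sample = 32L)
  }
  sidecar <- list(prefix = prefix, stride = maps$stride,
                  patch_size = maps$patch_size,
                  n_evaluations = maps$n_evaluations,
                  model_checksum = if (is.null(model)) NA else
                    rlang::hash(model$params))
  sidecar_path <- file.path(dir, sprintf("%s_maps.json", prefix))
  jsonlite::write_json(sidecar, sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(sidecar_path)
}

#' Write / read a threshold set as JSON
#'
#' @param thresholds A `threshold_set` tibble.
#' @param path JSON file path.
#' @return `write_thresholds`: `path` invisibly; `read_thresholds`: the
#'   `threshold_set`.
#' @export
write_thresholds <- function(thresholds, path) {
  jsonlite::write_json(as.data.frame(thresholds), path, auto_unbox = FALSE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(as_tibble(df), class = c("threshold_set", class(tibble())))
}

#' Write a segmentation as indexed PNGs
#'
#' The label map is written with pixel values 0 (none), 1 (exudate),
#' 2 (hemorrhage), 3 (microaneurysm) on the 8-bit scale (i.e. value/255 in
#' the PNG), plus one boolean PNG per sign.
#'
#' @param result A `lesion_segmentation`.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return The label-map path, invisibly.
#' @export
write_segmentation <- function(result, dir, prefix = "seg") {
  stopifnot(inherits(result, "lesion_segmentation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  label_path <- file.path(dir, sprintf("%s_labels.png", prefix))
  png::writePNG(result$label_map / 255, label_path)
  for (nm in names(result$masks)) {
    png::writePNG(result$masks[[nm]] * 1,
                  file.path(dir, sprintf("%s_%s.png", prefix, nm)))
  }
  invisible(label_path)
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file whose top-level keys override the corresponding
#' arguments of [run_pipeline()] and the nested config constructors
#' (`fixture`, `preprocess`, `patch`, `network`, `training` sections map to
#' [fixture_config()], [preprocess_config()], [patch_spec()],
#' [network_config()], [training_config()]). Unknown keys are rejected.
#'
#' @param path YAML file.
#' @return A named list of configuration overrides.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("seed", "n_images", "stride", "max_epochs", "out_dir",
               "fixture", "preprocess", "patch", "network", "training")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    stop_invalid(sprintf("unknown configuration key(s): %s",
                         paste(unknown, collapse = ", ")))
  }
  constructors <- list(fixture = fixture_config, preprocess = preprocess_config,
                       patch = patch_spec, network = network_config,
                       training = training_config)
  for (nm in intersect(names(cfg), names(constructors))) {
    cfg[[nm]] <- do.call(constructors[[nm]], cfg[[nm]])
  }
  cfg
}
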