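#' Fundus image container
#'
#' Bundles an intensity grid with an optional circular field-of-view (FOV)
#' mask and optional per-sign ground-truth lesion masks. Intensities follow the
#' 8-bit gray convention (0--255) but are kept in floating point throughout.
#'
#' @param pixels Numeric `H x W` matrix (single channel) or `H x W x 3` array.
#' @param fov_mask Optional logical `H x W` matrix marking the retinal field of
#'   view; pixels outside are ignored during pixel-level evaluation.
#' @param gt_masks Optional named list of logical `H x W` matrices, one per
#'   sign (`exudate`, `hemorrhage`, `microaneurysm`). Masks of distinct signs
#'   must be pairwise disjoint.
#' @param id Character identifier carried into patch manifests and reports.
#' @return An object of class `fundus_image`.
#' @export
fundus_image <- function(pixels, fov_mask = NULL, gt_masks = NULL,
                         id = "image") {
  if (is.matrix(pixels)) {
    dim(pixels) <- c(dim(pixels), 1L)
  }
  if (!is.array(pixels) || length(dim(pixels)) != 3L ||
      !dim(pixels)[3] %in% c(1L, 3L)) {
    stop_invalid("`pixels` must be an H x W matrix or H x W x 3 array.")
  }
  if (length(pixels) == 0L) {
    stop_invalid("`pixels` must be nonempty.")
  }
  if (!all(is.finite(pixels))) {
    stop_invalid("`pixels` contains non-finite values.")
  }
  hw <- dim(pixels)[1:2]
  check_mask <- function(m, what) {
    if (!is.matrix(m) || !is.logical(m) || !identical(dim(m), hw)) {
      stop_invalid(sprintf("%s must be a logical matrix matching the image dimensions.", what))
    }
    if (anyNA(m)) stop_invalid(sprintf("%s contains NA.", what))
  }
  if (!is.null(fov_mask)) check_mask(fov_mask, "`fov_mask`")
  if (!is.null(gt_masks)) {
    if (!is.list(gt_masks) ||
        (length(gt_masks) > 0L &&
         (is.null(names(gt_masks)) || !all(names(gt_masks) %in% dr_signs())))) {
      stop_invalid("`gt_masks` must be a named list with names among exudate, hemorrhage, microaneurysm.")
    }
    for (nm in names(gt_masks)) check_mask(gt_masks[[nm]], sprintf("gt_masks$%s", nm))
    if (length(gt_masks) > 1L) {
      total <- Reduce(`+`, lapply(gt_masks, function(m) m * 1L))
      if (any(total > 1L)) {
        stop_invalid("ground-truth masks of distinct signs must be pairwise disjoint.")
      }
    }
  }
  structure(
    list(pixels = pixels, fov_mask = fov_mask, gt_masks = gt_masks,
         id = as.character(id)),
    class = "fundus_image"
  )
}

#' @export
print.fundus_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<fundus_image '%s'> %d x %d, %d channel%s\n",
              x$id, d[1], d[2], d[3], if (d[3] > 1) "s" else ""))
  if (!is.null(x$fov_mask)) {
    cat(sprintf("  field of view: %d px\n", sum(x$fov_mask)))
  }
  if (!is.null(x$gt_masks)) {
    for (nm in names(x$gt_masks)) {
      cat(sprintf("  %s mask: %d px\n", nm, sum(x$gt_masks[[nm]])))
    }
  }
  invisible(x)
}

#' @export
dim.fundus_image <- function(x) dim(x$pixels)

is_fundus_image <- function(x) inherits(x, "fundus_image")

n_channels <- function(image) dim(image$pixels)[3]

#' Resize a fundus image (and its masks) to a reference resolution
#'
#' The intensity grid is resampled with bilinear interpolation; the field of
#' view and ground-truth masks with nearest-neighbor so they stay boolean.
#'
#' @param image A [fundus_image()].
#' @param target_h,target_w Target height and width in pixels (>= 1).
#' @return A [fundus_image()] of size `target_h x target_w`.
#' @export
resize_to_reference <- function(image, target_h, target_w) {
  stopifnot(is_fundus_image(image))
  if (!is.numeric(target_h) || !is.numeric(target_w) ||
      target_h < 1 || target_w < 1) {
    stop_invalid("target dimensions must be >= 1.")
  }
  target_h <- as.integer(round(target_h))
  target_w <- as.integer(round(target_w))
  d <- dim(image$pixels)
  if (target_h == d[1] && target_w == d[2]) return(image)
  # EBImage indexes dim 1 as x; our dim 1 is the image row, so w <- target_h.
  rs_num <- function(a, filter) {
    out <- EBImage::resize(EBImage::Image(a), w = target_h, h = target_w,
                           filter = filter)
    EBImage::imageData(out)
  }
  px <- rs_num(image$pixels, "bilinear")
  dim(px) <- c(target_h, target_w, d[3])
  rs_mask <- function(m) {
    if (is.null(m)) return(NULL)
    rs_num(m * 1, "none") > 0.5
  }
  fundus_image(px,
               fov_mask = rs_mask(image$fov_mask),
               gt_masks = if (is.null(image$gt_masks)) NULL else
                 lapply(image$gt_masks, rs_mask),
               id = image$id)
}
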