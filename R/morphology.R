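# Binary morphology with solid square structuring elements, implemented as
# vectorized Minkowski shift-combines. Pixels outside the image are background
# (FALSE) for both dilation and erosion, the usual convention for binary maps.
#
# For a k x k square the origin is the center for odd k; for even k it is the
# top-left of the four central pixels, i.e. element floor(k/2) (0-based) in
# each axis -- the documented convention for the 4 x 4 erosion mask.

se_offsets <- function(k) {
  o <- ceiling(k / 2) - 1L # 0-based origin index
  seq_len(k) - 1L - o
}

# Shift a logical matrix by (dy, dx), filling vacated cells with FALSE.
shift_mask <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  sr <- max(1L, 1L - dy):min(h, h - dy)
  sc <- max(1L, 1L - dx):min(w, w - dx)
  if (length(sr) > 0L && length(sc) > 0L) {
    out[sr + dy, sc + dx] <- m[sr, sc]
  }
  out
}

#' Binary morphological operations with square structuring elements
#'
#' Dilation, erosion, opening and closing of a logical matrix by a solid
#' `k x k` square. Pixels beyond the image border count as background.
#'
#' @param mask Logical matrix.
#' @param k Structuring-element side in pixels. `k = 1` is the identity.
#' @return Logical matrix of the same size.
#' @export
dilate_mask <- function(mask, k) {
  stopifnot(is.matrix(mask), is.logical(mask), k >= 1)
  if (k == 1L) return(mask)
  off <- se_offsets(as.integer(k))
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (dy in off) for (dx in off) out <- out | shift_mask(mask, dy, dx)
  out
}

#' @rdname dilate_mask
#' @export
erode_mask <- function(mask, k) {
  stopifnot(is.matrix(mask), is.logical(mask), k >= 1)
  if (k == 1L) return(mask)
  off <- se_offsets(as.integer(k))
  out <- matrix(TRUE, nrow(mask), ncol(mask))
  # erosion: x survives iff x + b is foreground for every SE offset b
  for (dy in off) for (dx in off) out <- out & shift_mask(mask, -dy, -dx)
  out
}

#' @rdname dilate_mask
#' @export
open_mask <- function(mask, k) dilate_mask(erode_mask(mask, k), k)

#' @rdname dilate_mask
#' @export
close_mask <- function(mask, k) erode_mask(dilate_mask(mask, k), k)

#' Label connected components
#'
#' Labels maximal connected sets of foreground pixels by iterative
#' label propagation (each pass takes the neighborhood maximum within the
#' mask, until a fixed point).
#'
#' @param mask Logical matrix.
#' @param connectivity 8 (default) or 4.
#' @return Integer matrix: 0 for background, 1..n_components for foreground,
#'   labels renumbered consecutively in raster order of first occurrence.
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), is.logical(mask), connectivity %in% c(4L, 8L))
  lab <- matrix(0, nrow(mask), ncol(mask))
  lab[mask] <- seq_len(sum(mask))
  shifts <- list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
  if (connectivity == 8L) {
    shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L), c(-1L, 1L), c(-1L, -1L)))
  }
  num_shift <- function(m, dy, dx) {
    h <- nrow(m); w <- ncol(m)
    out <- matrix(0, h, w)
    sr <- max(1L, 1L - dy):min(h, h - dy)
    sc <- max(1L, 1L - dx):min(w, w - dx)
    if (length(sr) > 0L && length(sc) > 0L) out[sr + dy, sc + dx] <- m[sr, sc]
    out
  }
  repeat {
    nxt <- lab
    for (sft in shifts) nxt <- pmax(nxt, num_shift(lab, sft[1], sft[2]))
    nxt[!mask] <- 0
    if (identical(nxt, lab)) break
    lab <- nxt
  }
  ids <- unique(lab[mask]) # raster order (column-major)
  out <- matrix(0L, nrow(mask), ncol(mask))
  out[mask] <- match(lab[mask], ids)
  out
}

#' Remove small connected components
#'
#' Drops every 8-connected (by default) component whose pixel area is below
#' `min_area`.
#'
#' @param mask Logical matrix.
#' @param min_area Minimum surviving component area in pixels (components with
#'   area strictly less are removed).
#' @param connectivity 8 (default) or 4.
#' @return Logical matrix.
#' @export
filter_small_components <- function(mask, min_area, connectivity = 8L) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!any(mask)) return(mask)
  lab <- label_components(mask, connectivity)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_area)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' Morphological post-processing of a binary sign map
#'
#' Applies, in order: morphological closing (square 5x5), opening (square
#' 5x5) and erosion (square 4x4), then removes every 8-connected component
#' with pixel area below `S^2/4` (625 for the reference patch size S = 50).
#' This removes redundant boundaries and cluttered false-positive pixels
#' around the segmented signs, then drops isolated detections too small to be
#' a sign at scale `S`. When the pipeline operates at a reduced working
#' resolution, pass the correspondingly scaled `patch_size` and
#' `kernel_sizes` (see [scale_to_width()]).
#'
#' @param mask Logical matrix (a binarized probability map).
#' @param patch_size Patch side `S`; the area threshold is `S^2/4`.
#' @param kernel_sizes Named integer vector of structuring-element sides,
#'   default `c(closing = 5, opening = 5, erosion = 4)`.
#' @param connectivity Component connectivity for the area rule (default 8).
#' @return Cleaned logical matrix.
#' @export
postprocess_mask <- function(mask, patch_size = 50L,
                             kernel_sizes = c(closing = 5L, opening = 5L,
                                              erosion = 4L),
                             connectivity = 8L) {
  stopifnot(is.matrix(mask), is.logical(mask))
  m <- close_mask(mask, kernel_sizes[["closing"]])
  m <- open_mask(m, kernel_sizes[["opening"]])
  m <- erode_mask(m, kernel_sizes[["erosion"]])
  filter_small_components(m, patch_size^2 / 4, connectivity)
}
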