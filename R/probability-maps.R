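#' Per-pixel class probability maps
#'
#' Slides an `S x S` window centered on each pixel of the image (the image is
#' reflect-padded by `floor(S/2)` so border pixels have a full window), feeds
#' every window through the trained classifier, and writes the four softmax
#' scores at the window's center. This yields one probability map per
#' pathological sign -- P_E, P_H, P_M -- plus the implicit background map.
#'
#' With `stride > 1` only pixels on the stride grid are evaluated (exactly
#' `ceiling(H/stride) * ceiling(W/stride)` model evaluations) and off-grid
#' pixels are filled by separable bilinear interpolation (constant
#' extrapolation past the last grid line). Batched evaluation is an internal
#' detail: results equal one-at-a-time evaluation.
#'
#' @param model A trained `lesion_cnn`.
#' @param image A [fundus_image()] (already contrast-enhanced, matching the
#'   training data).
#' @param stride Grid spacing in pixels (default 1: the per-pixel definition).
#' @param batch_size Windows per forward pass.
#' @return An object of class `probability_maps`: a list with `maps` (named
#'   list of `H x W` matrices for exudate, hemorrhage, microaneurysm,
#'   no_sign), the evaluation `grid`, `stride`, `patch_size` and
#'   `n_evaluations`.
#' @export
generate_probability_maps <- function(model, image, stride = 1L,
                                      batch_size = 256L) {
  stopifnot(inherits(model, "lesion_cnn"), is_fundus_image(image))
  if (!is.numeric(stride) || length(stride) != 1L || stride < 1) {
    stop_invalid("`stride` must be >= 1.")
  }
  stride <- as.integer(stride)
  s <- model$config$input_side
  d <- dim(image$pixels)
  if (d[1] < s || d[2] < s) {
    stop_invalid("image is smaller than the patch size.")
  }
  if (d[3] != model$config$n_channels) {
    stop_invalid("image channel count does not match the model.")
  }
  pad <- s %/% 2L
  padded <- pad_reflect(image$pixels, pad)
  grid_r <- seq.int(1L, d[1], by = stride)
  grid_c <- seq.int(1L, d[2], by = stride)

  # Window centered at image pixel (r, c): rows r..r+s-1 of the padded array
  # (for even s the center sits at offset floor(s/2) inside the window).
  # Windows are extracted per batch to bound memory.
  centers <- expand.grid(r = grid_r, c = grid_c)
  n <- nrow(centers)
  probs <- matrix(NA_real_, n, model$config$n_classes)
  for (start in seq.int(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    A <- array(0, c(s, s, length(idx), d[3]))
    for (i in seq_along(idx)) {
      r <- centers$r[idx[i]]; c <- centers$c[idx[i]]
      A[, , i, ] <- padded[r:(r + s - 1L), c:(c + s - 1L), , drop = FALSE]
    }
    probs[idx, ] <- cnn_forward(model, A, training = FALSE)$probs
  }
  colnames(probs) <- dr_classes()

  maps <- lapply(seq_len(ncol(probs)), function(k) {
    g <- matrix(probs[, k], length(grid_r), length(grid_c))
    if (stride == 1L) g else bilinear_fill(g, grid_r, grid_c, d[1], d[2])
  })
  names(maps) <- colnames(probs)
  structure(list(maps = maps, grid = list(rows = grid_r, cols = grid_c),
                 stride = stride, patch_size = s,
                 n_evaluations = nrow(centers)),
            class = "probability_maps")
}

# Reflect-pad an H x W x C array by `pad` pixels on every spatial side.
pad_reflect <- function(a, pad) {
  d <- dim(a)
  ri <- reflect_index(seq.int(1L - pad, d[1] + pad), d[1])
  ci <- reflect_index(seq.int(1L - pad, d[2] + pad), d[2])
  a[ri, ci, , drop = FALSE]
}

# Separable linear interpolation of grid values onto the full pixel lattice,
# with constant extrapolation beyond the outermost grid lines.
bilinear_fill <- function(g, grid_r, grid_c, h, w) {
  by_row <- apply(g, 2L, function(col) {
    approx(grid_r, col, xout = seq_len(h), rule = 2L)$y
  })
  t(apply(by_row, 1L, function(row) {
    approx(grid_c, row, xout = seq_len(w), rule = 2L)$y
  }))
}

#' @export
print.probability_maps <- function(x, ...) {
  d <- dim(x$maps[[1]])
  cat(sprintf("<probability_maps> %d x %d, stride %d, patch %d (%d model evaluations)\n",
              d[1], d[2], x$stride, x$patch_size, x$n_evaluations))
  for (nm in dr_signs()) {
    cat(sprintf("  P_%s: max %.3f\n", substr(nm, 1, 1), max(x$maps[[nm]])))
  }
  invisible(x)
}

#' Tidy a probability-maps object into long pixel form
#'
#' @param x A `probability_maps` object.
#' @param ... Unused.
#' @return Tibble with columns `row`, `col`, `sign`, `probability`.
#' @export
tidy.probability_maps <- function(x, ...) {
  purrr::imap(x$maps, function(m, nm) {
    tibble(row = rep(seq_len(nrow(m)), ncol(m)),
           col = rep(seq_len(ncol(m)), each = nrow(m)),
           sign = nm, probability = as.vector(m))
  }) |> dplyr::bind_rows()
}

#' @export
autoplot.probability_maps <- function(object, signs = dr_signs(), ...) {
  df <- tidy(object)
  df <- df[df$sign %in% signs, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$probability)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::facet_wrap(~sign) +
    ggplot2::labs(x = NULL, y = NULL, fill = "P")
}
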