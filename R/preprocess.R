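#' Contrast-enhancement configuration
#'
#' Parameters of the Gaussian-difference contrast enhancement
#' `I_CE = alpha * I + beta * (G_sigma * I) + mu`, where `G_sigma` is a
#' unit-sum Gaussian kernel of scale `sigma` and `*` is convolution. With the
#' default `alpha = -beta` the transform is a scaled high-pass filter re-based
#' at the mid-gray `mu`: flat regions map to `mu`, edges are amplified
#' `alpha`-fold.
#'
#' @param alpha Gain on the raw image (unitless). Default 4.
#' @param beta Gain on the Gaussian-smoothed image (unitless). Default -4.
#' @param sigma Gaussian scale in pixels at the working resolution. Default 10,
#'   the value appropriate at the 1500-px reference width; use
#'   [scale_to_width()] when operating at other resolutions.
#' @param mu Gray-level offset. Default 128 (8-bit mid-gray).
#' @param clip_range Inclusive output bounds, default `c(0, 255)`; `NULL`
#'   disables clipping.
#' @param per_channel Apply the transform independently to each color channel
#'   (default `TRUE`).
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(alpha = 4, beta = -4, sigma = 10, mu = 128,
                              clip_range = c(0, 255), per_channel = TRUE) {
  stopifnot(is.numeric(alpha), is.numeric(beta), is.numeric(mu))
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop_invalid("`sigma` must be a positive scalar.")
  }
  if (!is.null(clip_range)) {
    if (length(clip_range) != 2L || clip_range[1] >= clip_range[2]) {
      stop_invalid("`clip_range` must be c(low, high) with low < high.")
    }
  }
  structure(list(alpha = alpha, beta = beta, sigma = sigma, mu = mu,
                 clip_range = clip_range, per_channel = isTRUE(per_channel)),
            class = "preprocess_config")
}

# 1-D Gaussian taps truncated at 4*sigma per side, renormalized to unit sum,
# so convolving a constant image reproduces the constant exactly.
gaussian_taps <- function(sigma) {
  r <- ceiling(4 * sigma)
  x <- seq(-r, r)
  w <- exp(-x^2 / (2 * sigma^2))
  w / sum(w)
}

# Indices implementing symmetric (reflect-with-edge) padding: ... 2 1 | 1 2
# ... n | n n-1 ...  Valid for any pad size (the reflection is folded).
reflect_index <- function(idx, n) {
  if (n == 1L) return(rep(1L, length(idx)))
  period <- 2L * n
  k <- (idx - 1L) %% period
  k <- ifelse(k < 0L, k + period, k)
  as.integer(ifelse(k < n, k + 1L, period - k))
}

# Separable Gaussian convolution of a matrix with reflect padding.
gaussian_convolve <- function(mat, sigma) {
  taps <- gaussian_taps(sigma)
  r <- (length(taps) - 1L) / 2L
  conv_cols <- function(m) {
    n <- nrow(m)
    padded <- m[reflect_index(seq.int(1L - r, n + r), n), , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(taps)) {
      out <- out + taps[j] * padded[seq.int(j, j + n - 1L), , drop = FALSE]
    }
    out
  }
  t(conv_cols(t(conv_cols(mat))))
}

#' Enhance the contrast of a fundus image
#'
#' Applies the Gaussian-difference transform
#' `I_CE = alpha * I + beta * (G_sigma * I) + mu` pixelwise (see
#' [preprocess_config()]), then clips to `clip_range` when set. The Gaussian
#' convolution uses reflect padding at the image border, avoiding dark halos at
#' the field-of-view rim. Field-of-view and ground-truth masks pass through
#' unchanged.
#'
#' @param image A [fundus_image()].
#' @param config A [preprocess_config()].
#' @return A [fundus_image()] of the same shape with enhanced intensities.
#' @export
enhance_contrast <- function(image, config = preprocess_config()) {
  stopifnot(is_fundus_image(image), inherits(config, "preprocess_config"))
  d <- dim(image$pixels)
  px <- image$pixels
  channels <- seq_len(d[3])
  if (!config$per_channel && d[3] == 3L) {
    # Joint mode: enhance the luminance-like channel mean, reapply per channel.
    gray <- (px[, , 1] + px[, , 2] + px[, , 3]) / 3
    sm <- gaussian_convolve(gray, config$sigma)
    out <- px
    for (k in channels) {
      out[, , k] <- config$alpha * px[, , k] + config$beta * sm + config$mu
    }
  } else {
    out <- px
    for (k in channels) {
      sm <- gaussian_convolve(px[, , k], config$sigma)
      out[, , k] <- config$alpha * px[, , k] + config$beta * sm + config$mu
    }
  }
  if (!is.null(config$clip_range)) {
    out <- pmin(pmax(out, config$clip_range[1]), config$clip_range[2])
  }
  fundus_image(out, fov_mask = image$fov_mask, gt_masks = image$gt_masks,
               id = image$id)
}
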