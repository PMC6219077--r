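#' Synthetic fundus fixture configuration
#'
#' Parameters of the seeded synthetic fundus generator: a reddish-orange
#' retinal disc (circular field of view on a black background) with smooth
#' dark vessel-like curves, bright soft-edged blobs (exudates), larger dark
#' red blobs (hemorrhages) and tiny dark red dots (microaneurysms), all placed
#' without overlap and recorded in pairwise-disjoint ground-truth masks.
#' Lesion appearance is parametric, not photorealistic: the generator targets
#' the pipeline's contracts, not clinical realism.
#'
#' @param image_side Square image side in pixels (default 300).
#' @param n_exudates,n_hemorrhages,n_microaneurysms Lesion counts per image.
#' @param exudate_radius,hemorrhage_radius,microaneurysm_radius Two-element
#'   radius ranges in pixels.
#' @param exudate_delta Peak brightness increase of an exudate (gray levels).
#' @param hemorrhage_delta,microaneurysm_delta Peak darkening (gray levels).
#' @param n_vessels Number of vessel-like curves.
#' @param vessel_delta Vessel darkening (gray levels).
#' @param background RGB base color of the retinal disc (0-255).
#' @param noise_sd Gaussian pixel noise standard deviation (gray levels).
#' @param seed Integer seed; generation is bit-reproducible given it.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(image_side = 300L,
                           n_exudates = 3L, n_hemorrhages = 2L,
                           n_microaneurysms = 5L,
                           exudate_radius = c(8, 14), exudate_delta = 80,
                           hemorrhage_radius = c(8, 13), hemorrhage_delta = 70,
                           microaneurysm_radius = c(3, 5),
                           microaneurysm_delta = 80,
                           n_vessels = 4L, vessel_delta = 50,
                           background = c(170, 80, 35), noise_sd = 2,
                           seed = 1L) {
  ranges <- list(exudate_radius, hemorrhage_radius, microaneurysm_radius)
  if (any(vapply(ranges, function(r) length(r) != 2L || any(r <= 0) || r[1] > r[2],
                 TRUE))) {
    stop_invalid("lesion radius ranges must be positive c(min, max).")
  }
  if (image_side < 32) stop_invalid("`image_side` must be >= 32.")
  structure(list(image_side = as.integer(image_side),
                 n_exudates = as.integer(n_exudates),
                 n_hemorrhages = as.integer(n_hemorrhages),
                 n_microaneurysms = as.integer(n_microaneurysms),
                 exudate_radius = exudate_radius,
                 exudate_delta = exudate_delta,
                 hemorrhage_radius = hemorrhage_radius,
                 hemorrhage_delta = hemorrhage_delta,
                 microaneurysm_radius = microaneurysm_radius,
                 microaneurysm_delta = microaneurysm_delta,
                 n_vessels = as.integer(n_vessels),
                 vessel_delta = vessel_delta,
                 background = background, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "fixture_config")
}

# Relative per-channel weights of each structure's intensity change.
lesion_channel_weights <- function(kind) {
  switch(kind,
         exudate = c(1, 0.85, 0.25),        # bright, yellowish
         hemorrhage = c(0.9, 0.8, 0.3),     # dark red
         microaneurysm = c(0.9, 0.8, 0.3),  # dark red dot
         vessel = c(0.8, 0.9, 0.4))
}

#' Generate one synthetic fundus image with ground truth
#'
#' Deterministic given `config$seed`. Lesions are placed by rejection
#' sampling, keeping at least 2 px of clearance between structures; an error
#' is raised if a lesion cannot be placed within 200 attempts. Each sign's
#' mask records exactly the pixels whose intensity the lesion modified.
#'
#' @param config A [fixture_config()].
#' @param id Image identifier.
#' @return A [fundus_image()] with `fov_mask` and per-sign `gt_masks`.
#' @export
simulate_fundus <- function(config = fixture_config(), id = "fixture") {
  stopifnot(inherits(config, "fixture_config"))
  withr::with_seed(config$seed, simulate_fundus_impl(config, id))
}

simulate_fundus_impl <- function(config, id) {
  side <- config$image_side
  ctr <- (side + 1) / 2
  fov_radius <- 0.48 * side
  rr <- matrix(seq_len(side), side, side)
  cc <- matrix(seq_len(side), side, side, byrow = TRUE)
  d2 <- (rr - ctr)^2 + (cc - ctr)^2
  fov <- d2 <= fov_radius^2

  # Background disc with mild vignetting and pixel noise.
  vignette <- 1 - 0.25 * d2 / fov_radius^2
  px <- array(0, c(side, side, 3L))
  for (k in 1:3) {
    ch <- config$background[k] * vignette +
      matrix(rnorm(side^2, sd = config$noise_sd), side)
    ch[!fov] <- 0
    px[, , k] <- ch
  }

  # Vessel-like curves: biased random walks from near the center outward.
  vessel <- matrix(FALSE, side, side)
  for (v in seq_len(config$n_vessels)) {
    ang <- runif(1, 0, 2 * pi)
    pos <- c(ctr, ctr) + (0.05 * side) * c(sin(ang), cos(ang))
    width <- sample(1:2, 1L)
    pts_r <- integer(0); pts_c <- integer(0)
    for (step in seq_len(4L * side)) {
      ang <- ang + rnorm(1, 0, 0.12)
      pos <- pos + c(sin(ang), cos(ang))
      if ((pos[1] - ctr)^2 + (pos[2] - ctr)^2 > (fov_radius - 2)^2) break
      pts_r <- c(pts_r, round(pos[1])); pts_c <- c(pts_c, round(pos[2]))
    }
    if (length(pts_r) == 0L) next
    off <- expand.grid(dy = -width:width, dx = -width:width)
    off <- off[off$dy^2 + off$dx^2 <= width^2, ]
    for (j in seq_len(nrow(off))) {
      r <- pts_r + off$dy[j]; c <- pts_c + off$dx[j]
      ok <- r >= 1 & r <= side & c >= 1 & c <= side
      vessel[cbind(r[ok], c[ok])] <- TRUE
    }
  }
  w <- lesion_channel_weights("vessel")
  for (k in 1:3) {
    ch <- px[, , k]
    ch[vessel & fov] <- ch[vessel & fov] - w[k] * config$vessel_delta
    px[, , k] <- ch
  }

  # Lesions: soft radial profile, elliptical for hemorrhages.
  occupied <- dilate_mask(vessel, 5L)
  masks <- list(exudate = matrix(FALSE, side, side),
                hemorrhage = matrix(FALSE, side, side),
                microaneurysm = matrix(FALSE, side, side))
  place <- list(exudate = list(n = config$n_exudates,
                               radius = config$exudate_radius,
                               delta = config$exudate_delta, sign = +1),
                hemorrhage = list(n = config$n_hemorrhages,
                                  radius = config$hemorrhage_radius,
                                  delta = config$hemorrhage_delta, sign = -1),
                microaneurysm = list(n = config$n_microaneurysms,
                                     radius = config$microaneurysm_radius,
                                     delta = config$microaneurysm_delta,
                                     sign = -1))
  for (kind in names(place)) {
    p <- place[[kind]]
    wgt <- lesion_channel_weights(kind)
    for (i in seq_len(p$n)) {
      placed <- FALSE
      for (attempt in seq_len(200L)) {
        r <- runif(1, p$radius[1], p$radius[2])
        margin <- fov_radius - r - 3
        ang <- runif(1, 0, 2 * pi)
        rad <- sqrt(runif(1)) * margin
        cy <- ctr + rad * sin(ang); cx <- ctr + rad * cos(ang)
        if (kind == "hemorrhage") {
          theta <- runif(1, 0, pi)
          ecc <- runif(1, 0.6, 1)
          dy <- rr - cy; dx <- cc - cx
          u <- cos(theta) * dy + sin(theta) * dx
          v <- -sin(theta) * dy + cos(theta) * dx
          q <- (u / r)^2 + (v / (ecc * r))^2
        } else {
          q <- ((rr - cy)^2 + (cc - cx)^2) / r^2
        }
        support <- q < 1
        if (!any(support)) next
        if (any(support & occupied)) next
        profile <- matrix(0, side, side)
        profile[support] <- (1 - q[support])^0.75
        for (k in 1:3) {
          px[, , k] <- px[, , k] + p$sign * wgt[k] * p$delta * profile
        }
        masks[[kind]] <- masks[[kind]] | support
        occupied <- occupied | dilate_mask(support, 5L)
        placed <- TRUE
        break
      }
      if (!placed) {
        abort(sprintf("could not place %s %d without overlap after 200 attempts.",
                      kind, i))
      }
    }
  }
  px <- pmin(pmax(px, 0), 255)
  fundus_image(px, fov_mask = fov, gt_masks = masks, id = id)
}

#' Generate a reproducible set of synthetic fundus images
#'
#' Draws `n_images` independent seeded images and assigns each a role:
#' `train` (classifier training), `threshold` (held-out images for fitting
#' the decision thresholds) and `test` (final evaluation), apportioned by
#' `role_fractions` in order.
#'
#' @param n_images Number of images (>= 1).
#' @param config A [fixture_config()]; its `seed` is ignored in favor of
#'   `seed`.
#' @param seed Integer seed for the whole set.
#' @param role_fractions Named fractions for train/threshold/test.
#' @return A tibble with columns `image_id`, `role` and `image` (list column
#'   of [fundus_image()]).
#' @export
simulate_fundus_set <- function(n_images, config = fixture_config(),
                                seed = 1L,
                                role_fractions = c(train = 0.6,
                                                   threshold = 0.2,
                                                   test = 0.2)) {
  if (!is.numeric(n_images) || n_images < 1) {
    stop_invalid("`n_images` must be >= 1.")
  }
  n_images <- as.integer(n_images)
  image_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                                   n_images))
  sizes <- largest_remainder(n_images, role_fractions)
  roles <- rep(names(role_fractions), times = sizes)
  images <- lapply(seq_len(n_images), function(i) {
    cfg <- config
    cfg$seed <- image_seeds[i]
    simulate_fundus(cfg, id = sprintf("fixture_%03d", i))
  })
  tibble(image_id = vapply(images, function(im) im$id, ""),
         role = factor(roles, levels = names(role_fractions)),
         image = images)
}
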