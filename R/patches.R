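#' Patch dataset specification
#'
#' Controls how annotated images are tiled into labeled square patches and how
#' the patch set is split for training.
#'
#' @param patch_size Side `S` of the square window in pixels (default 50, the
#'   value chosen from the smallest pathological sign at the 1500-px reference
#'   resolution; must be >= 8).
#' @param split_fractions Named train/validation/test fractions in (0,1),
#'   summing to 1. Default `c(train = 0.70, validation = 0.15, test = 0.15)`.
#' @param seed Integer seed making the stratified split deterministic.
#' @param augment Whether the training split is expanded with the 8 dihedral
#'   variants of each patch (default `TRUE`).
#' @param label_rule_min_overlap Fraction of a patch's pixels that must lie
#'   inside a sign's ground-truth mask for the patch to receive that sign's
#'   label (default 0.10). Ties go to the sign with the larger overlap, then to
#'   the fixed priority exudate > hemorrhage > microaneurysm.
#' @return A `patch_spec` list.
#' @export
patch_spec <- function(patch_size = 50,
                       split_fractions = c(train = 0.70, validation = 0.15,
                                           test = 0.15),
                       seed = 1L, augment = TRUE,
                       label_rule_min_overlap = 0.10) {
  if (!is.numeric(patch_size) || length(patch_size) != 1L || patch_size < 8) {
    stop_invalid("`patch_size` must be a single number >= 8.")
  }
  if (length(split_fractions) != 3L || any(split_fractions < 0) ||
      any(split_fractions > 1) ||
      abs(sum(split_fractions) - 1) > 1e-9) {
    stop_invalid("`split_fractions` must be three fractions summing to 1.")
  }
  if (is.null(names(split_fractions))) {
    names(split_fractions) <- c("train", "validation", "test")
  }
  if (!is.numeric(label_rule_min_overlap) ||
      any(label_rule_min_overlap <= 0) || any(label_rule_min_overlap > 1)) {
    stop_invalid("`label_rule_min_overlap` must be in (0, 1].")
  }
  structure(list(patch_size = as.integer(patch_size),
                 split_fractions = split_fractions,
                 seed = as.integer(seed), augment = isTRUE(augment),
                 label_rule_min_overlap = label_rule_min_overlap),
            class = "patch_spec")
}

# Per-grid-cell pixel counts of a mask on a non-overlapping S-stride grid.
cell_counts <- function(mask, s, n_row, n_col) {
  m <- mask[seq_len(n_row * s), seq_len(n_col * s), drop = FALSE] * 1
  dim(m) <- c(s, n_row, s, n_col)
  apply(m, c(2L, 4L), sum)
}

#' Extract labeled patches from an annotated image
#'
#' Tiles the image with non-overlapping `S x S` windows on an `S`-stride grid
#' (top-left aligned, 0-based, half-open windows). Each patch is labeled with
#' the sign whose ground-truth mask covers at least
#' `label_rule_min_overlap` of its area; if several qualify the largest
#' overlap wins, exact ties broken by the priority
#' exudate > hemorrhage > microaneurysm; otherwise the patch is `no_sign`.
#'
#' @param image A [fundus_image()] carrying `gt_masks` (possibly empty).
#' @param spec A [patch_spec()].
#' @return A tibble with columns `image_id`, `row`, `col` (0-based top-left
#'   corner), `label` (factor over the four classes) and `window` (list column
#'   of `S x S x C` arrays).
#' @export
extract_patches <- function(image, spec = patch_spec()) {
  stopifnot(is_fundus_image(image), inherits(spec, "patch_spec"))
  if (is.null(image$gt_masks)) {
    stop_invalid("`image` must carry gt_masks (possibly an empty list).")
  }
  s <- spec$patch_size
  d <- dim(image$pixels)
  if (d[1] < s || d[2] < s) {
    stop_invalid("image is smaller than the patch size.")
  }
  n_row <- d[1] %/% s
  n_col <- d[2] %/% s
  signs <- intersect(dr_signs(), names(image$gt_masks))
  min_ov <- spec$label_rule_min_overlap
  if (!is.null(names(min_ov))) min_ov <- min_ov[signs]
  frac <- lapply(signs, function(sg) {
    cell_counts(image$gt_masks[[sg]], s, n_row, n_col) / s^2
  })
  names(frac) <- signs
  labels <- matrix("no_sign", n_row, n_col)
  best <- matrix(0, n_row, n_col)
  min_ov_vec <- if (length(min_ov) == 1L) setNames(rep(min_ov, length(signs)), signs) else min_ov
  for (sg in signs) { # priority order: earlier sign wins exact ties
    f <- frac[[sg]]
    take <- f >= min_ov_vec[[sg]] & f > best
    labels[take] <- sg
    best[take] <- f[take]
  }
  grid <- expand.grid(r = seq_len(n_row), c = seq_len(n_col))
  windows <- purrr::map2(grid$r, grid$c, function(r, c) {
    image$pixels[((r - 1L) * s + 1L):(r * s), ((c - 1L) * s + 1L):(c * s), ,
                 drop = FALSE]
  })
  tibble(
    image_id = image$id,
    row = as.integer((grid$r - 1L) * s),
    col = as.integer((grid$c - 1L) * s),
    label = factor(labels[cbind(grid$r, grid$c)], levels = dr_classes()),
    window = windows
  )
}

# The 8 elements of the dihedral group acting on a square matrix.
dihedral_ops <- function() {
  rot90 <- function(m) t(m)[, rev(seq_len(nrow(m))), drop = FALSE]
  list(
    identity = function(m) m,
    rot90 = rot90,
    rot180 = function(m) rot90(rot90(m)),
    rot270 = function(m) rot90(rot90(rot90(m))),
    flip_h = function(m) m[, rev(seq_len(ncol(m))), drop = FALSE],
    flip_v = function(m) m[rev(seq_len(nrow(m))), , drop = FALSE],
    transpose = function(m) t(m),
    anti_transpose = function(m) t(m)[rev(seq_len(ncol(m))), rev(seq_len(nrow(m))), drop = FALSE]
  )
}

apply_dihedral <- function(window, op) {
  ch <- lapply(seq_len(dim(window)[3]), function(k) op(window[, , k]))
  array(unlist(ch), dim = dim(window))
}

#' Augment patches with their 8 dihedral variants
#'
#' Expands each patch into the 8 symmetries of the square (identity, the three
#' right-angle rotations, horizontal and vertical flips, and the two
#' transposes), preserving labels -- the flip-and-rotate augmentation used to
#' increase training-set robustness.
#'
#' @param patches A patch tibble from [extract_patches()], or a single
#'   `S x S (x C)` window.
#' @return For a tibble input: the tibble with 8 rows per input row and a
#'   `variant` column. For a single window: a named list of 8 windows.
#' @export
augment_patches <- function(patches) {
  ops <- dihedral_ops()
  if (is.array(patches) || is.matrix(patches)) {
    w <- patches
    if (is.matrix(w)) dim(w) <- c(dim(w), 1L)
    if (dim(w)[1] != dim(w)[2]) stop_invalid("patch window must be square.")
    return(lapply(ops, function(op) apply_dihedral(w, op)))
  }
  stopifnot(is.data.frame(patches))
  if (any(vapply(patches$window, function(w) dim(w)[1] != dim(w)[2], TRUE))) {
    stop_invalid("patch windows must be square.")
  }
  out <- tidyr::expand_grid(patches, variant = names(ops))
  out$window <- purrr::map2(out$window, out$variant,
                            function(w, v) apply_dihedral(w, ops[[v]]))
  out
}

# Largest-remainder apportionment of n items to fractions f (sums to n).
largest_remainder <- function(n, f) {
  raw <- n * f
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(raw - base, decreasing = TRUE) # ties: earlier split first
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Split a patch set into train/validation/test
#'
#' Stratified by class label: within each class, patches are shuffled
#' deterministically (by `spec$seed`) and apportioned to the three splits by
#' largest remainder, so split sizes are exact up to rounding. A class with
#' fewer patches than active splits is placed entirely in training, with a
#' warning. The partition is disjoint and exhaustive.
#'
#' @param patches A patch tibble from [extract_patches()] (rows from several
#'   images may be concatenated with [dplyr::bind_rows()]).
#' @param spec A [patch_spec()].
#' @return The tibble with an added `split` factor column
#'   (train/validation/test).
#' @export
split_patches <- function(patches, spec = patch_spec()) {
  stopifnot(is.data.frame(patches), inherits(spec, "patch_spec"))
  if (nrow(patches) == 0L) stop_invalid("`patches` is empty.")
  f <- spec$split_fractions
  split_names <- names(f)
  n_active <- sum(f > 0)
  split <- character(nrow(patches))
  withr::with_seed(spec$seed, {
    for (cls in levels(patches$label)) {
      idx <- which(patches$label == cls)
      n <- length(idx)
      if (n == 0L) next
      if (n < n_active) {
        warn(sprintf("class '%s' has %d patch(es), fewer than the %d active splits; placed entirely in training.",
                     cls, n, n_active))
        split[idx] <- split_names[1]
        next
      }
      sizes <- largest_remainder(n, f)
      idx <- sample(idx)
      split[idx] <- rep(split_names, times = sizes)
    }
  })
  patches$split <- factor(split, levels = split_names)
  patches
}
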