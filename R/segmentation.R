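#' ROC-optimal decision threshold for one sign
#'
#' Sweeps every distinct score value as a candidate threshold (decision rule
#' `score >= Th`) and returns the one maximizing Youden's
#' `J = sensitivity + specificity - 1`; exact ties are broken toward the
#' higher threshold. `criterion = "closest_topleft"` instead minimizes the
#' distance to the ideal (0,1) corner of the ROC curve.
#'
#' @param scores Numeric vector of per-pixel (or per-unit) probabilities.
#' @param truth Logical vector of the same length; both classes must be
#'   present.
#' @param criterion `"youden"` (default) or `"closest_topleft"`.
#' @return A one-row tibble: `threshold`, `sensitivity`, `specificity`,
#'   `youden_j`, `criterion`.
#' @export
select_threshold <- function(scores, truth, criterion = c("youden", "closest_topleft")) {
  criterion <- match.arg(criterion)
  if (length(scores) != length(truth)) {
    stop_invalid("`scores` and `truth` must have equal length.")
  }
  truth <- as.logical(truth)
  if (anyNA(scores) || anyNA(truth)) stop_invalid("NA in scores or truth.")
  n_pos <- sum(truth); n_neg <- sum(!truth)
  if (n_pos == 0L || n_neg == 0L) {
    stop_invalid("both classes must be present in `truth`.")
  }
  cand <- sort(unique(scores), decreasing = TRUE)
  if (length(cand) == 1L) {
    warn("all scores identical; threshold selection is degenerate.")
  }
  # With candidates descending, tp/fp at threshold cand[i] are cumulative
  # counts of units scoring >= cand[i].
  ord <- order(scores, decreasing = TRUE)
  sc <- scores[ord]; tr <- truth[ord]
  idx_last <- length(sc) - match(cand, rev(sc)) + 1L # last position of each candidate
  tp <- cumsum(tr)[idx_last]
  fp <- cumsum(!tr)[idx_last]
  sens <- tp / n_pos
  spec <- (n_neg - fp) / n_neg
  obj <- switch(criterion,
                youden = sens + spec - 1,
                closest_topleft = -sqrt((1 - sens)^2 + (1 - spec)^2))
  # ties.method = "first" on descending candidates => higher threshold wins
  best <- which.max(obj)
  tibble(threshold = cand[best], sensitivity = sens[best],
         specificity = spec[best], youden_j = sens[best] + spec[best] - 1,
         criterion = criterion)
}

#' Fit per-sign thresholds from probability maps and ground truth
#'
#' Pools pixels (restricted to the field of view when present) across one or
#' more images and selects a decision threshold per sign with
#' [select_threshold()]. Fit thresholds on held-out images, never on the
#' images being evaluated.
#'
#' @param maps A `probability_maps` object or list of them.
#' @param images The matching [fundus_image()] (or list), providing
#'   `gt_masks` and optional `fov_mask`.
#' @param criterion Passed to [select_threshold()].
#' @return A `threshold_set` tibble: one row per sign with the threshold and
#'   its ROC summary.
#' @export
fit_thresholds <- function(maps, images, criterion = "youden") {
  if (inherits(maps, "probability_maps")) maps <- list(maps)
  if (is_fundus_image(images)) images <- list(images)
  stopifnot(length(maps) == length(images))
  rows <- lapply(dr_signs(), function(sg) {
    scores <- numeric(0); truth <- logical(0)
    for (i in seq_along(maps)) {
      img <- images[[i]]
      if (is.null(img$gt_masks)) stop_invalid("images must carry gt_masks.")
      keep <- if (is.null(img$fov_mask)) TRUE else img$fov_mask
      m <- maps[[i]]$maps[[sg]]
      gt <- img$gt_masks[[sg]]
      if (is.null(gt)) gt <- matrix(FALSE, nrow(m), ncol(m))
      scores <- c(scores, m[keep])
      truth <- c(truth, gt[keep])
    }
    dplyr::mutate(select_threshold(scores, truth, criterion), sign = sg,
                  .before = 1L)
  })
  structure(dplyr::bind_rows(rows), class = c("threshold_set", class(tibble())))
}

#' Binarize a probability map
#'
#' @param map Numeric matrix of probabilities.
#' @param th Threshold in (0, 1); pixels with `map >= th` become `TRUE`.
#' @return Logical matrix.
#' @export
binarize_map <- function(map, th) {
  stopifnot(is.matrix(map), is.numeric(map))
  if (!is.numeric(th) || length(th) != 1L || th <= 0 || th >= 1) {
    stop_invalid("`th` must be a single probability strictly in (0, 1).")
  }
  map >= th
}

#' Resolve overlaps between per-sign binary maps
#'
#' Pixels positive in exactly one binary map keep that sign; pixels positive
#' in two or more are assigned the sign with the highest probability at that
#' pixel, exact ties broken by the fixed priority
#' exudate > hemorrhage > microaneurysm.
#'
#' @param maps A `probability_maps` object (or named list of probability
#'   matrices).
#' @param binary_maps Named list of logical matrices, one per sign.
#' @return Integer label matrix: 0 none, 1 exudate, 2 hemorrhage,
#'   3 microaneurysm.
#' @export
resolve_overlaps <- function(maps, binary_maps) {
  prob <- if (inherits(maps, "probability_maps")) maps$maps else maps
  signs <- dr_signs()
  dims <- dim(binary_maps[[signs[1]]])
  for (sg in signs) {
    if (!identical(dim(binary_maps[[sg]]), dims) ||
        !identical(dim(prob[[sg]]), dims)) {
      stop_invalid("probability and binary maps must share one shape.")
    }
  }
  label <- matrix(0L, dims[1], dims[2])
  best <- matrix(-Inf, dims[1], dims[2])
  for (i in seq_along(signs)) {
    sg <- signs[i]
    sc <- ifelse(binary_maps[[sg]], prob[[sg]], -Inf)
    take <- sc > best # strict: earlier (higher-priority) sign keeps ties
    label[take] <- i
    best[take] <- sc[take]
  }
  label
}

#' Segment an image from its probability maps
#'
#' The image-analysis back end: each sign's probability map is binarized at
#' its threshold, overlaps are resolved by probability ranking
#' ([resolve_overlaps()]), and each sign's mask is cleaned by
#' [postprocess_mask()]. Morphological closing can re-join pixels claimed by
#' different signs, so exclusivity is re-established afterwards (probability
#' ranking again) and the minimum-area rule re-applied; the returned per-sign
#' masks are therefore pairwise disjoint and contain no component smaller
#' than `patch_size^2/4`.
#'
#' @param maps A `probability_maps` object.
#' @param thresholds A `threshold_set` from [fit_thresholds()], or a named
#'   numeric vector of per-sign thresholds.
#' @param patch_size Patch side `S` for the area rule (defaults to the size
#'   recorded in `maps`).
#' @param kernel_sizes Structuring-element sides, see [postprocess_mask()].
#' @return An object of class `lesion_segmentation`: `label_map` (0 none,
#'   1 exudate, 2 hemorrhage, 3 microaneurysm), `masks` (named list of
#'   disjoint logical matrices) and the thresholds used.
#' @export
segment_image <- function(maps, thresholds, patch_size = NULL,
                          kernel_sizes = c(closing = 5L, opening = 5L,
                                           erosion = 4L)) {
  stopifnot(inherits(maps, "probability_maps"))
  th <- thresholds
  if (is.data.frame(th)) th <- setNames(th$threshold, th$sign)
  if (is.null(patch_size)) patch_size <- maps$patch_size
  signs <- dr_signs()
  binary <- lapply(signs, function(sg) binarize_map(maps$maps[[sg]], th[[sg]]))
  names(binary) <- signs
  label <- resolve_overlaps(maps, binary)
  cleaned <- lapply(seq_along(signs), function(i) {
    postprocess_mask(label == i, patch_size, kernel_sizes)
  })
  names(cleaned) <- signs
  # Closing may have re-created overlaps; resolve them again and re-apply the
  # area rule so both invariants hold.
  n_claims <- Reduce(`+`, lapply(cleaned, function(m) m * 1L))
  if (any(n_claims > 1L)) {
    label2 <- resolve_overlaps(maps, cleaned)
    cleaned <- lapply(seq_along(signs), function(i) {
      filter_small_components(label2 == i, patch_size^2 / 4)
    })
    names(cleaned) <- signs
  }
  label_map <- matrix(0L, nrow(label), ncol(label))
  for (i in seq_along(signs)) label_map[cleaned[[signs[i]]]] <- i
  structure(list(label_map = label_map, masks = cleaned,
                 thresholds = th, patch_size = patch_size,
                 kernel_sizes = kernel_sizes),
            class = "lesion_segmentation")
}

#' @export
print.lesion_segmentation <- function(x, ...) {
  d <- dim(x$label_map)
  cat(sprintf("<lesion_segmentation> %d x %d\n", d[1], d[2]))
  for (sg in dr_signs()) {
    cat(sprintf("  %s: %d px (threshold %.3f)\n", sg, sum(x$masks[[sg]]),
                x$thresholds[[sg]]))
  }
  invisible(x)
}

#' @export
tidy.lesion_segmentation <- function(x, ...) {
  m <- x$label_map
  tibble(row = rep(seq_len(nrow(m)), ncol(m)),
         col = rep(seq_len(ncol(m)), each = nrow(m)),
         label = factor(c("none", dr_signs())[as.vector(m) + 1L],
                        levels = c("none", dr_signs())))
}

#' @export
autoplot.lesion_segmentation <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$label)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(values = c(none = "grey15", exudate = "gold",
                                          hemorrhage = "firebrick",
                                          microaneurysm = "deeppink")) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL)
}
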