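#' One-vs-rest confusion counts
#'
#' Tallies true/false positives/negatives of `predicted` against `truth` for
#' one positive class; all other labels count as negative.
#'
#' @param predicted,truth Vectors of equal length (factors, characters or
#'   logicals).
#' @param positive_class The class treated as positive.
#' @return A one-row tibble: `tp`, `fp`, `tn`, `fn` (and the class).
#' @export
confusion_counts <- function(predicted, truth, positive_class) {
  if (length(predicted) != length(truth)) {
    stop_invalid("`predicted` and `truth` must have equal length.")
  }
  p <- predicted == positive_class
  t <- truth == positive_class
  tibble(class = as.character(positive_class),
         tp = sum(p & t), fp = sum(p & !t),
         tn = sum(!p & !t), fn = sum(!p & t))
}

#' Validation metrics from confusion counts
#'
#' Computes accuracy `(TP+TN)/(TP+TN+FP+FN)`, error rate
#' `(FP+FN)/(TP+TN+FP+FN)`, positive predictive value `TP/(TP+FP)`,
#' sensitivity `TP/(TP+FN)` and specificity `TN/(TN+FP)`. A metric with a
#' zero denominator is reported as `NA` and named in the `undefined` column
#' rather than silently zeroed.
#'
#' @param counts A one-row data frame (or named list/vector) with `tp`, `fp`,
#'   `tn`, `fn`; extra columns (e.g. `class`) are carried through.
#' @return A one-row tibble of the five metrics plus an `undefined` column
#'   (comma-separated names of undefined metrics, or `NA`).
#' @export
compute_metrics <- function(counts) {
  cn <- as.list(counts)
  tp <- cn$tp; fp <- cn$fp; tn <- cn$tn; fn <- cn$fn
  if (any(vapply(list(tp, fp, tn, fn), is.null, TRUE))) {
    stop_invalid("`counts` must provide tp, fp, tn and fn.")
  }
  vals <- c(tp, fp, tn, fn)
  if (any(vals < 0) || any(vals != round(vals))) {
    stop_invalid("confusion counts must be nonnegative integers.")
  }
  total <- tp + fp + tn + fn
  if (total == 0) stop_invalid("confusion counts sum to zero.")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  out <- tibble(
    accuracy = (tp + tn) / total,
    error_rate = (fp + fn) / total,
    ppv = ratio(tp, tp + fp),
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp)
  )
  undef <- names(out)[vapply(out, is.na, TRUE)]
  out$undefined <- if (length(undef)) paste(undef, collapse = ",") else NA_character_
  if (!is.null(cn$class)) out <- dplyr::mutate(out, class = cn$class, .before = 1L)
  out
}

#' Patch-level evaluation of a trained classifier
#'
#' Classifies each test patch by the class of maximum softmax probability and
#' reports the one-vs-rest validation metrics per class, together with the
#' raw score table for ROC plotting. For the mean over repeated
#' train/evaluate runs (the usual protocol is ten repetitions with seeds
#' 0..9), evaluate each run and average with [average_metrics()].
#'
#' @param model A trained `lesion_cnn`.
#' @param patches A patch tibble (typically the test split).
#' @param batch_size Windows per forward pass.
#' @return An object of class `patch_evaluation`: `metrics` (per-class
#'   tibble), `scores` (tibble with truth and the four class probabilities)
#'   and overall `accuracy`.
#' @export
evaluate_patches <- function(model, patches, batch_size = 256L) {
  stopifnot(inherits(model, "lesion_cnn"), is.data.frame(patches))
  if (nrow(patches) == 0L) stop_invalid("`patches` is empty.")
  probs <- predict_patch_probs(model, patches$window, batch_size)
  pred <- factor(dr_classes()[max.col(probs, ties.method = "first")],
                 levels = dr_classes())
  metrics <- dplyr::bind_rows(lapply(dr_classes(), function(cl) {
    compute_metrics(confusion_counts(pred, patches$label, cl))
  }))
  scores <- dplyr::bind_cols(
    tibble(truth = patches$label, predicted = pred),
    as_tibble(probs)
  )
  structure(list(metrics = metrics, scores = scores,
                 accuracy = mean(pred == patches$label)),
            class = "patch_evaluation")
}

#' @export
print.patch_evaluation <- function(x, ...) {
  cat(sprintf("<patch_evaluation> %d patches, overall accuracy %.3f\n",
              nrow(x$scores), x$accuracy))
  print(x$metrics)
  invisible(x)
}

#' @export
tidy.patch_evaluation <- function(x, ...) x$metrics

#' @export
glance.patch_evaluation <- function(x, ...) {
  tibble(n = nrow(x$scores), accuracy = x$accuracy)
}

#' Average metric reports over repetitions
#'
#' @param reports A list of per-class metric tibbles (or `patch_evaluation`
#'   objects) from repeated runs.
#' @return A tibble with the per-class mean of every numeric metric.
#' @export
average_metrics <- function(reports) {
  tabs <- lapply(reports, function(r) if (inherits(r, "patch_evaluation")) r$metrics else r)
  dplyr::bind_rows(tabs) |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(dplyr::across(dplyr::where(is.numeric),
                                   ~mean(.x, na.rm = TRUE)),
                     .groups = "drop")
}

#' Pixel-level evaluation of a segmentation
#'
#' Compares each sign's predicted mask with its ground-truth mask pixel by
#' pixel, restricted to the field of view when one is supplied (black corners
#' outside the retina would otherwise inflate the true-negative count), and
#' reports the one-vs-rest validation metrics per sign.
#'
#' @param result A `lesion_segmentation` (or named list of logical masks).
#' @param gt_masks Named list of ground-truth logical matrices per sign.
#' @param fov_mask Optional logical field-of-view matrix.
#' @return A per-sign tibble of confusion counts and metrics.
#' @export
evaluate_segmentation <- function(result, gt_masks, fov_mask = NULL) {
  masks <- if (inherits(result, "lesion_segmentation")) result$masks else result
  rows <- lapply(dr_signs(), function(sg) {
    pm <- masks[[sg]]
    gt <- gt_masks[[sg]]
    if (is.null(gt)) gt <- matrix(FALSE, nrow(pm), ncol(pm))
    if (!identical(dim(pm), dim(gt))) {
      stop_invalid("prediction and ground-truth shapes differ.")
    }
    keep <- if (is.null(fov_mask)) rep(TRUE, length(pm)) else as.vector(fov_mask)
    cc <- confusion_counts(pm[keep], gt[keep], TRUE)
    cc$class <- sg
    dplyr::bind_cols(cc["class"],
                     cc[c("tp", "fp", "tn", "fn")],
                     compute_metrics(cc)[c("accuracy", "error_rate", "ppv",
                                           "sensitivity", "specificity",
                                           "undefined")])
  })
  dplyr::bind_rows(rows)
}

#' Dice overlap coefficient between two masks
#'
#' `2|A ∩ B| / (|A| + |B|)`; 1 when both masks are empty.
#'
#' @param a,b Logical matrices of one shape.
#' @return Scalar in [0, 1].
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
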