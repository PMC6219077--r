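test_that("confusion counts match hand cases and a per-item tally oracle", {
  all_pos <- rep("a", 8)
  cc <- confusion_counts(all_pos, all_pos, "a")
  expect_identical(c(cc$tp, cc$fp, cc$tn, cc$fn), c(8L, 0L, 0L, 0L))
  cc2 <- confusion_counts(rep("b", 8), all_pos, "a")
  expect_identical(c(cc2$tp, cc2$tn), c(0L, 0L))
  expect_identical(c(cc2$fp, cc2$fn), c(0L, 8L))

  withr::with_seed(1, {
    pred <- sample(letters[1:4], 100, replace = TRUE)
    truth <- sample(letters[1:4], 100, replace = TRUE)
  })
  cc3 <- confusion_counts(pred, truth, "c")
  tally <- c(tp = 0L, fp = 0L, tn = 0L, fn = 0L)
  for (i in 1:100) {
    p <- pred[i] == "c"; t <- truth[i] == "c"
    nm <- if (p && t) "tp" else if (p) "fp" else if (t) "fn" else "tn"
    tally[nm] <- tally[nm] + 1L
  }
  expect_identical(c(cc3$tp, cc3$fp, cc3$tn, cc3$fn), unname(tally))
  expect_identical(cc3$tp + cc3$fp + cc3$tn + cc3$fn, 100L)
  expect_error(confusion_counts(pred[1:5], truth, "a"),
               class = "fundusdr_invalid_input")
})

test_that("the five validation metrics follow their printed formulas", {
  m <- compute_metrics(list(tp = 1, tn = 1, fp = 0, fn = 0))
  expect_equal(unlist(m[c("accuracy", "error_rate", "ppv", "sensitivity",
                          "specificity")]),
               c(accuracy = 1, error_rate = 0, ppv = 1, sensitivity = 1,
                 specificity = 1))
  m2 <- compute_metrics(list(tp = 96, fn = 4, tn = 98, fp = 2))
  expect_equal(m2$sensitivity, 0.96)
  expect_equal(m2$specificity, 0.98)
  expect_equal(m2$accuracy, 0.97)
  expect_equal(m2$ppv, 96 / 98)
  m3 <- compute_metrics(list(tp = 0, fp = 0, tn = 5, fn = 3))
  expect_true(is.na(m3$ppv))
  expect_match(m3$undefined, "ppv")
  expect_error(compute_metrics(list(tp = 0, fp = 0, tn = 0, fn = 0)),
               class = "fundusdr_invalid_input")
  expect_error(compute_metrics(list(tp = -1, fp = 1, tn = 1, fn = 1)),
               class = "fundusdr_invalid_input")
})

test_that("accuracy and error rate always sum to one", {
  withr::with_seed(2, {
    for (rep in 1:20) {
      cn <- as.list(setNames(sample(0:50, 4, replace = TRUE),
                             c("tp", "fp", "tn", "fn")))
      if (sum(unlist(cn)) == 0) next
      m <- compute_metrics(cn)
      expect_equal(m$accuracy + m$error_rate, 1, tolerance = 1e-15)
      vals <- unlist(m[c("accuracy", "error_rate", "ppv", "sensitivity",
                         "specificity")])
      expect_true(all(is.na(vals) | (vals >= 0 & vals <= 1)))
    }
  })
})

test_that("metrics are invariant to relabeling among negative classes", {
  withr::with_seed(3, {
    pred <- sample(c("a", "b", "c"), 60, replace = TRUE)
    truth <- sample(c("a", "b", "c"), 60, replace = TRUE)
  })
  swap <- function(x) ifelse(x == "b", "c", ifelse(x == "c", "b", x))
  m1 <- compute_metrics(confusion_counts(pred, truth, "a"))
  m2 <- compute_metrics(confusion_counts(swap(pred), swap(truth), "a"))
  expect_equal(m1, m2)
})

test_that("patch evaluation composes argmax prediction with the metric formulas", {
  patches <- separable_patches(n_images = 2L, seed = 20)
  model <- build_lesion_cnn(network_config(input_side = 16), seed = 9)
  model$input_stats <- list(channel_means = rep(0.5, 3))
  ev <- evaluate_patches(model, patches)
  probs <- predict_patch_probs(model, patches$window)
  pred <- factor(dr_classes()[max.col(probs, ties.method = "first")],
                 levels = dr_classes())
  for (cl in dr_classes()) {
    want <- compute_metrics(confusion_counts(pred, patches$label, cl))
    got <- ev$metrics[ev$metrics$class == cl, ]
    expect_equal(got$accuracy, want$accuracy)
    expect_equal(got$sensitivity, want$sensitivity)
  }
  expect_identical(nrow(ev$scores), nrow(patches))
  expect_equal(ev$accuracy, mean(pred == patches$label))
  expect_error(evaluate_patches(model, patches[0, ]),
               class = "fundusdr_invalid_input")
})

test_that("a trained classifier reaches high per-class patch accuracy on the separable fixture", {
  patches <- separable_patches(n_images = 4L, seed = 30)
  spec <- patch_spec(patch_size = 16, seed = 5)
  patches <- split_patches(patches, spec)
  model <- fit_lesion_cnn(
    build_lesion_cnn(network_config(input_side = 16, weight_init_sd = 0.2),
                     seed = 5),
    patches, training_config(learning_rate = 0.03, max_epochs = 8, seed = 5),
    spec)
  ev <- evaluate_patches(model, patches[patches$split == "test", ])
  expect_true(all(ev$metrics$accuracy >= 0.9))
})

test_that("averaging metric reports over repetitions is a per-class mean", {
  r1 <- tibble::tibble(class = c("a", "b"), accuracy = c(0.9, 0.8),
                       sensitivity = c(1, 0.5))
  r2 <- tibble::tibble(class = c("a", "b"), accuracy = c(0.7, 0.6),
                       sensitivity = c(0.8, 0.7))
  avg <- average_metrics(list(r1, r2))
  expect_equal(avg$accuracy[avg$class == "a"], 0.8)
  expect_equal(avg$sensitivity[avg$class == "b"], 0.6)
})

test_that("pixel-level evaluation tallies masks and respects the field of view", {
  withr::with_seed(4, {
    gt <- list(exudate = matrix(runif(100) < 0.2, 10),
               hemorrhage = matrix(runif(100) < 0.2, 10),
               microaneurysm = matrix(runif(100) < 0.2, 10))
  })
  # identical prediction: accuracy 1, error 0 for every sign
  ev <- evaluate_segmentation(gt, gt)
  expect_true(all(ev$accuracy == 1))
  expect_true(all(ev$error_rate == 0))
  # empty prediction with nonempty truth: sensitivity 0
  empty <- lapply(gt, function(m) m & FALSE)
  ev0 <- evaluate_segmentation(empty, gt)
  expect_true(all(ev0$sensitivity == 0))
  # random prediction equals a brute-force pixel tally
  withr::with_seed(5, pred <- lapply(gt, function(m) matrix(runif(100) < 0.3, 10)))
  ev_r <- evaluate_segmentation(pred, gt)
  for (sg in dr_signs()) {
    expect_identical(ev_r$tp[ev_r$class == sg], sum(pred[[sg]] & gt[[sg]]))
    expect_identical(ev_r$tn[ev_r$class == sg], sum(!pred[[sg]] & !gt[[sg]]))
  }
  # a field-of-view mask excludes outside pixels from every count
  fov <- matrix(FALSE, 10, 10); fov[3:8, 3:8] <- TRUE
  ev_f <- evaluate_segmentation(pred, gt, fov_mask = fov)
  expect_identical(ev_f$tp[1] + ev_f$fp[1] + ev_f$tn[1] + ev_f$fn[1], sum(fov))
  expect_error(evaluate_segmentation(list(exudate = matrix(FALSE, 3, 3),
                                          hemorrhage = matrix(FALSE, 3, 3),
                                          microaneurysm = matrix(FALSE, 3, 3)),
                                     gt),
               class = "fundusdr_invalid_input")
})

test_that("the Dice coefficient matches its closed form", {
  a <- matrix(FALSE, 5, 5); b <- matrix(FALSE, 5, 5)
  expect_equal(dice_coefficient(a, b), 1)
  a[1:2, 1:2] <- TRUE
  expect_equal(dice_coefficient(a, b), 0)
  b[1:2, 1] <- TRUE
  expect_equal(dice_coefficient(a, b), 2 * 2 / (4 + 2))
})
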