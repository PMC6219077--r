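test_that("perfect separation yields a threshold with sensitivity = specificity = 1", {
  scores <- c(rep(0.9, 40), rep(0.1, 60))
  truth <- c(rep(TRUE, 40), rep(FALSE, 60))
  out <- select_threshold(scores, truth)
  expect_gt(out$threshold, 0.1)
  expect_lte(out$threshold, 0.9)
  expect_equal(out$sensitivity, 1)
  expect_equal(out$specificity, 1)
  expect_equal(out$youden_j, 1)
})

test_that("identical scores trigger the degenerate-threshold warning", {
  expect_warning(select_threshold(rep(0.5, 10), rep(c(TRUE, FALSE), 5)),
                 "degenerate")
  expect_error(select_threshold(runif(10), rep(TRUE, 10)),
               class = "fundusdr_invalid_input")
  expect_error(select_threshold(runif(5), c(TRUE, FALSE, TRUE, FALSE)),
               class = "fundusdr_invalid_input")
})

test_that("threshold selection equals the exhaustive Youden sweep", {
  withr::with_seed(42, {
    for (rep in 1:5) {
      n <- 200
      truth <- runif(n) < 0.35
      scores <- ifelse(truth, rbeta(n, 4, 2), rbeta(n, 2, 4))
      got <- select_threshold(scores, truth)
      want <- oracle_youden(scores, truth)
      expect_identical(got$threshold, want$threshold)
      expect_equal(got$youden_j, want$j, tolerance = 1e-12)
      # optimality: J at the returned threshold >= J at every candidate
      for (th in unique(scores)) {
        pred <- scores >= th
        j <- sum(pred & truth) / sum(truth) +
          sum(!pred & !truth) / sum(!truth) - 1
        expect_lte(j, got$youden_j + 1e-12)
      }
    }
  })
})

test_that("the Youden maximum agrees with pROC as an independent cross-check", {
  skip_if_not_installed("pROC")
  withr::with_seed(7, {
    truth <- runif(300) < 0.4
    scores <- ifelse(truth, rbeta(300, 5, 2), rbeta(300, 2, 5))
  })
  got <- select_threshold(scores, truth)
  roc <- pROC::roc(truth, scores, quiet = TRUE)
  best <- pROC::coords(roc, "best", best.method = "youden",
                       ret = c("sensitivity", "specificity"))
  expect_equal(got$sensitivity + got$specificity,
               max(best$sensitivity + best$specificity), tolerance = 1e-9)
})

test_that("binarization follows the >= convention elementwise", {
  z <- matrix(0, 5, 5)
  expect_false(any(binarize_map(z, 0.5)))
  m <- matrix(0.37, 4, 4)
  expect_true(all(binarize_map(m, 0.37)))
  withr::with_seed(1, r <- matrix(runif(30 * 30), 30))
  expect_identical(sum(binarize_map(r, 0.6)), sum(r >= 0.6))
  expect_error(binarize_map(r, 0), class = "fundusdr_invalid_input")
  expect_error(binarize_map(r, 1), class = "fundusdr_invalid_input")
})

test_that("raising a threshold never increases the positive-pixel count", {
  withr::with_seed(2, r <- matrix(runif(40 * 40), 40))
  counts <- vapply(seq(0.05, 0.95, by = 0.05),
                   function(th) sum(binarize_map(r, th)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

fake_maps <- function(p_list, patch_size = 16L, stride = 1L) {
  p_list$no_sign <- pmax(0, 1 - Reduce(`+`, p_list[dr_signs()]))
  structure(list(maps = p_list,
                 grid = list(rows = seq_len(nrow(p_list[[1]])),
                             cols = seq_len(ncol(p_list[[1]]))),
                 stride = stride, patch_size = patch_size,
                 n_evaluations = length(p_list[[1]])),
            class = "probability_maps")
}

test_that("overlap resolution keeps unique claims and ranks shared pixels", {
  h <- 6; w <- 6
  pe <- matrix(0, h, w); ph <- matrix(0, h, w); pm <- matrix(0, h, w)
  pe[2, 2] <- 0.9; ph[2, 2] <- 0.8            # shared -> exudate (higher p)
  ph[3, 3] <- 0.7                             # unique -> hemorrhage
  pe[4, 4] <- 0.6; ph[4, 4] <- 0.6            # exact tie -> priority: exudate
  pm[5, 5] <- 0.95
  maps <- fake_maps(list(exudate = pe, hemorrhage = ph, microaneurysm = pm))
  bin <- lapply(maps$maps[dr_signs()], function(m) m > 0.5)
  lab <- resolve_overlaps(maps, bin)
  expect_identical(lab[2, 2], 1L)
  expect_identical(lab[3, 3], 2L)
  expect_identical(lab[4, 4], 1L)
  expect_identical(lab[5, 5], 3L)
  expect_identical(sum(lab > 0), 4L)
})

test_that("overlap resolution equals a per-pixel argmax oracle on random maps", {
  withr::with_seed(3, {
    h <- 12; w <- 10
    prob <- list(exudate = matrix(runif(h * w), h),
                 hemorrhage = matrix(runif(h * w), h),
                 microaneurysm = matrix(runif(h * w), h))
    bin <- lapply(prob, function(m) matrix(runif(h * w) < 0.5, h))
  })
  maps <- fake_maps(prob)
  got <- resolve_overlaps(maps, bin)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      active <- which(vapply(dr_signs(), function(s) bin[[s]][i, j], TRUE))
      want <- if (length(active) == 0L) 0L else {
        vals <- vapply(dr_signs()[active], function(s) prob[[s]][i, j], 0)
        active[which.max(vals)] # which.max takes the first = priority order
      }
      expect_identical(got[i, j], as.integer(want))
    }
  }
})

test_that("segmentation output masks are disjoint and exclusivity holds on shared regions", {
  h <- 60; w <- 60
  base <- matrix(0.01, h, w)
  pe <- base; ph <- base; pm <- base
  pe[10:35, 10:35] <- 0.9
  ph[10:35, 10:35] <- 0.85 # the same region exceeds both thresholds
  maps <- fake_maps(list(exudate = pe, hemorrhage = ph, microaneurysm = pm))
  th <- c(exudate = 0.5, hemorrhage = 0.5, microaneurysm = 0.5)
  seg <- segment_image(maps, th, patch_size = 16,
                       kernel_sizes = c(closing = 2L, opening = 2L, erosion = 1L))
  claims <- Reduce(`+`, lapply(seg$masks, function(m) m * 1L))
  expect_true(all(claims <= 1L))
  expect_gt(sum(seg$masks$exudate), 0)
  expect_identical(sum(seg$masks$hemorrhage), 0L)
  # all-background maps segment to nothing
  empty <- fake_maps(list(exudate = base, hemorrhage = base,
                          microaneurysm = base))
  seg0 <- segment_image(empty, th, patch_size = 16,
                        kernel_sizes = c(closing = 2L, opening = 2L, erosion = 1L))
  expect_false(any(seg0$label_map > 0))
})

test_that("no surviving component is smaller than the area rule after segmentation", {
  withr::with_seed(4, {
    h <- 80; w <- 80
    prob <- list(exudate = matrix(runif(h * w, 0, 0.9), h),
                 hemorrhage = matrix(runif(h * w, 0, 0.9), h),
                 microaneurysm = matrix(runif(h * w, 0, 0.9), h))
  })
  maps <- fake_maps(prob)
  seg <- segment_image(maps, c(exudate = 0.55, hemorrhage = 0.55,
                               microaneurysm = 0.55),
                       patch_size = 20)
  for (sg in dr_signs()) {
    if (any(seg$masks[[sg]])) {
      sizes <- tabulate(label_components(seg$masks[[sg]], 8L))
      expect_true(all(sizes >= 20^2 / 4))
    }
  }
})

test_that("threshold sets round-trip through JSON", {
  ts <- structure(tibble::tibble(sign = dr_signs(),
                                 threshold = c(0.61, 0.52, 0.43),
                                 sensitivity = c(0.9, 0.8, 0.7),
                                 specificity = c(0.95, 0.9, 0.85),
                                 youden_j = c(0.85, 0.7, 0.55),
                                 criterion = "youden"),
                  class = c("threshold_set", class(tibble::tibble())))
  path <- withr::local_tempfile(fileext = ".json")
  write_thresholds(ts, path)
  back <- read_thresholds(path)
  expect_equal(back$threshold, ts$threshold)
  expect_identical(back$sign, ts$sign)
})
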