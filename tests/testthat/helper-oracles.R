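# Independent brute-force oracles used across the suite. These deliberately
# re-derive each operation from its set/sum definition, sharing no code with
# the implementation they check.

random_mask <- function(h, w, p = 0.4, seed = 1) {
  withr::with_seed(seed, matrix(runif(h * w) < p, h, w))
}

# Dense 2-D convolution with a truncated Gaussian kernel and symmetric
# (reflect-with-edge) padding: O(H * W * k^2) quadruple loop.
oracle_gaussian_convolve <- function(mat, sigma) {
  r <- ceiling(4 * sigma)
  x <- seq(-r, r)
  k1 <- exp(-x^2 / (2 * sigma^2))
  kern <- outer(k1, k1)
  kern <- kern / sum(kern)
  h <- nrow(mat); w <- ncol(mat)
  refl <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      acc <- 0
      for (di in -r:r) {
        for (dj in -r:r) {
          acc <- acc + kern[di + r + 1, dj + r + 1] *
            mat[refl(i + di, h), refl(j + dj, w)]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# The dihedral group of the square, enumerated by composing the two
# generators (quarter rotation, horizontal flip) to closure.
oracle_dihedral_set <- function(m) {
  rot <- function(x) t(x)[, rev(seq_len(nrow(x))), drop = FALSE]
  flip <- function(x) x[, rev(seq_len(ncol(x))), drop = FALSE]
  seen <- list(m)
  repeat {
    new <- list()
    for (x in seen) {
      for (y in list(rot(x), flip(x))) {
        if (!any(vapply(c(seen, new), identical, TRUE, y = y))) {
          new <- c(new, list(y))
        }
      }
    }
    if (length(new) == 0L) break
    seen <- c(seen, new)
  }
  seen
}

# Minkowski morphology from the set definition, with background outside.
oracle_se <- function(k) {
  o <- ceiling(k / 2) - 1
  off <- expand.grid(dy = seq_len(k) - 1 - o, dx = seq_len(k) - 1 - o)
  off
}

oracle_dilate <- function(mask, k) {
  off <- oracle_se(k)
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      for (t in seq_len(nrow(off))) {
        ii <- i - off$dy[t]; jj <- j - off$dx[t]
        if (ii >= 1 && ii <= h && jj >= 1 && jj <= w && mask[ii, jj]) {
          out[i, j] <- TRUE
          break
        }
      }
    }
  }
  out
}

oracle_erode <- function(mask, k) {
  off <- oracle_se(k)
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(TRUE, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      for (t in seq_len(nrow(off))) {
        ii <- i + off$dy[t]; jj <- j + off$dx[t]
        if (ii < 1 || ii > h || jj < 1 || jj > w || !mask[ii, jj]) {
          out[i, j] <- FALSE
          break
        }
      }
    }
  }
  out
}

oracle_open <- function(mask, k) oracle_dilate(oracle_erode(mask, k), k)
oracle_close <- function(mask, k) oracle_erode(oracle_dilate(mask, k), k)

# Connected components by breadth-first search.
oracle_components <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  nb <- if (connectivity == 8) {
    expand.grid(dy = -1:1, dx = -1:1)
  } else {
    data.frame(dy = c(-1, 1, 0, 0), dx = c(0, 0, -1, 1))
  }
  nb <- nb[!(nb$dy == 0 & nb$dx == 0), ]
  lab <- matrix(0L, h, w)
  nxt <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      i <- (p - 1L) %% h + 1L; j <- (p - 1L) %/% h + 1L
      for (t in seq_len(nrow(nb))) {
        ii <- i + nb$dy[t]; jj <- j + nb$dx[t]
        if (ii >= 1 && ii <= h && jj >= 1 && jj <= w &&
            mask[ii, jj] && lab[ii, jj] == 0L) {
          q <- (jj - 1L) * h + ii
          lab[q] <- nxt
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

# Exhaustive Youden-J maximization over every candidate cut (all distinct
# score values), ties toward the higher threshold.
oracle_youden <- function(scores, truth) {
  best <- -Inf; best_th <- NA_real_
  for (th in sort(unique(scores), decreasing = TRUE)) {
    pred <- scores >= th
    sens <- sum(pred & truth) / sum(truth)
    spec <- sum(!pred & !truth) / sum(!truth)
    j <- sens + spec - 1
    if (j > best) { # strict: the first (highest) threshold keeps ties
      best <- j
      best_th <- th
    }
  }
  list(threshold = best_th, j = best)
}

# Nearest-class-centroid classifier on standardized per-channel summary
# features (mean, min, max): an interpretable separability oracle for patch
# sets. Considers only windows lying fully on the retina, away from the
# near-black field-of-view rim (outside it the background class is trivially
# multimodal and the summary features collapse).
oracle_on_retina <- function(patches) {
  keep <- vapply(patches$window, function(w) {
    all(w[, , 1] + w[, , 2] + w[, , 3] > 50)
  }, TRUE)
  patches[keep, ]
}

oracle_nearest_mean <- function(train, test) {
  train <- oracle_on_retina(train)
  test <- oracle_on_retina(test)
  feat <- function(w) {
    as.vector(vapply(seq_len(dim(w)[3]), function(k) {
      ch <- w[, , k]
      c(mean(ch), min(ch), max(ch))
    }, numeric(3)))
  }
  ftr <- t(vapply(train$window, feat, numeric(3 * dim(train$window[[1]])[3])))
  fte <- t(vapply(test$window, feat, numeric(3 * dim(test$window[[1]])[3])))
  mu <- colMeans(ftr)
  sd_f <- pmax(apply(ftr, 2L, sd), 1e-9)
  ftr <- sweep(sweep(ftr, 2L, mu), 2L, sd_f, "/")
  fte <- sweep(sweep(fte, 2L, mu), 2L, sd_f, "/")
  centroids <- lapply(split(seq_len(nrow(ftr)), droplevels(train$label)),
                      function(i) colMeans(ftr[i, , drop = FALSE]))
  cls <- names(centroids)
  pred <- vapply(seq_len(nrow(fte)), function(i) {
    d <- vapply(centroids, function(ce) sum((fte[i, ] - ce)^2), numeric(1))
    cls[which.min(d)]
  }, "")
  list(pred = factor(pred, levels = levels(test$label)),
       truth = test$label)
}

# Grid patching labels a patch by overlap, so a window catching the corner of
# a large lesion carries its label while looking locally like a smaller sign
# (or background): such fragments are label noise for ANY local classifier.
# A patch is "unambiguous" when, for every sign it touches, it either
# contains the touched components entirely or is dominated by them
# (>= 40 % of the window).
unambiguous_patches <- function(patches, images, s) {
  comp <- lapply(images, function(im) lapply(im$gt_masks, label_components))
  names(comp) <- vapply(images, function(im) im$id, "")
  sizes <- lapply(comp, function(cs) lapply(cs, function(l) tabulate(l)))
  keep <- vapply(seq_len(nrow(patches)), function(i) {
    id <- patches$image_id[i]
    rows <- (patches$row[i] + 1):(patches$row[i] + s)
    cols <- (patches$col[i] + 1):(patches$col[i] + s)
    for (sg in dr_signs()) {
      sub <- comp[[id]][[sg]][rows, cols]
      ids <- setdiff(unique(as.vector(sub)), 0L)
      if (length(ids) == 0L) next
      inside <- sum(sub > 0L)
      whole <- sum(sizes[[id]][[sg]][ids])
      if (inside < whole && inside < 0.4 * s^2) return(FALSE)
    }
    TRUE
  }, TRUE)
  patches[keep, ]
}

# A small, strongly separated fixture configuration used by training tests:
# no vessels, low noise, large intensity deltas.
separable_fixture_config <- function(seed = 1L) {
  fixture_config(image_side = 160L, n_exudates = 2L, n_hemorrhages = 2L,
                 n_microaneurysms = 4L,
                 exudate_radius = c(7, 11), exudate_delta = 110,
                 hemorrhage_radius = c(7, 11), hemorrhage_delta = 90,
                 microaneurysm_radius = c(3, 4), microaneurysm_delta = 110,
                 n_vessels = 0L, noise_sd = 1, seed = seed)
}

# Labeled patch set pooled over a few separable fixture images (raw, i.e.
# without contrast enhancement, to keep class means interpretable).
separable_images <- function(n_images = 4L, seed = 1L) {
  lapply(seq_len(n_images), function(i) {
    simulate_fundus(separable_fixture_config(seed = seed + i),
                    id = sprintf("sep_%d", i))
  })
}

separable_patches <- function(n_images = 4L, seed = 1L, patch_size = 16L) {
  spec <- patch_spec(patch_size = patch_size, seed = seed)
  imgs <- separable_images(n_images, seed)
  dplyr::bind_rows(lapply(imgs, extract_patches, spec = spec))
}
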