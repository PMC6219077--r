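tiny_config <- function(...) {
  network_config(input_side = 16L, n_channels = 2L, feature_maps = 3L,
                 fc_units = 6L, dropout_rate = 0, ...)
}

randomized_model <- function(config, seed = 5, sd = 0.3) {
  m <- build_lesion_cnn(config, seed = 42)
  withr::with_seed(seed, {
    for (nm in names(m$params)) {
      for (pn in names(m$params[[nm]])) {
        m$params[[nm]][[pn]][] <- rnorm(length(m$params[[nm]][[pn]]), sd = sd)
      }
    }
  })
  m$input_stats <- list(channel_means = rep(0.5, config$n_channels))
  m
}

test_that("the built network matches the reference architecture contract", {
  cfg <- network_config()
  expect_identical(cfg$n_conv_blocks, 4L)
  expect_identical(cfg$feature_maps, 16L)
  expect_identical(cfg$fc_units, 256L)
  expect_identical(cfg$dropout_rate, 0.5)
  model <- build_lesion_cnn(cfg, seed = 1)
  for (b in 1:4) {
    expect_identical(ncol(model$params[[paste0("conv", b)]]$W), 16L)
    expect_identical(length(model$params[[paste0("conv", b)]]$b), 16L)
    expect_true(all(model$params[[paste0("conv", b)]]$b == 0))
  }
  # feature-map sides under floor pooling: 50 -> 25 -> 12 -> 6 -> 3
  expect_identical(fundusdr:::feature_map_sides(cfg), c(25L, 12L, 6L, 3L))
  expect_identical(nrow(model$params$fc2$W), 4L)

  withr::with_seed(2, patch <- array(runif(50 * 50 * 3, 0, 255), c(50, 50, 3)))
  p <- predict_patch(model, patch)
  expect_identical(length(p), 4L)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(sum(p), 1, tolerance = 1e-6)
  # dropout is inactive at inference: repeated passes agree exactly
  expect_identical(p, predict_patch(model, patch))
})

test_that("an input too small for four pooling stages is rejected", {
  expect_error(network_config(input_side = 15),
               class = "fundusdr_invalid_config")
  expect_silent(network_config(input_side = 16))
})

test_that("weight initialization is a seeded zero-mean Gaussian of sd 0.01", {
  model <- build_lesion_cnn(network_config(), seed = 7)
  w <- as.vector(model$params$fc1$W)
  expect_equal(sd(w), 0.01, tolerance = 0.01)
  expect_lt(abs(mean(w)), 1e-3)
  expect_identical(model$params,
                   build_lesion_cnn(network_config(), seed = 7)$params)
})

test_that("softmax outputs are normalized for random inputs and weights", {
  cfg <- tiny_config()
  withr::with_seed(3, {
    for (rep in 1:5) {
      m <- randomized_model(cfg, seed = sample.int(1e6, 1))
      A <- array(runif(16 * 16 * 3 * 2, 0, 255), c(16, 16, 3, 2))
      probs <- fundusdr:::cnn_forward(m, A)$probs
      expect_equal(rowSums(probs), rep(1, 3), tolerance = 1e-6)
      expect_true(all(probs >= 0 & probs <= 1))
    }
  })
})

test_that("cross-entropy loss reproduces its closed forms", {
  expect_equal(cross_entropy_loss(matrix(c(1, 0, 0, 0), 1), 1L), 0)
  expect_equal(cross_entropy_loss(matrix(0.25, 1, 4), 3L), log(4),
               tolerance = 1e-12)
  p <- rbind(c(exp(-1), 1 - exp(-1), 0, 0),
             c(1 - exp(-3), exp(-3), 0, 0))
  expect_equal(cross_entropy_loss(p, c(1L, 2L)), 2, tolerance = 1e-12)
  # invariant to sample order
  expect_equal(cross_entropy_loss(p[2:1, ], c(2L, 1L)),
               cross_entropy_loss(p, c(1L, 2L)))
  expect_error(cross_entropy_loss(matrix(0.25, 1, 4), 5L),
               class = "fundusdr_invalid_input")
  expect_error(cross_entropy_loss(matrix(c(0.9, 0.4, 0, 0), 1), 1L),
               class = "fundusdr_invalid_input")
})

test_that("the SGD update follows the printed rule exactly", {
  # plain gradient step
  up <- sgd_update(2, 0.5, lr = 0.1)
  expect_equal(up$theta, 2 - 0.05)
  # fixed point at zero gradient
  up <- sgd_update(2, 0, lr = 0.1)
  expect_equal(up$theta, 2)
  expect_equal(up$velocity, 0)
  # hand-evaluated scalar step with momentum and weight decay:
  # theta' = 1 - 0.1*0.5 + 0.9*(-0.02) - 0.1*0.1*1 = 0.922
  up <- sgd_update(1, 0.5, lr = 0.1, momentum = 0.9, weight_decay = 0.1,
                   velocity = -0.02)
  expect_equal(up$theta, 0.922, tolerance = 1e-15)
  expect_equal(up$velocity, 0.922 - 1)
  # nested structures update leaf-wise
  th <- list(a = matrix(1, 2, 2), b = list(c = rep(2, 3)))
  gr <- list(a = matrix(1, 2, 2), b = list(c = rep(1, 3)))
  up <- sgd_update(th, gr, lr = 0.5)
  expect_equal(up$theta$a, matrix(0.5, 2, 2))
  expect_equal(up$theta$b$c, rep(1.5, 3))
  expect_error(sgd_update(matrix(1, 2, 2), matrix(1, 3, 3), lr = 0.1),
               class = "fundusdr_invalid_input")
})

test_that("one SGD step descends a quadratic objective", {
  theta <- c(3, -2)
  loss <- function(t) sum(t^2)
  up <- sgd_update(theta, 2 * theta, lr = 0.1)
  expect_lt(loss(up$theta), loss(theta))
})

test_that("the step-down schedule multiplies the rate by gamma every lr_step epochs", {
  cfg <- training_config(learning_rate = 0.01, lr_gamma = 0.1, lr_step = 33)
  lr <- vapply(1:100, function(e) fundusdr:::effective_lr(cfg, e), numeric(1))
  expect_equal(lr[1:33], rep(0.01, 33))
  expect_equal(lr[34:66], rep(0.001, 33))
  expect_equal(lr[67:99], rep(1e-4, 33))
  # closed form: gamma0 * gamma^floor(e / step) with e counted from 0
  e0 <- 0:99
  expect_equal(lr, 0.01 * 0.1^(e0 %/% 33))
})

test_that("backpropagation matches finite-difference gradients", {
  for (norm in c("lrn", "none", "batch")) {
    cfg <- tiny_config(norm = norm)
    m <- randomized_model(cfg)
    withr::with_seed(1, A <- array(runif(16 * 16 * 4 * 2, 0, 255),
                                   c(16, 16, 4, 2)))
    y <- c(1L, 2L, 3L, 4L)
    Y <- diag(4)[y, ]
    training <- norm == "batch" # batch stats must match between passes
    loss_at <- function(mm) {
      cross_entropy_loss(fundusdr:::cnn_forward(mm, A, training)$probs, y)
    }
    fw <- fundusdr:::cnn_forward(m, A, training, keep_caches = TRUE)
    g <- fundusdr:::cnn_backward(m, fw$caches, Y)
    eps <- 1e-5
    withr::with_seed(2, {
      for (nm in names(m$params)) {
        for (pn in names(m$params[[nm]])) {
          P <- m$params[[nm]][[pn]]
          for (i in sample(length(P), min(4L, length(P)))) {
            m2 <- m
            m2$params[[nm]][[pn]][i] <- P[i] + eps
            lp <- loss_at(m2)
            m2$params[[nm]][[pn]][i] <- P[i] - eps
            lm <- loss_at(m2)
            num <- (lp - lm) / (2 * eps)
            expect_equal(g[[nm]][[pn]][i], num, tolerance = 1e-4)
          }
        }
      }
    })
  }
})

test_that("a zero learning rate with zero decay leaves parameters unchanged", {
  patches <- separable_patches(n_images = 1L, seed = 3)
  spec <- patch_spec(patch_size = 16, seed = 1, augment = FALSE)
  patches <- suppressWarnings(split_patches(patches, spec))
  cfg <- network_config(input_side = 16)
  model <- build_lesion_cnn(cfg, seed = 1)
  before <- model$params
  trained <- fit_lesion_cnn(model, patches,
                            training_config(learning_rate = 0,
                                            weight_decay = 0, momentum = 0,
                                            max_epochs = 2, seed = 1),
                            spec)
  expect_equal(trained$params, before, tolerance = 1e-15)
})

test_that("training is deterministic and learns the separable fixture", {
  imgs <- separable_images(n_images = 4L, seed = 10)
  spec <- patch_spec(patch_size = 16, seed = 2)
  patches <- dplyr::bind_rows(lapply(imgs, extract_patches, spec = spec))
  patches <- split_patches(patches, spec)
  # desk-scale calibration: larger init and rate (see the methods vignette)
  net_cfg <- network_config(input_side = 16, weight_init_sd = 0.2)
  train_cfg <- training_config(learning_rate = 0.03, max_epochs = 10, seed = 4)
  m1 <- fit_lesion_cnn(build_lesion_cnn(net_cfg, seed = 4),
                       patches, train_cfg, spec)
  expect_gt(dplyr::last(m1$history$val_accuracy), 0.9)

  # the same classes (unambiguous windows) are separable for a
  # nearest-centroid oracle, so the training property is attainable
  clean <- unambiguous_patches(patches, imgs, 16L)
  nm <- oracle_nearest_mean(clean[clean$split == "train", ],
                            clean[clean$split != "train", ])
  expect_equal(mean(nm$pred == nm$truth), 1.0)

  # determinism: an identical seed reproduces the loss history exactly
  m2 <- fit_lesion_cnn(build_lesion_cnn(net_cfg, seed = 4),
                       patches, train_cfg, spec)
  expect_identical(m1$history, m2$history)
  expect_equal(m1$params, m2$params)
})

test_that("tidy, glance and checkpoints expose the fitted model", {
  patches <- separable_patches(n_images = 2L, seed = 6)
  spec <- patch_spec(patch_size = 16, seed = 2, augment = FALSE)
  patches <- split_patches(patches, spec)
  model <- fit_lesion_cnn(build_lesion_cnn(network_config(input_side = 16), seed = 1),
                          patches, training_config(max_epochs = 2, seed = 1),
                          spec)
  h <- tidy(model)
  expect_identical(names(h), c("epoch", "lr", "train_loss", "val_accuracy"))
  expect_identical(nrow(h), 2L)
  g <- glance(model)
  expect_identical(g$epochs_trained, 2L)
  expect_identical(g$feature_maps, 16L)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  model2 <- load_checkpoint(path)
  expect_equal(model2$params, model$params)
  w <- patches$window[[1]]
  expect_identical(predict_patch(model2, w), predict_patch(model, w))
})

test_that("wrong-size patches are rejected at prediction", {
  model <- build_lesion_cnn(network_config(input_side = 16), seed = 1)
  expect_error(predict_patch(model, array(0, c(20, 20, 3))),
               class = "fundusdr_invalid_input")
})
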