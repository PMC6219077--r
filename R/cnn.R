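#' Network architecture configuration
#'
#' Describes the four-block patch classifier: four stages of
#' `conv(16, 3x3) -> ReLU -> maxpool(2x2) -> normalization`, followed by a
#' 256-unit fully connected layer with ReLU and dropout, and a 4-way softmax
#' over the classes exudate / hemorrhage / microaneurysm / no-sign.
#'
#' @param input_side Side of the square input patch in pixels. Must admit the
#'   four pooling stages (i.e. be at least `2^n_conv_blocks`).
#' @param n_channels Input channels (3 for RGB).
#' @param n_conv_blocks Number of conv/pool blocks (default 4).
#' @param feature_maps Feature maps per convolutional layer (default 16).
#' @param conv_kernel Convolution kernel side (fixed at 3).
#' @param pool_kernel Pooling kernel side (fixed at 2, stride 2, floor on odd
#'   sides, no padding; convolutions use same-padding).
#' @param fc_units Width of the hidden fully connected layer (default 256).
#' @param n_classes Number of output classes (4).
#' @param dropout_rate Dropout probability on the hidden FC layer (default 0.5).
#' @param norm Normalization layer after each pooling stage: `"lrn"` (local
#'   response normalization, the default), `"batch"`, or `"none"`.
#' @param weight_init_sd Standard deviation of the zero-mean Gaussian weight
#'   initialization (default 0.01); biases start at zero.
#' @return A `network_config` list.
#' @export
network_config <- function(input_side = 50L, n_channels = 3L,
                           n_conv_blocks = 4L, feature_maps = 16L,
                           conv_kernel = 3L, pool_kernel = 2L,
                           fc_units = 256L, n_classes = 4L,
                           dropout_rate = 0.5,
                           norm = c("lrn", "batch", "none"),
                           weight_init_sd = 0.01) {
  norm <- match.arg(norm)
  counts <- c(n_conv_blocks, feature_maps, fc_units, n_classes, n_channels)
  if (any(counts < 1)) stop_invalid("all layer counts must be >= 1.")
  if (conv_kernel != 3L) stop_invalid("only 3x3 convolution kernels are supported.")
  if (pool_kernel != 2L) stop_invalid("only 2x2 pooling kernels are supported.")
  if (n_classes != 4L) stop_invalid("the classifier is four-class by design.")
  if (input_side < 2^n_conv_blocks) {
    abort(sprintf("input_side %d is too small for %d pooling stages (needs >= %d).",
                  input_side, n_conv_blocks, 2^n_conv_blocks),
          class = "fundusdr_invalid_config")
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop_invalid("`dropout_rate` must be in [0, 1).")
  }
  structure(list(input_side = as.integer(input_side),
                 n_channels = as.integer(n_channels),
                 n_conv_blocks = as.integer(n_conv_blocks),
                 feature_maps = as.integer(feature_maps),
                 conv_kernel = 3L, pool_kernel = 2L,
                 fc_units = as.integer(fc_units), n_classes = 4L,
                 dropout_rate = dropout_rate, norm = norm,
                 weight_init_sd = weight_init_sd),
            class = "network_config")
}

#' Training (SGD) configuration
#'
#' Hyperparameters of mini-batch stochastic gradient descent with classical
#' momentum, weight decay and a step-down learning-rate policy:
#' the effective learning rate at (1-based) epoch `e` is
#' `learning_rate * lr_gamma^((e - 1) %/% lr_step)`.
#'
#' @param learning_rate Initial learning rate (default 0.01).
#' @param momentum Momentum rate in `[0, 1)` (default 0.9).
#' @param weight_decay Weight-decay rate (default 5e-4).
#' @param train_batch Mini-batch size for training (default 128).
#' @param eval_batch Batch size for validation/test passes (default 32).
#' @param lr_gamma Multiplier applied to the learning rate at each step-down
#'   (default 0.1).
#' @param lr_step Epochs between step-downs (default 33).
#' @param max_epochs Number of training epochs (default 43).
#' @param seed Integer seed; training is deterministic given it.
#' @return A `training_config` list.
#' @export
training_config <- function(learning_rate = 0.01, momentum = 0.9,
                            weight_decay = 5e-4, train_batch = 128L,
                            eval_batch = 32L, lr_gamma = 0.1, lr_step = 33L,
                            max_epochs = 43L, seed = 1L) {
  if (learning_rate < 0) stop_invalid("`learning_rate` must be >= 0.")
  if (momentum < 0 || momentum >= 1) stop_invalid("`momentum` must be in [0, 1).")
  if (lr_gamma <= 0 || lr_gamma > 1) stop_invalid("`lr_gamma` must be in (0, 1].")
  if (lr_step < 1) stop_invalid("`lr_step` must be >= 1.")
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 weight_decay = weight_decay,
                 train_batch = as.integer(train_batch),
                 eval_batch = as.integer(eval_batch),
                 lr_gamma = lr_gamma, lr_step = as.integer(lr_step),
                 max_epochs = as.integer(max_epochs), seed = as.integer(seed)),
            class = "training_config")
}

# Spatial side of each feature map after b conv/pool blocks (floor pooling).
feature_map_sides <- function(config) {
  side <- config$input_side
  sides <- integer(config$n_conv_blocks)
  for (b in seq_len(config$n_conv_blocks)) {
    side <- side %/% 2L
    sides[b] <- side
  }
  sides
}

#' Build the four-block patch classifier
#'
#' Instantiates the network of [network_config()] with weights drawn from a
#' zero-mean Gaussian (`sd = weight_init_sd`) and zero biases.
#'
#' @param config A [network_config()].
#' @param seed Optional integer seed for the weight initialization.
#' @return An object of class `lesion_cnn` holding the parameters
#'   `theta = {W_i, b_i}`, the configuration, and (once fitted) input
#'   statistics and a training history.
#' @export
build_lesion_cnn <- function(config = network_config(), seed = NULL) {
  stopifnot(inherits(config, "network_config"))
  init <- function() {
    params <- list()
    c_in <- config$n_channels
    for (b in seq_len(config$n_conv_blocks)) {
      params[[paste0("conv", b)]] <- list(
        W = matrix(rnorm(9L * c_in * config$feature_maps,
                         sd = config$weight_init_sd),
                   9L * c_in, config$feature_maps),
        b = numeric(config$feature_maps))
      if (config$norm == "batch") {
        params[[paste0("bn", b)]] <- list(
          gamma = rep(1, config$feature_maps),
          beta = numeric(config$feature_maps))
      }
      c_in <- config$feature_maps
    }
    n_flat <- tail(feature_map_sides(config), 1L)^2 * config$feature_maps
    params$fc1 <- list(
      W = matrix(rnorm(config$fc_units * n_flat, sd = config$weight_init_sd),
                 config$fc_units, n_flat),
      b = numeric(config$fc_units))
    params$fc2 <- list(
      W = matrix(rnorm(config$n_classes * config$fc_units,
                       sd = config$weight_init_sd),
                 config$n_classes, config$fc_units),
      b = numeric(config$n_classes))
    params
  }
  params <- if (is.null(seed)) init() else withr::with_seed(seed, init())
  running <- NULL
  if (config$norm == "batch") {
    running <- replicate(config$n_conv_blocks,
                         list(mean = numeric(config$feature_maps),
                              var = rep(1, config$feature_maps)),
                         simplify = FALSE)
  }
  structure(list(config = config, params = params, running = running,
                 input_stats = NULL, history = NULL),
            class = "lesion_cnn")
}

#' @export
print.lesion_cnn <- function(x, ...) {
  cfg <- x$config
  sides <- feature_map_sides(cfg)
  cat(sprintf("<lesion_cnn> input %dx%dx%d -> %s -> FC(%d) -> FC(%d) softmax\n",
              cfg$input_side, cfg$input_side, cfg$n_channels,
              paste(sprintf("conv(%d)@%d", cfg$feature_maps, sides),
                    collapse = " -> "),
              cfg$fc_units, cfg$n_classes))
  cat(sprintf("  normalization: %s; dropout %.2f; %s\n", cfg$norm,
              cfg$dropout_rate,
              if (is.null(x$history)) "untrained" else
                sprintf("trained %d epochs (val accuracy %.3f)",
                        nrow(x$history), tail(x$history$val_accuracy, 1L))))
  invisible(x)
}

# Scale raw 0-255 windows to [0,1] and subtract per-channel training means.
normalize_batch <- function(model, A) {
  A <- A / 255
  means <- model$input_stats$channel_means
  if (!is.null(means)) {
    for (c in seq_along(means)) {
      A[, , , c] <- A[, , , c, drop = FALSE] - means[c]
    }
  }
  A
}

# Stack a list of (S, S, C) windows into an (S, S, B, C) activation array.
stack_windows <- function(windows, s, n_ch) {
  A <- array(0, c(s, s, length(windows), n_ch))
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    if (is.matrix(w)) dim(w) <- c(dim(w), 1L)
    A[, , i, ] <- w
  }
  A
}

# Full forward pass. `A` is a raw (S, S, B, C) window stack in 0-255.
# Returns class probabilities (B x 4) and, when `keep_caches`, everything
# needed for backpropagation.
cnn_forward <- function(model, A, training = FALSE, keep_caches = FALSE) {
  cfg <- model$config
  A <- normalize_batch(model, A)
  caches <- list()
  for (b in seq_len(cfg$n_conv_blocks)) {
    cv <- conv_forward(A, model$params[[paste0("conv", b)]]$W,
                       model$params[[paste0("conv", b)]]$b)
    rl <- relu_forward(cv$out)
    mp <- maxpool_forward(rl$out)
    nm <- switch(cfg$norm,
      lrn = lrn_forward(mp$out),
      batch = batchnorm_forward(mp$out, model$params[[paste0("bn", b)]]$gamma,
                                model$params[[paste0("bn", b)]]$beta,
                                model$running[[b]], training),
      none = list(out = mp$out))
    if (cfg$norm == "batch" && training) model$running[[b]] <- nm$running
    A <- nm$out
    if (keep_caches) {
      caches[[b]] <- list(conv = cv["in_dim"], conv_X = cv$X, relu = rl,
                          pool = mp, norm = nm)
    }
  }
  d <- dim(A)
  Z <- aperm(A, c(1L, 2L, 4L, 3L))
  dim(Z) <- c(d[1] * d[2] * d[4], d[3])
  fc1 <- fc_forward(Z, model$params$fc1$W, model$params$fc1$b)
  rl_fc <- relu_forward(fc1$out)
  dp <- dropout_forward(rl_fc$out, cfg$dropout_rate, training)
  fc2 <- fc_forward(dp$out, model$params$fc2$W, model$params$fc2$b)
  probs <- softmax_columns(fc2$out)
  out <- list(probs = t(probs), model = model)
  if (keep_caches) {
    out$caches <- list(blocks = caches, flat_dim = d, fc1 = fc1,
                       relu_fc = rl_fc, dropout = dp, fc2 = fc2,
                       probs = probs)
  }
  out
}

# Backward pass from per-sample one-hot targets Y (B x 4). Returns gradients
# with the same nesting as `model$params`.
cnn_backward <- function(model, caches, Y) {
  cfg <- model$config
  B <- nrow(Y)
  grads <- list()
  dlogits <- (caches$probs - t(Y)) / B
  fcb2 <- fc_backward(dlogits, caches$fc2, model$params$fc2$W)
  grads$fc2 <- list(W = fcb2$dW, b = fcb2$db)
  dZ <- dropout_backward(fcb2$dZ, caches$dropout)
  dZ <- relu_backward(dZ, caches$relu_fc)
  fcb1 <- fc_backward(dZ, caches$fc1, model$params$fc1$W)
  grads$fc1 <- list(W = fcb1$dW, b = fcb1$db)
  d <- caches$flat_dim
  dA <- fcb1$dZ
  dim(dA) <- c(d[1], d[2], d[4], d[3])
  dA <- aperm(dA, c(1L, 2L, 4L, 3L))
  for (b in rev(seq_len(cfg$n_conv_blocks))) {
    ch <- caches$blocks[[b]]
    dA <- switch(cfg$norm,
      lrn = lrn_backward(dA, ch$norm),
      batch = {
        bb <- batchnorm_backward(dA, ch$norm)
        grads[[paste0("bn", b)]] <- list(gamma = bb$dgamma, beta = bb$dbeta)
        bb$dA
      },
      none = dA)
    dA <- maxpool_backward(dA, ch$pool)
    dA <- relu_backward(dA, ch$relu)
    cvb <- conv_backward(dA, list(in_dim = ch$conv$in_dim, X = ch$conv_X),
                         model$params[[paste0("conv", b)]]$W)
    grads[[paste0("conv", b)]] <- list(W = cvb$dW, b = cvb$db)
    dA <- cvb$dA
  }
  grads
}

#' Mean cross-entropy loss
#'
#' The training objective: the mean over samples of the negative log
#' probability assigned to the true class,
#' `L_c = -(1/|C|) * sum_i ln p(D_i | C_i)`. Probabilities are floored at
#' `eps` for numerical safety.
#'
#' @param predicted_probs Numeric matrix, one row per sample, one column per
#'   class; rows must be nonnegative and sum to 1 (within 1e-3).
#' @param labels True classes: integer indices (1-based), or a factor whose
#'   levels match the columns.
#' @param eps Probability floor (default 1e-12).
#' @return The scalar loss.
#' @export
cross_entropy_loss <- function(predicted_probs, labels, eps = 1e-12) {
  p <- as.matrix(predicted_probs)
  if (is.factor(labels)) labels <- as.integer(labels)
  labels <- as.integer(labels)
  if (length(labels) != nrow(p)) {
    stop_invalid("`labels` must have one entry per row of `predicted_probs`.")
  }
  if (any(labels < 1L) || any(labels > ncol(p))) {
    stop_invalid("label index out of range.")
  }
  if (any(p < -1e-9) || any(abs(rowSums(p) - 1) > 1e-3)) {
    stop_invalid("each row of `predicted_probs` must be a probability vector.")
  }
  mean(-log(pmax(p[cbind(seq_len(nrow(p)), labels)], eps)))
}

#' One stochastic-gradient-descent update
#'
#' Applies the update
#' `theta(p+1) = theta(p) - gamma * grad + momentum * delta(p)
#'  - decay * gamma * theta(p)`,
#' where `delta(p)` is the previously applied step (classical momentum). The
#' returned `velocity` is the step just applied.
#'
#' @param theta Parameters: a numeric vector/matrix/array or a (nested) list
#'   of them.
#' @param gradient Gradient of the loss, same shape as `theta`.
#' @param lr Learning rate `gamma`.
#' @param momentum Momentum rate (default 0).
#' @param weight_decay Weight-decay rate (default 0).
#' @param velocity Previously applied step, same shape as `theta`; `NULL`
#'   means zero.
#' @return `list(theta = updated parameters, velocity = applied step)`.
#' @export
sgd_update <- function(theta, gradient, lr, momentum = 0, weight_decay = 0,
                       velocity = NULL) {
  if (is.list(theta)) {
    if (!is.list(gradient) || !identical(names(theta), names(gradient))) {
      stop_invalid("`gradient` must mirror the structure of `theta`.")
    }
    out <- purrr::map(seq_along(theta), function(i) {
      sgd_update(theta[[i]], gradient[[i]], lr, momentum, weight_decay,
                 if (is.null(velocity)) NULL else velocity[[i]])
    })
    names(out) <- names(theta)
    return(list(theta = purrr::map(out, "theta"),
                velocity = purrr::map(out, "velocity")))
  }
  if (!identical(dim(theta), dim(gradient)) ||
      length(theta) != length(gradient)) {
    stop_invalid("`theta` and `gradient` shapes do not match.")
  }
  if (is.null(velocity)) velocity <- theta * 0
  step <- -lr * gradient + momentum * velocity - weight_decay * lr * theta
  list(theta = theta + step, velocity = step)
}

# Effective learning rate at 1-based epoch e under the step-down policy.
effective_lr <- function(config, epoch) {
  config$learning_rate * config$lr_gamma^((epoch - 1L) %/% config$lr_step)
}

#' Train the patch classifier
#'
#' Runs mini-batch SGD (see [sgd_update()]) with the step-down learning-rate
#' policy on the training split of a patch set, evaluating accuracy on the
#' validation split after each epoch. When `spec$augment` is `TRUE` the
#' training split is expanded with the 8 dihedral variants of each patch;
#' validation patches are never augmented. Input windows are scaled to [0,1]
#' and centered by per-channel means computed from the training split.
#' Training is deterministic given `config$seed`.
#'
#' @param model An untrained [build_lesion_cnn()] model.
#' @param patches A patch tibble with a `split` column (see
#'   [split_patches()]).
#' @param config A [training_config()].
#' @param spec The [patch_spec()] used to build `patches` (controls
#'   augmentation).
#' @param verbose Print per-epoch progress.
#' @return The trained `lesion_cnn`, with `$history` a tibble of
#'   `epoch, lr, train_loss, val_accuracy`.
#' @export
fit_lesion_cnn <- function(model, patches, config = training_config(),
                           spec = patch_spec(), verbose = FALSE) {
  stopifnot(inherits(model, "lesion_cnn"), inherits(config, "training_config"))
  if (!"split" %in% names(patches)) {
    stop_invalid("`patches` must carry a `split` column; see split_patches().")
  }
  train <- patches[patches$split == "train", ]
  val <- patches[patches$split == "validation", ]
  if (nrow(train) == 0L || nrow(val) == 0L) {
    stop_invalid("training and validation splits must both be nonempty.")
  }
  if (spec$augment) train <- augment_patches(train)
  cfg <- model$config
  s <- cfg$input_side
  bad <- vapply(train$window, function(w) dim(w)[1] != s || dim(w)[2] != s, TRUE)
  if (any(bad)) stop_invalid("patch windows do not match the network input side.")

  # Per-channel means of the training split, on the [0,1] scale.
  ch_sums <- numeric(cfg$n_channels)
  for (w in train$window) {
    for (c in seq_len(cfg$n_channels)) ch_sums[c] <- ch_sums[c] + mean(w[, , c])
  }
  model$input_stats <- list(channel_means = ch_sums / nrow(train) / 255)

  y_train <- as.integer(train$label)
  n_train <- nrow(train)
  velocity <- NULL
  history <- vector("list", config$max_epochs)

  withr::with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      lr <- effective_lr(config, epoch)
      ord <- sample.int(n_train)
      losses <- numeric(0)
      for (start in seq.int(1L, n_train, by = config$train_batch)) {
        idx <- ord[start:min(start + config$train_batch - 1L, n_train)]
        A <- stack_windows(train$window[idx], s, cfg$n_channels)
        fwd <- cnn_forward(model, A, training = TRUE, keep_caches = TRUE)
        model <- fwd$model # batch-norm running stats
        yb <- y_train[idx]
        loss <- cross_entropy_loss(fwd$probs, yb)
        if (!is.finite(loss)) {
          abort(sprintf("non-finite loss at epoch %d (lr %.4g, batch of %d); training aborted.",
                        epoch, lr, length(idx)))
        }
        losses <- c(losses, loss)
        Y <- matrix(0, length(idx), cfg$n_classes)
        Y[cbind(seq_along(idx), yb)] <- 1
        grads <- cnn_backward(model, fwd$caches, Y)
        grads <- grads[names(model$params)]
        upd <- sgd_update(model$params, grads, lr, config$momentum,
                          config$weight_decay, velocity)
        model$params <- upd$theta
        velocity <- upd$velocity
      }
      val_pred <- predict_patch_probs(model, val$window,
                                      batch_size = config$eval_batch)
      val_acc <- mean(max.col(val_pred, ties.method = "first") ==
                        as.integer(val$label))
      history[[epoch]] <- tibble(epoch = epoch, lr = lr,
                                 train_loss = mean(losses),
                                 val_accuracy = val_acc)
      if (verbose) {
        message(sprintf("epoch %3d  lr %.4g  loss %.4f  val acc %.3f",
                        epoch, lr, mean(losses), val_acc))
      }
    }
  })
  model$history <- dplyr::bind_rows(history)
  model
}

#' Class probabilities for a batch of windows
#'
#' @param model A `lesion_cnn`.
#' @param windows List of raw `S x S (x C)` windows (0-255 scale).
#' @param batch_size Windows per forward pass.
#' @return Matrix, one row per window, columns named by class.
#' @export
predict_patch_probs <- function(model, windows, batch_size = 256L) {
  stopifnot(inherits(model, "lesion_cnn"))
  cfg <- model$config
  out <- matrix(NA_real_, length(windows), cfg$n_classes)
  for (start in seq.int(1L, length(windows), by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, length(windows))
    A <- stack_windows(windows[idx], cfg$input_side, cfg$n_channels)
    out[idx, ] <- cnn_forward(model, A, training = FALSE)$probs
  }
  colnames(out) <- dr_classes()
  out
}

#' Classify a single patch
#'
#' Softmax membership probabilities of one `S x S` window for the four
#' classes; dropout is inactive, so repeated calls are identical.
#'
#' @param model A `lesion_cnn`.
#' @param patch Raw `S x S (x C)` window on the 0-255 scale.
#' @return Named numeric vector of 4 probabilities summing to 1.
#' @export
predict_patch <- function(model, patch) {
  stopifnot(inherits(model, "lesion_cnn"))
  if (is.matrix(patch)) dim(patch) <- c(dim(patch), 1L)
  d <- dim(patch)
  if (d[1] != model$config$input_side || d[2] != model$config$input_side ||
      d[3] != model$config$n_channels) {
    stop_invalid(sprintf("patch must be %d x %d x %d.",
                         model$config$input_side, model$config$input_side,
                         model$config$n_channels))
  }
  drop(predict_patch_probs(model, list(patch)))
}

#' @export
tidy.lesion_cnn <- function(x, ...) {
  if (is.null(x$history)) {
    return(tibble(epoch = integer(), lr = double(), train_loss = double(),
                  val_accuracy = double()))
  }
  x$history
}

#' @export
glance.lesion_cnn <- function(x, ...) {
  cfg <- x$config
  tibble(
    n_conv_blocks = cfg$n_conv_blocks, feature_maps = cfg$feature_maps,
    fc_units = cfg$fc_units, dropout_rate = cfg$dropout_rate,
    norm = cfg$norm, input_side = cfg$input_side,
    n_parameters = sum(vapply(rapply(x$params, length, how = "unlist"),
                              identity, numeric(1))),
    epochs_trained = if (is.null(x$history)) 0L else nrow(x$history),
    final_val_accuracy = if (is.null(x$history)) NA_real_ else
      tail(x$history$val_accuracy, 1L)
  )
}

#' @export
autoplot.lesion_cnn <- function(object, ...) {
  h <- tidy(object)
  long <- tidyr::pivot_longer(h, c("train_loss", "val_accuracy"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = "Training loss and validation accuracy by epoch")
}

#' Save / load a trained model checkpoint
#'
#' The checkpoint is a single RDS file embedding parameters, configuration,
#' input statistics and training history.
#'
#' @param model A `lesion_cnn`.
#' @param path Checkpoint file path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "lesion_cnn"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "lesion_cnn")) stop_invalid("not a lesion_cnn checkpoint.")
  model
}
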