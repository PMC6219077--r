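# Layer primitives for the patch classifier.
#
# Activations are stored as 4-d arrays with dimensions (H, W, batch, channel):
# with R's column-major order, an (H, W, batch) block for one channel is
# contiguous. The convolution and pooling kernels are compiled
# (src/cnn_kernels.cpp, im2col + BLAS GEMM); normalization and the dense head
# stay in R where matrix algebra already dominates.

# --- convolution (3x3, stride 1, zero same-padding) -------------------------

# Weights are a (9 * C_in) x F matrix; row order is offset-major:
# rows [(k-1)*C_in + c] for offset k in 1..9, channel c.
conv_forward <- function(A, W, b) {
  d <- dim(A)
  res <- cpp_conv_forward(A, d, W, b)
  list(out = res$out, X = res$X, in_dim = d)
}

conv_backward <- function(dY, cache, W) {
  d <- cache$in_dim
  f <- dim(dY)[4]
  dim(dY) <- c(prod(d[1:3]), f)
  res <- cpp_conv_backward(dY, cache$X, W, d)
  list(dA = res$dA, dW = res$dW, db = as.numeric(res$db))
}

# --- ReLU -------------------------------------------------------------------

relu_forward <- function(A) list(out = pmax(A, 0), A = A)
relu_backward <- function(dY, cache) dY * (cache$A > 0)

# --- max pooling (2x2, stride 2, floor on odd sides, no padding) ------------

maxpool_forward <- function(A) {
  res <- cpp_maxpool_forward(A, dim(A))
  list(out = res$out, which = res$which, in_dim = dim(A))
}

maxpool_backward <- function(dY, cache) {
  cpp_maxpool_backward(dY, cache$which, cache$in_dim)
}

# --- local response normalization (across channels) -------------------------
#
# b_i = a_i / (k + (alpha/n) * sum_{j in window(i)} a_j^2)^beta with the
# conventional defaults n = 5, alpha = 1e-4, beta = 0.75, k = 1. The window
# sum over channels is a product with a banded 0/1 matrix, so both passes are
# single GEMMs on the flattened activations.

lrn_band <- function(C, n) {
  half <- (n - 1L) %/% 2L
  outer(seq_len(C), seq_len(C), function(i, j) as.numeric(abs(i - j) <= half))
}

lrn_forward <- function(A, n = 5L, alpha = 1e-4, beta = 0.75, k = 1) {
  d <- dim(A)
  C <- d[4]
  M <- A
  dim(M) <- c(prod(d[1:3]), C)
  band <- lrn_band(C, n)
  S <- k + (alpha / n) * ((M * M) %*% band)
  Spow <- S^(-beta)
  out <- M * Spow
  dim(out) <- d
  list(out = out, M = M, S = S, Spow = Spow, band = band,
       n = n, alpha = alpha, beta = beta, dims = d)
}

lrn_backward <- function(dY, cache) {
  d <- cache$dims
  G <- dY
  dim(G) <- dim(cache$M)
  Tm <- G * (cache$M * cache$Spow) / cache$S # g_i * b_i / s_i
  dA <- G * cache$Spow -
    2 * cache$beta * (cache$alpha / cache$n) * cache$M * (Tm %*% cache$band)
  dim(dA) <- d
  dA
}

# --- batch normalization (per channel; optional alternative to LRN) ---------

# Channels occupy the last dimension, so per-channel statistics are column
# operations on the flattened (H*W*B) x C view — no per-channel loops.
batchnorm_forward <- function(A, gamma, beta_p, running, training,
                              momentum = 0.9, eps = 1e-5) {
  d <- dim(A)
  C <- d[4]
  M <- A
  dim(M) <- c(prod(d[1:3]), C)
  if (training) {
    mean_c <- colMeans(M)
    var_c <- colMeans(sweep(M, 2L, mean_c)^2)
    running$mean <- momentum * running$mean + (1 - momentum) * mean_c
    running$var <- momentum * running$var + (1 - momentum) * var_c
  } else {
    mean_c <- running$mean
    var_c <- running$var
  }
  inv_sd <- 1 / sqrt(var_c + eps)
  xhat <- sweep(sweep(M, 2L, mean_c), 2L, inv_sd, "*")
  out <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta_p, "+")
  dim(out) <- d
  list(out = out, xhat = xhat, var = var_c, eps = eps,
       gamma = gamma, running = running, dims = d)
}

batchnorm_backward <- function(dY, cache) {
  d <- cache$dims
  G <- dY
  dim(G) <- dim(cache$xhat)
  dgamma <- colSums(G * cache$xhat)
  dbeta <- colSums(G)
  dxh <- sweep(G, 2L, cache$gamma, "*")
  inv_sd <- 1 / sqrt(cache$var + cache$eps)
  dA <- sweep(dxh, 2L, colMeans(dxh)) -
    sweep(cache$xhat, 2L, colMeans(dxh * cache$xhat), "*")
  dA <- sweep(dA, 2L, inv_sd, "*")
  dim(dA) <- d
  list(dA = dA, dgamma = dgamma, dbeta = dbeta)
}

# --- fully connected / dropout / softmax ------------------------------------

fc_forward <- function(Z, W, b) {
  list(out = W %*% Z + b, Z = Z)
}

fc_backward <- function(dY, cache, W) {
  list(dZ = crossprod(W, dY), dW = tcrossprod(dY, cache$Z),
       db = rowSums(dY))
}

# Inverted dropout: activations are rescaled at training time so inference is
# a plain forward pass.
dropout_forward <- function(Z, rate, training) {
  if (!training || rate <= 0) {
    return(list(out = Z, mask = NULL))
  }
  keep <- 1 - rate
  mask <- (matrix(runif(length(Z)), nrow(Z)) < keep) / keep
  list(out = Z * mask, mask = mask)
}

dropout_backward <- function(dY, cache) {
  if (is.null(cache$mask)) dY else dY * cache$mask
}

softmax_columns <- function(logits) {
  m <- apply(logits, 2L, max)
  e <- exp(sweep(logits, 2L, m))
  sweep(e, 2L, colSums(e), "/")
}
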