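# Minimal 1-D deep-learning primitives on base-R BLAS matrix operations.
#
# The conv -> batchnorm -> ReLU -> maxpool backbone stage used by the model
# lives in the compiled kernels (src/nn_kernels.cpp); the plain-R layer
# functions below serve the remaining layers (attention, dense, dropout)
# and double as an independent reference implementation against which the
# compiled stage is checked in the tests.
#
# A batch of B waveform feature maps with C channels and L time steps is
# stored as a single C x (L*B) matrix whose columns are grouped by sample
# (time runs fastest). Convolutions stack the K time-shifted copies of the
# zero-padded input into a (C*K) x (L*B) matrix so that the whole layer is
# one dgemm against the (Cout x C*K) stacked kernel; batch normalization,
# ReLU, pooling and attention are plain vectorized matrix ops. Gradients
# are validated against numerical differentiation in the test suite.

# column indices of the valid (unpadded) positions in the padded layout
conv_pad_index <- function(L, B, half) {
  Lp <- L + 2L * half
  rep(seq(0L, by = Lp, length.out = B), each = L) + seq_len(L) + half
}

conv1d_forward <- function(x, L, B, Wstk, cin, K) {
  half <- (K - 1L) %/% 2L
  valid <- conv_pad_index(L, B, half)
  Xp <- matrix(0, cin, (L + 2L * half) * B)
  Xp[, valid] <- x
  Xstk <- matrix(0, cin * K, L * B)
  for (k in seq_len(K)) {
    Xstk[((k - 1L) * cin + 1L):(k * cin), ] <- Xp[, valid + (k - 1L - half)]
  }
  list(out = Wstk %*% Xstk, cache = Xstk)
}

conv1d_backward <- function(cache_Xstk, L, B, Wstk, cin, K, dy) {
  half <- (K - 1L) %/% 2L
  valid <- conv_pad_index(L, B, half)
  dW <- tcrossprod(dy, cache_Xstk)
  dXstk <- crossprod(Wstk, dy)
  dXp <- matrix(0, cin, (L + 2L * half) * B)
  for (k in seq_len(K)) {
    cols <- valid + (k - 1L - half)
    dXp[, cols] <- dXp[, cols] + dXstk[((k - 1L) * cin + 1L):(k * cin), ]
  }
  list(dx = dXp[, valid, drop = FALSE], dW = dW)
}

bn_forward <- function(x, gamma, beta, state, training,
                       momentum = 0.1, eps = 1e-5) {
  m <- ncol(x)
  if (training) {
    mu <- rowMeans(x)
    xc <- x - mu
    v <- rowMeans(xc * xc)
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var +
      momentum * v * m / max(1, m - 1)
  } else {
    mu <- state$mean
    v <- state$var
    xc <- x - mu
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- xc * invstd
  list(out = gamma * xhat + beta,
       cache = list(xhat = xhat, invstd = invstd, gamma = gamma),
       state = state)
}

bn_backward <- function(cache, dy) {
  dgamma <- rowSums(dy * cache$xhat)
  dbeta <- rowSums(dy)
  dxhat <- dy * cache$gamma
  dx <- cache$invstd *
    (dxhat - rowMeans(dxhat) - cache$xhat * rowMeans(dxhat * cache$xhat))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

maxpool_index <- function(L, B) {
  L2 <- L %/% 2L
  base <- rep(seq(0L, by = L, length.out = B), each = L2)
  a <- base + rep(seq(1L, 2L * L2, by = 2L), B)
  list(L2 = L2, a = a, b = a + 1L)
}

maxpool_forward <- function(x, L, B) {
  ix <- maxpool_index(L, B)
  a <- x[, ix$a, drop = FALSE]
  b <- x[, ix$b, drop = FALSE]
  d <- a - b
  mask <- (d >= 0) * 1  # ties resolve to the earlier sample, deterministically
  list(out = b + d * mask,
       cache = list(mask = mask, ix = ix, L = L, B = B))
}

maxpool_backward <- function(cache, dy) {
  dx <- matrix(0, nrow(dy), cache$L * cache$B)
  da <- dy * cache$mask
  dx[, cache$ix$a] <- da
  dx[, cache$ix$b] <- dy - da
  dx
}

attention_forward <- function(x, L, B, Wa, ba) {
  C <- nrow(x)
  grp <- rep(seq_len(B), each = L)
  g_avg <- t(rowsum(t(x), grp, reorder = FALSE)) / L
  dimnames(g_avg) <- NULL
  g_max <- matrix(0, C, B)
  amax <- matrix(0L, C, B)
  for (b in seq_len(B)) {
    xb <- x[, (b - 1L) * L + seq_len(L), drop = FALSE]
    idx <- max.col(xb, ties.method = "first")
    amax[, b] <- idx
    g_max[, b] <- xb[cbind(seq_len(C), idx)]
  }
  G <- rbind(g_avg, g_max)
  A <- 1 / (1 + exp(-(Wa %*% G + ba)))
  acol <- A[, grp, drop = FALSE]
  list(out = x * acol,
       cache = list(x = x, A = A, acol = acol, G = G, amax = amax,
                    L = L, B = B))
}

attention_backward <- function(cache, dy, Wa) {
  L <- cache$L
  B <- cache$B
  C <- nrow(dy)
  grp <- rep(seq_len(B), each = L)
  dx <- dy * cache$acol
  dA <- t(rowsum(t(dy * cache$x), grp, reorder = FALSE))
  dimnames(dA) <- NULL
  dpre <- dA * cache$A * (1 - cache$A)
  dWa <- tcrossprod(dpre, cache$G)
  dba <- rowSums(dpre)
  dG <- crossprod(Wa, dpre)
  davg <- dG[seq_len(C), , drop = FALSE] / L
  dmax <- dG[C + seq_len(C), , drop = FALSE]
  dx <- dx + davg[, grp, drop = FALSE]
  for (b in seq_len(B)) {
    at <- cbind(seq_len(C), (b - 1L) * L + cache$amax[, b])
    dx[at] <- dx[at] + dmax[, b]
  }
  list(dx = dx, dWa = dWa, dba = dba)
}

dense_forward <- function(x, W, b) list(out = W %*% x + b, cache = x)

dense_backward <- function(cache, W, dy) {
  list(dx = crossprod(W, dy), dW = tcrossprod(dy, cache), db = rowSums(dy))
}

# Inverted dropout; draws the mask from the caller's RNG stream so that a
# seeded training run is bit-reproducible.
dropout_forward <- function(x, p, training) {
  if (!training || p <= 0) return(list(out = x, mask = NULL))
  mask <- (matrix(stats::runif(length(x)), nrow(x)) >= p) / (1 - p)
  list(out = x * mask, mask = mask)
}

softmax_probs <- function(logits) {
  m <- apply(logits, 2, max)
  e <- exp(logits - rep(m, each = nrow(logits)))
  e / rep(colSums(e), each = nrow(logits))
}

# mean cross-entropy over the batch; labels are 0-based class codes
cross_entropy <- function(probs, labels) {
  idx <- cbind(labels + 1L, seq_len(ncol(probs)))
  -mean(log(pmax(probs[idx], 1e-12)))
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, opt, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}
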