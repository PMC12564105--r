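# Preprocessing: zero-phase band-pass filtering, epoching, FastICA
# decomposition and reconstruction with excluded components.

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a 4th-order Butterworth band-pass forward and backward
#' (`signal::filtfilt`), i.e. zero phase, so evoked-response latencies are
#' not distorted. MEG and magnetic reference channels are filtered; the
#' trigger line is passed through untouched.
#'
#' @param rec a [recording()].
#' @param low,high band edges in Hz, `0 < low < high < sampling_rate / 2`.
#' @return a filtered [recording()] of the same shape.
#' @export
bandpass_filter <- function(rec, low = 1.5, high = 40) {
  if (!inherits(rec, "recording")) stop("`rec` must be a recording",
                                        call. = FALSE)
  fs <- rec$sampling_rate
  if (!(low > 0 && low < high && high < fs / 2)) {
    stop("band edges must satisfy 0 < low < high < sampling_rate/2",
         call. = FALSE)
  }
  bf <- signal::butter(4, c(low, high) / (fs / 2), type = "pass")
  out <- rec$data
  for (i in which(rec$channel_roles != "TRIGGER")) {
    out[i, ] <- signal::filtfilt(bf, rec$data[i, ])
  }
  recording(out, fs, rec$channel_roles)
}

#' Segment a recording into consecutive non-overlapping epochs
#'
#' @param rec a [recording()].
#' @param epoch_seconds epoch length in seconds (default 10 s, i.e. 10,000
#'   samples at 1000 Hz). A trailing partial epoch is discarded.
#' @return an object of class `epoch_set`: list of channels x samples
#'   matrices plus sampling rate, epoch length and channel roles.
#' @export
segment_epochs <- function(rec, epoch_seconds = 10) {
  if (!inherits(rec, "recording")) stop("`rec` must be a recording",
                                        call. = FALSE)
  len <- round(epoch_seconds * rec$sampling_rate)
  n_epochs <- ncol(rec$data) %/% len
  if (n_epochs < 1) {
    stop("recording shorter than one epoch", call. = FALSE)
  }
  epochs <- lapply(seq_len(n_epochs), function(k) {
    rec$data[, ((k - 1) * len + 1):(k * len), drop = FALSE]
  })
  structure(list(epochs = epochs, sampling_rate = rec$sampling_rate,
                 epoch_length = len, channel_roles = rec$channel_roles),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs of %d channels x %d samples\n",
              length(x$epochs), nrow(x$epochs[[1]]), x$epoch_length))
  invisible(x)
}

# Symmetric FastICA with the logcosh (tanh) contrast. X: channels x samples.
# Returns NULL if the fixed-point iteration did not converge.
fastica_once <- function(X, n_comp, seed, max_iter = 300, tol = 1e-4) {
  n <- ncol(X)
  m <- rowMeans(X)
  Xc <- X - m
  covm <- tcrossprod(Xc) / n
  eg <- eigen(covm, symmetric = TRUE)
  d <- eg$values[seq_len(n_comp)]
  if (any(d <= .Machine$double.eps * max(eg$values) * nrow(X))) {
    stop("input is rank-deficient for the requested number of components",
         call. = FALSE)
  }
  K <- diag(1 / sqrt(d), n_comp) %*% t(eg$vectors[, seq_len(n_comp),
                                                  drop = FALSE])
  Z <- K %*% Xc

  sym_decorrelate <- function(W) {
    sw <- eigen(tcrossprod(W), symmetric = TRUE)
    sw$vectors %*% diag(1 / sqrt(pmax(sw$values, 1e-12)), n_comp) %*%
      t(sw$vectors) %*% W
  }

  W <- with_seed(seed, matrix(stats::rnorm(n_comp^2), n_comp))
  W <- sym_decorrelate(W)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    G <- tanh(W %*% Z)
    W1 <- tcrossprod(G, Z) / n - (1 - rowMeans(G * G)) * W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) return(NULL)

  unmixing <- W %*% K
  # pseudo-inverse of the whitening map restricted to the retained subspace
  K_pinv <- eg$vectors[, seq_len(n_comp), drop = FALSE] %*% diag(sqrt(d),
                                                                 n_comp)
  mixing <- K_pinv %*% t(W)
  sources <- unmixing %*% Xc
  # unit-variance source convention: scale absorbed into mixing columns
  sds <- apply(sources, 1, stats::sd)
  sources <- sources / sds
  mixing <- mixing * rep(sds, each = nrow(mixing))
  unmixing <- unmixing / sds
  list(unmixing = unmixing, mixing = mixing, sources = sources,
       channel_mean = m, n_components = n_comp, seed = seed,
       n_iter = iter, converged = TRUE)
}

#' FastICA decomposition of one epoch
#'
#' Symmetric FastICA (logcosh contrast) on a channels x samples matrix of
#' MEG channels. Sources follow the unit-variance convention with the scale
#' absorbed into the mixing columns, so downstream thresholds and network
#' inputs are scale-free. Component order is arbitrary. If the fixed-point
#' iteration does not converge, the fit is retried with seeds `seed + 1` and
#' `seed + 2` before raising an error.
#'
#' @param epoch numeric matrix, MEG channels x samples.
#' @param n_components number of components (default: number of channels,
#'   which makes the decomposition exactly invertible).
#' @param seed integer seed for the random initial unmixing matrix.
#' @param max_iter,tol fixed-point iteration controls.
#' @return an object of class `ica_decomposition` with elements `unmixing`
#'   (components x channels), `mixing` (channels x components), `sources`
#'   (components x samples, unit variance), `channel_mean`, `n_components`,
#'   `seed`, `n_iter`, `converged`.
#' @export
ica_decompose <- function(epoch, n_components = nrow(epoch), seed = 1,
                          max_iter = 300, tol = 1e-4) {
  if (!is.matrix(epoch) || !is.numeric(epoch)) {
    stop("`epoch` must be a numeric channels x samples matrix", call. = FALSE)
  }
  if (n_components > nrow(epoch)) {
    stop("n_components must not exceed the number of channels", call. = FALSE)
  }
  for (s in seed + 0:2) {
    fit <- fastica_once(epoch, n_components, s, max_iter, tol)
    if (!is.null(fit)) {
      fit$seed <- s
      class(fit) <- "ica_decomposition"
      return(fit)
    }
  }
  stop(sprintf(
    "FastICA did not converge within %d iterations for seeds %d..%d",
    max_iter, seed, seed + 2), call. = FALSE)
}

#' @export
print.ica_decomposition <- function(x, ...) {
  cat(sprintf("<ica_decomposition> %d components x %d samples (seed %d, %d iterations)\n",
              x$n_components, ncol(x$sources), x$seed, x$n_iter))
  invisible(x)
}

#' Reconstruct an epoch from an ICA decomposition, excluding components
#'
#' @param decomposition an `ica_decomposition`.
#' @param exclude integer vector of component indices (1-based) whose rows
#'   are zeroed before mixing back; empty for a plain round trip.
#' @return channels x samples matrix `mixing %*% sources + channel_mean`
#'   with the excluded source rows set to zero.
#' @export
ica_reconstruct <- function(decomposition, exclude = integer(0)) {
  if (!inherits(decomposition, "ica_decomposition")) {
    stop("`decomposition` must come from ica_decompose()", call. = FALSE)
  }
  exclude <- as.integer(exclude)
  if (length(exclude) &&
      (any(exclude < 1L) || any(exclude > decomposition$n_components))) {
    stop("`exclude` contains out-of-range component indices", call. = FALSE)
  }
  S <- decomposition$sources
  if (length(exclude)) S[exclude, ] <- 0
  decomposition$mixing %*% S + decomposition$channel_mean
}
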