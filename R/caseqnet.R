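# CA-SeqNet: a channel-attention 1-D convolutional classifier for ICA
# component waveforms. Architecture: seven CBR units (Conv1d kernel 3 with
# same padding -> BatchNorm1d -> ReLU) each followed by max-pooling of 2,
# then a channel-attention gate fusing global average and global max pooled
# channel descriptors, two FRD units (fully connected -> ReLU -> dropout),
# and a final linear + softmax over the three classes
# {0 cardiac, 1 blink, 2 none}.

#' CA-SeqNet architecture configuration
#'
#' The default backbone carries the seven convolutions of the first three
#' blocks of the classic VGG16 network (widths 64, 64, 128, 128, 256, 256,
#' 256), each wrapped into a CBR unit and followed by a max-pool of 2.
#'
#' @param input_length waveform length in samples.
#' @param conv_channels output channels of the seven convolution stages.
#' @param kernel_size convolution kernel taps (odd, same padding).
#' @param pool_size temporal max-pool factor after each CBR unit.
#' @param frd_hidden hidden widths of the two FRD units.
#' @param dropout_rate dropout probability inside the FRD units.
#' @param n_classes number of output classes (3).
#' @return a list of class `ca_seqnet_config`.
#' @export
ca_seqnet_config <- function(input_length = 10000,
                             conv_channels = c(64, 64, 128, 128, 256, 256, 256),
                             kernel_size = 3,
                             pool_size = 2,
                             frd_hidden = c(256, 64),
                             dropout_rate = 0.5,
                             n_classes = 3) {
  if (length(conv_channels) != 7) {
    stop("the backbone uses exactly seven convolution stages", call. = FALSE)
  }
  if (n_classes != 3) stop("n_classes must be 3", call. = FALSE)
  if (kernel_size %% 2 != 1) stop("kernel_size must be odd", call. = FALSE)
  if (pool_size != 2) stop("only pool_size = 2 is supported", call. = FALSE)
  L <- input_length
  lens <- integer(7)
  for (i in 1:7) {
    L <- L %/% pool_size
    lens[i] <- L
  }
  if (L < 1) stop("input_length too short for seven pooling stages",
                  call. = FALSE)
  structure(list(input_length = as.integer(input_length),
                 conv_channels = as.integer(conv_channels),
                 kernel_size = as.integer(kernel_size),
                 pool_size = as.integer(pool_size),
                 frd_hidden = as.integer(frd_hidden),
                 dropout_rate = dropout_rate,
                 n_classes = as.integer(n_classes),
                 stage_lengths = lens,
                 flat_dim = as.integer(conv_channels[7] * L)),
            class = "ca_seqnet_config")
}

# fan-in-scaled uniform initialization, U(-1/sqrt(fan_in), +1/sqrt(fan_in))
init_uniform <- function(dims, fan_in) {
  bound <- 1 / sqrt(fan_in)
  array(stats::runif(prod(dims), -bound, bound), dims)
}

#' Initialize an untrained CA-SeqNet model
#'
#' Weights use fan-in-scaled uniform initialization drawn from the seeded
#' generator; batch-norm scales start at 1 with zero shift and unit running
#' variance.
#'
#' @param config a [ca_seqnet_config()].
#' @param seed integer seed for the weight draws.
#' @return a list of class `ca_seqnet` with elements `config`, `params`,
#'   `bn_state`, `seed` and (after training) `history`.
#' @export
ca_seqnet_init <- function(config = ca_seqnet_config(), seed = 42) {
  cc <- config$conv_channels
  K <- config$kernel_size
  params <- with_seed(seed, {
    p <- list()
    cin <- 1L
    for (i in 1:7) {
      # stacked kernel: (Cout x Cin*K), tap-major blocks of Cin columns
      p[[paste0("conv", i)]] <- init_uniform(c(cc[i], cin * K), cin * K)
      p[[paste0("bn_gamma", i)]] <- rep(1, cc[i])
      p[[paste0("bn_beta", i)]] <- rep(0, cc[i])
      cin <- cc[i]
    }
    C <- cc[7]
    p$att_W <- init_uniform(c(C, 2 * C), 2 * C)
    p$att_b <- rep(0, C)
    dims <- c(config$flat_dim, config$frd_hidden, config$n_classes)
    for (j in 1:3) {
      p[[paste0("fc", j, "_W")]] <- init_uniform(c(dims[j + 1], dims[j]),
                                                 dims[j])
      p[[paste0("fc", j, "_b")]] <- rep(0, dims[j + 1])
    }
    p
  })
  bn_state <- lapply(1:7, function(i) list(mean = rep(0, cc[i]),
                                           var = rep(1, cc[i])))
  structure(list(config = config, params = params, bn_state = bn_state,
                 seed = seed, history = NULL),
            class = "ca_seqnet")
}

#' @export
print.ca_seqnet <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<ca_seqnet> input %d, conv [%s], %s parameters%s\n",
              x$config$input_length,
              paste(x$config$conv_channels, collapse = ", "),
              format(n_par, big.mark = ","),
              if (is.null(x$history)) " (untrained)" else ""))
  invisible(x)
}

#' Channel attention over a feature map
#'
#' Pools each channel over time with global average and global max pooling,
#' concatenates the two descriptors, maps them back to one weight per
#' channel through a linear layer, and gates every channel by its sigmoid
#' weight (each strictly in (0, 1)).
#'
#' @param f feature map, a channels x time matrix.
#' @param W,b linear map (C x 2C) and bias (C) producing the attention
#'   pre-activations.
#' @return list with `out` (gated feature map, same shape as `f`) and
#'   `weights` (the C attention weights).
#' @export
channel_attention <- function(f, W, b) {
  res <- attention_forward(f, ncol(f), 1L, W, b)
  list(out = res$out, weights = res$cache$A[, 1])
}

# Full forward pass. x: (1 x L*B) matrix, one sample per L-column block.
# Returns logits plus layer caches (training = TRUE also applies dropout and
# batch statistics, and updates the running batch-norm state).
nn_forward <- function(model, x, B, training = FALSE) {
  p <- model$params
  cfg <- model$config
  K <- cfg$kernel_size
  caches <- list()
  h <- x
  L <- cfg$input_length
  cin <- 1L
  for (i in 1:7) {
    st <- cpp_cbr_pool_forward(h, p[[paste0("conv", i)]],
                               p[[paste0("bn_gamma", i)]],
                               p[[paste0("bn_beta", i)]],
                               model$bn_state[[i]]$mean,
                               model$bn_state[[i]]$var,
                               L, B, K, training, 0.1, 1e-5)
    if (training) {
      model$bn_state[[i]] <- list(mean = as.numeric(st$mean),
                                  var = as.numeric(st$var))
    }
    caches[[paste0("stage", i)]] <- st[c("Xstk", "xhat", "invstd", "arg")]
    h <- st$out
    L <- L %/% cfg$pool_size
    cin <- cfg$conv_channels[i]
  }
  att <- attention_forward(h, L, B, p$att_W, p$att_b)
  caches$att <- att$cache
  h <- matrix(att$out, cfg$flat_dim, B)
  for (j in 1:2) {
    fc <- dense_forward(h, p[[paste0("fc", j, "_W")]],
                        p[[paste0("fc", j, "_b")]])
    caches[[paste0("fc_in", j)]] <- fc$cache
    h <- fc$out
    mask <- (h > 0) * 1
    caches[[paste0("fc_relu", j)]] <- mask
    h <- h * mask
    dp <- dropout_forward(h, cfg$dropout_rate, training)
    caches[[paste0("drop", j)]] <- dp$mask
    h <- dp$out
  }
  fc <- dense_forward(h, p$fc3_W, p$fc3_b)
  caches$fc_in3 <- fc$cache
  list(logits = fc$out, caches = caches, model = model)
}

# Backward pass from d(logits); returns gradients named like the parameters.
nn_backward <- function(model, caches, B, dlogits) {
  p <- model$params
  cfg <- model$config
  K <- cfg$kernel_size
  g <- list()
  bk <- dense_backward(caches$fc_in3, p$fc3_W, dlogits)
  g$fc3_W <- bk$dW
  g$fc3_b <- bk$db
  dh <- bk$dx
  for (j in 2:1) {
    mask <- caches[[paste0("drop", j)]]
    if (!is.null(mask)) dh <- dh * mask
    dh <- dh * caches[[paste0("fc_relu", j)]]
    bk <- dense_backward(caches[[paste0("fc_in", j)]],
                         p[[paste0("fc", j, "_W")]], dh)
    g[[paste0("fc", j, "_W")]] <- bk$dW
    g[[paste0("fc", j, "_b")]] <- bk$db
    dh <- bk$dx
  }
  dh <- matrix(dh, cfg$conv_channels[7], cfg$stage_lengths[7] * B)
  atb <- attention_backward(caches$att, dh, p$att_W)
  g$att_W <- atb$dWa
  g$att_b <- atb$dba
  dh <- atb$dx
  for (i in 7:1) {
    L <- if (i == 1) cfg$input_length else cfg$stage_lengths[i - 1]
    st <- caches[[paste0("stage", i)]]
    bk <- cpp_cbr_pool_backward(dh, st$Xstk, p[[paste0("conv", i)]],
                                p[[paste0("bn_gamma", i)]],
                                p[[paste0("bn_beta", i)]],
                                st$xhat, st$invstd, st$arg, L, B, K)
    g[[paste0("conv", i)]] <- bk$dW
    g[[paste0("bn_gamma", i)]] <- as.numeric(bk$dgamma)
    g[[paste0("bn_beta", i)]] <- as.numeric(bk$dbeta)
    dh <- bk$dx
  }
  g
}

# waveforms: samples x length matrix -> 1 x (L*B) matrix, sample-major
as_input_matrix <- function(waveforms) {
  matrix(as.vector(t(waveforms)), nrow = 1L)
}

# loss + gradients on one mini-batch (training mode); used by the training
# loop and by the numerical gradient check in the tests
nn_loss_and_grads <- function(model, xmat, B, labels, training = TRUE) {
  fw <- nn_forward(model, xmat, B, training)
  probs <- softmax_probs(fw$logits)
  loss <- cross_entropy(probs, labels)
  onehot <- matrix(0, nrow(probs), B)
  onehot[cbind(labels + 1L, seq_len(B))] <- 1
  dlogits <- (probs - onehot) / B
  grads <- nn_backward(fw$model, fw$caches, B, dlogits)
  list(loss = loss, grads = grads, model = fw$model)
}

#' Forward pass of a CA-SeqNet model (inference mode)
#'
#' Deterministic: dropout is disabled and batch normalization uses the
#' running statistics.
#'
#' @param model a `ca_seqnet`.
#' @param waveforms numeric matrix, one waveform per row, of the configured
#'   input length; rows should be standardized (zero mean, unit variance).
#' @param batch_size internal chunk size.
#' @return matrix of class probabilities (rows = waveforms, columns =
#'   classes 0 cardiac, 1 blink, 2 none); rows sum to 1.
#' @export
ca_seqnet_forward <- function(model, waveforms, batch_size = 64) {
  if (!inherits(model, "ca_seqnet")) stop("`model` must be a ca_seqnet",
                                          call. = FALSE)
  if (is.vector(waveforms)) waveforms <- matrix(waveforms, nrow = 1)
  if (ncol(waveforms) != model$config$input_length) {
    stop(sprintf("waveforms must have %d samples, got %d",
                 model$config$input_length, ncol(waveforms)), call. = FALSE)
  }
  n <- nrow(waveforms)
  probs <- matrix(0, n, model$config$n_classes)
  for (start in seq(1, n, by = batch_size)) {
    rows <- start:min(n, start + batch_size - 1)
    fw <- nn_forward(model, as_input_matrix(waveforms[rows, , drop = FALSE]),
                     length(rows), training = FALSE)
    probs[rows, ] <- t(softmax_probs(fw$logits))
  }
  colnames(probs) <- c("cardiac", "blink", "none")
  probs
}

#' Predict class labels for waveforms
#'
#' @param model a trained `ca_seqnet`.
#' @param waveforms numeric matrix, one waveform per row (standardized
#'   internally to zero mean, unit variance).
#' @return integer labels (0 cardiac, 1 blink, 2 none).
#' @export
ca_seqnet_predict <- function(model, waveforms) {
  if (is.vector(waveforms)) waveforms <- matrix(waveforms, nrow = 1)
  probs <- ca_seqnet_forward(model, standardize_rows(waveforms))
  max.col(probs, ties.method = "first") - 1L
}

#' Training configuration
#'
#' Defaults follow the reference recipe: 100 epochs, batch size 16, Adam
#' with initial learning rate 0.001 decayed by a factor of 0.1 every 10
#' epochs, fixed seed 42 (weight initialization, batch shuffling and
#' dropout all derive from it).
#'
#' @param epochs training epochs.
#' @param batch_size mini-batch size.
#' @param lr initial learning rate.
#' @param lr_decay_factor multiplicative decay factor.
#' @param lr_decay_every epochs between decays.
#' @param seed master seed.
#' @return a list of class `train_config`.
#' @export
train_config <- function(epochs = 100, batch_size = 16, lr = 0.001,
                         lr_decay_factor = 0.1, lr_decay_every = 10,
                         seed = 42) {
  stopifnot_scalar(epochs, "epochs")
  stopifnot_scalar(batch_size, "batch_size")
  stopifnot_scalar(lr, "lr")
  stopifnot_scalar(lr_decay_factor, "lr_decay_factor")
  stopifnot_scalar(lr_decay_every, "lr_decay_every")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 lr_decay_factor = lr_decay_factor,
                 lr_decay_every = as.integer(lr_decay_every),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Train CA-SeqNet on an artifact dataset
#'
#' Minimizes the multiclass cross-entropy with Adam under the seeded,
#' single-threaded deterministic regime: two runs with the same seed and
#' data produce bit-identical histories and parameters.
#'
#' @param train an `artifact_dataset` (waveform length must match
#'   `config$input_length`).
#' @param test optional held-out `artifact_dataset`; when given, accuracy
#'   and macro-F1 are logged per epoch.
#' @param config a [ca_seqnet_config()].
#' @param tc a [train_config()].
#' @param verbose print one line per epoch.
#' @return a trained `ca_seqnet` with a `history` data.frame (epoch,
#'   learning rate, mean training loss, optional test metrics).
#' @export
ca_seqnet_train <- function(train, test = NULL,
                            config = ca_seqnet_config(),
                            tc = train_config(), verbose = FALSE) {
  if (!inherits(train, "artifact_dataset")) {
    stop("`train` must be an artifact_dataset", call. = FALSE)
  }
  if (ncol(train$waveforms) != config$input_length) {
    stop(sprintf("training waveforms have %d points but the model expects %d",
                 ncol(train$waveforms), config$input_length), call. = FALSE)
  }
  X <- standardize_rows(train$waveforms)
  y <- train$labels
  n <- nrow(X)
  model <- ca_seqnet_init(config, seed = tc$seed)
  opt <- adam_init(model$params)
  history <- vector("list", tc$epochs)
  with_seed(derive_seed(tc$seed, 97), {
    for (epoch in seq_len(tc$epochs)) {
      lr <- tc$lr * tc$lr_decay_factor^((epoch - 1) %/% tc$lr_decay_every)
      order <- sample.int(n)
      losses <- c()
      for (start in seq(1, n, by = tc$batch_size)) {
        rows <- order[start:min(n, start + tc$batch_size - 1)]
        res <- nn_loss_and_grads(model,
                                 as_input_matrix(X[rows, , drop = FALSE]),
                                 length(rows), y[rows], training = TRUE)
        if (!is.finite(res$loss)) {
          stop(sprintf(
            "non-finite training loss at epoch %d (lr %.3g); try a lower learning rate or a different seed",
            epoch, lr), call. = FALSE)
        }
        model <- res$model
        step <- adam_step(model$params, res$grads, opt, lr)
        model$params <- step$params
        opt <- step$opt
        losses <- c(losses, res$loss)
      }
      row <- data.frame(epoch = epoch, lr = lr, loss = mean(losses))
      if (!is.null(test)) {
        pred <- ca_seqnet_predict(model, test$waveforms)
        mt <- compute_metrics(test$labels, pred)
        row$test_accuracy <- mt$accuracy
        row$test_macro_f1 <- mt$macro$f1
      }
      history[[epoch]] <- row
      if (verbose) {
        cat(sprintf("epoch %3d  lr %.1e  loss %.4f%s\n", epoch, lr,
                    row$loss,
                    if (!is.null(test)) sprintf("  test acc %.2f%%  macro-F1 %.2f%%",
                                                row$test_accuracy,
                                                row$test_macro_f1) else ""))
      }
    }
  })
  model$history <- do.call(rbind, history)
  model
}

#' Classify the components of an ICA decomposition
#'
#' Resamples each source waveform to the model's input length (regular
#' decimation, see [resample_waveform()]), standardizes it, and predicts its
#' class. Components flagged cardiac (0) or blink (1) form the removal set.
#'
#' @param model a trained `ca_seqnet`.
#' @param decomposition an `ica_decomposition`.
#' @return list with `labels` (one per component) and `removal` (indices of
#'   artifact-flagged components, possibly empty).
#' @export
predict_components <- function(model, decomposition) {
  if (!inherits(decomposition, "ica_decomposition")) {
    stop("`decomposition` must come from ica_decompose()", call. = FALSE)
  }
  W <- t(apply(decomposition$sources, 1, resample_waveform,
               target_length = model$config$input_length))
  labels <- ca_seqnet_predict(model, W)
  list(labels = labels,
       removal = which(labels %in% c(CLASS_CARDIAC, CLASS_BLINK)))
}
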