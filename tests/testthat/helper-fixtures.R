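# Shared fixtures: small synthetic objects built in code, plus a memoised
# scaled-down end-to-end study reused by the acceptance tests.

# A compact session for unit tests: fewer MEG channels keeps per-epoch ICA
# fast while exercising the full channel-role contract.
small_session <- function(seed = 1, duration = 10, n_meg = 8, ...) {
  simulate_session(sim_config(n_meg_channels = n_meg, duration = duration,
                              seed = seed, ...))
}

# Three-class toy waveforms with distinct morphologies (periodic spikes /
# sparse bumps / noise), linearly separable for a small network.
toy_dataset <- function(n_per = 20, len = 256, seed = 1) {
  set.seed(seed)
  mk <- function(cls) {
    t(sapply(seq_len(n_per), function(i) {
      tt <- seq_len(len) / len
      base <- stats::rnorm(len) * 0.3
      if (cls == 0) {
        base + 2 * sin(2 * pi * 8 * tt)
      } else if (cls == 1) {
        base + 5 * exp(-((tt - stats::runif(1, 0.3, 0.7)) / 0.05)^2)
      } else {
        base
      }
    }))
  }
  waves <- rbind(mk(0), mk(1), mk(2))
  labels <- rep(c(0L, 1L, 2L), each = n_per)
  prov <- data.frame(group = seq_len(3 * n_per), inverted = FALSE)
  opmclean:::new_artifact_dataset(opmclean:::standardize_rows(waves),
                                  labels, prov)
}

toy_net_config <- function(len = 256) {
  ca_seqnet_config(input_length = len,
                   conv_channels = c(8, 8, 16, 16, 32, 32, 32),
                   frd_hidden = c(32, 16), dropout_rate = 0.3)
}

# Harvest one synthetic subject: one session -> labeled component pool.
# Subjects alternate between the natural and rapid blinking conditions.
harvest_subject <- function(subject, seed, duration = 50,
                            waveform_length = 2000) {
  mode <- if (subject %% 2 == 1) "normal" else "rapid"
  ses <- simulate_session(sim_config(duration = duration, blink_mode = mode,
                                     seed = seed))
  harvest_components(ses$recording, subject_id = subject, ica_seed = seed,
                     params = rdc_params(seed = seed),
                     waveform_length = waveform_length)
}

# The scaled-down end-to-end study: 12 synthetic subjects, balanced
# 1:1:4 dataset with inversion augmentation, 4:1 split, 20 training epochs.
# Memoised because several acceptance tests reuse the trained model.
.e2e_cache <- new.env(parent = emptyenv())
get_e2e_study <- function() {
  if (!is.null(.e2e_cache$study)) return(.e2e_cache$study)
  hs <- lapply(1:12, function(s) harvest_subject(s, 100 + s))
  waves <- do.call(rbind, lapply(hs, `[[`, "waveforms"))
  labels <- unlist(lapply(hs, `[[`, "labels"))
  prov <- do.call(rbind, lapply(hs, `[[`, "provenance"))
  ds <- augment_invert(assemble_dataset(waves, labels, prov, seed = 1))
  sp <- split_dataset(ds, seed = 2)
  model <- ca_seqnet_train(sp$train,
                           config = ca_seqnet_config(input_length = 2000),
                           tc = train_config(epochs = 20, seed = 42))
  pred <- ca_seqnet_predict(model, sp$test$waveforms)
  metrics <- compute_metrics(sp$test$labels, pred)
  .e2e_cache$study <- list(dataset = ds, split = sp, model = model,
                           metrics = metrics)
  .e2e_cache$study
}
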