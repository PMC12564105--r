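# Evaluation: multiclass classification metrics, end-to-end artifact
# removal, event-related field (ERF) averaging and pre/post-stimulus SNR.

#' Per-class F1 score from precision and recall
#'
#' `F1 = 2 * P * R / (P + R)`, the harmonic mean of precision and recall,
#' on whatever scale the inputs use (fractions or percentages). Returns 0
#' when both inputs are 0.
#'
#' @param precision,recall numeric (vectorized).
#' @return numeric F1 on the same scale.
#' @export
f1_score <- function(precision, recall) {
  denom <- precision + recall
  ifelse(denom > 0, 2 * precision * recall / denom, 0)
}

#' Multiclass classification metrics
#'
#' Builds the 3 x 3 confusion matrix (rows = true, columns = predicted) and
#' reports one-vs-rest precision, recall, F1 and accuracy per class plus the
#' macro (unweighted mean) aggregates and overall accuracy, all as
#' percentages. A zero denominator yields 0 with a warning.
#'
#' @param true,pred equal-length integer label vectors over {0, 1, 2}
#'   (0 cardiac, 1 blink, 2 none).
#' @return list of class `metrics_report` with `confusion`, `per_class`
#'   (data.frame), `macro` (list with precision, recall, f1) and `accuracy`.
#' @export
compute_metrics <- function(true, pred) {
  if (length(true) == 0 || length(true) != length(pred)) {
    stop("`true` and `pred` must be non-empty vectors of equal length",
         call. = FALSE)
  }
  classes <- c(cardiac = 0L, blink = 1L, none = 2L)
  if (!all(c(true, pred) %in% classes)) {
    stop("labels must be in {0, 1, 2}", call. = FALSE)
  }
  cm <- table(factor(true, levels = classes),
              factor(pred, levels = classes))
  cm <- matrix(as.integer(cm), 3, 3,
               dimnames = list(true = names(classes),
                               predicted = names(classes)))
  total <- sum(cm)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("zero denominator for %s; reporting 0", what),
              call. = FALSE)
      return(0)
    }
    num / den
  }
  per <- lapply(seq_along(classes), function(i) {
    tp <- cm[i, i]
    fp <- sum(cm[-i, i])
    fn <- sum(cm[i, -i])
    tn <- total - tp - fp - fn
    p <- 100 * safe_div(tp, tp + fp, paste0("precision/", names(classes)[i]))
    r <- 100 * safe_div(tp, tp + fn, paste0("recall/", names(classes)[i]))
    data.frame(class = names(classes)[i],
               precision = p, recall = r, f1 = f1_score(p, r),
               accuracy = 100 * (tp + tn) / total)
  })
  per <- do.call(rbind, per)
  structure(list(
    confusion = cm,
    per_class = per,
    macro = list(precision = mean(per$precision),
                 recall = mean(per$recall),
                 f1 = mean(per$f1)),
    accuracy = 100 * sum(diag(cm)) / total
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Confusion matrix (rows = true, cols = predicted):\n")
  print(x$confusion)
  cat("\nPer-class metrics (%):\n")
  print(x$per_class, row.names = FALSE, digits = 4)
  cat(sprintf("\nOverall accuracy %.2f%%, macro P %.2f%%, R %.2f%%, F1 %.2f%%\n",
              x$accuracy, x$macro$precision, x$macro$recall, x$macro$f1))
  invisible(x)
}

#' Remove recognized artifact components from a recording
#'
#' Runs the deployment pipeline: band-pass filter, 10-s epoching, per-epoch
#' FastICA, CA-SeqNet component classification, and reconstruction with the
#' flagged blink/cardiac components excluded. Epochs are re-concatenated;
#' the reference and trigger channels pass through the cleaning stage
#' untouched (the references are still band-pass filtered, the trigger
#' never is). The output is trimmed to a whole number of epochs.
#'
#' @param rec a [recording()].
#' @param model a trained `ca_seqnet`.
#' @param low,high band-pass edges in Hz.
#' @param epoch_seconds epoch length in seconds.
#' @param n_components ICA components per epoch (default: all MEG channels).
#' @param ica_seed seed for the per-epoch ICA fits.
#' @return list with `recording` (cleaned), `filtered` (the filtered,
#'   uncleaned recording trimmed to the same length) and `removed`
#'   (per-epoch list of flagged component indices).
#' @export
clean_recording <- function(rec, model, low = 1.5, high = 40,
                            epoch_seconds = 10, n_components = NULL,
                            ica_seed = 1) {
  filt <- bandpass_filter(rec, low, high)
  es <- segment_epochs(filt, epoch_seconds)
  meg_idx <- which(es$channel_roles == "MEG")
  if (is.null(n_components)) n_components <- length(meg_idx)
  n_keep <- length(es$epochs) * es$epoch_length
  cleaned <- filt$data[, seq_len(n_keep), drop = FALSE]
  removed <- vector("list", length(es$epochs))
  for (k in seq_along(es$epochs)) {
    dec <- tryCatch(
      ica_decompose(es$epochs[[k]][meg_idx, , drop = FALSE],
                    n_components, seed = derive_seed(ica_seed, k)),
      error = function(e) {
        warning(sprintf("epoch %d left uncleaned: %s", k,
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
    removed[[k]] <- integer(0)
    if (is.null(dec)) next
    pc <- predict_components(model, dec)
    removed[[k]] <- pc$removal
    cols <- ((k - 1) * es$epoch_length + 1):(k * es$epoch_length)
    cleaned[meg_idx, cols] <- ica_reconstruct(dec, exclude = pc$removal)
  }
  filtered <- recording(filt$data[, seq_len(n_keep), drop = FALSE],
                        filt$sampling_rate, filt$channel_roles)
  list(recording = recording(cleaned, filt$sampling_rate, filt$channel_roles),
       filtered = filtered,
       removed = removed)
}

#' Trigger onsets from the trigger channel
#'
#' @param rec a [recording()].
#' @param threshold level crossing that marks a pulse edge.
#' @return integer sample indices of rising edges.
#' @export
detect_trigger_onsets <- function(rec, threshold = 0.5) {
  trig <- channel_data(rec, "TRIGGER")
  high <- trig > threshold
  which(high & !c(FALSE, high[-length(high)]))
}

#' Event-related field by trial averaging
#'
#' Averages MEG segments time-locked to the stimulus onsets and subtracts
#' the per-channel pre-stimulus mean (baseline correction). Trials whose
#' window extends past the recording edges are dropped.
#'
#' @param rec a [recording()].
#' @param window window in seconds relative to onset, default `c(-0.2, 0.5)`.
#' @param onsets onset sample indices; `NULL` detects them from the trigger
#'   channel.
#' @return list of class `erf_waveform`: `data` (MEG channels x window
#'   samples), `times` (seconds relative to onset), `n_trials`,
#'   `sampling_rate`.
#' @export
erf_average <- function(rec, window = c(-0.2, 0.5), onsets = NULL) {
  fs <- rec$sampling_rate
  if (!(window[1] < 0 && window[2] > 0)) {
    stop("window must contain the onset (window[1] < 0 < window[2])",
         call. = FALSE)
  }
  if (is.null(onsets)) onsets <- detect_trigger_onsets(rec)
  rel <- seq(round(window[1] * fs), round(window[2] * fs))
  n <- ncol(rec$data)
  usable <- onsets[onsets + rel[1] >= 1 & onsets + rel[length(rel)] <= n]
  if (!length(usable)) stop("no trial with a full window inside the recording",
                            call. = FALSE)
  meg <- channel_data(rec, "MEG")
  acc <- matrix(0, nrow(meg), length(rel))
  for (on in usable) acc <- acc + meg[, on + rel, drop = FALSE]
  avg <- acc / length(usable)
  times <- rel / fs
  baseline <- rowMeans(avg[, times < 0, drop = FALSE])
  structure(list(data = avg - baseline, times = times,
                 n_trials = length(usable), sampling_rate = fs),
            class = "erf_waveform")
}

#' Pre/post-stimulus SNR of an ERF in dB
#'
#' `SNR = 20 log10(RMS_post / RMS_pre)` where the RMS pools all MEG channels
#' and samples: post-stimulus over onset to +0.2 s (closed at the onset
#' sample), pre-stimulus over -0.2 s to strictly before the onset.
#'
#' @param erf an `erf_waveform` whose window covers `[-0.2, 0.2]` s.
#' @return SNR in dB.
#' @export
snr_db <- function(erf) {
  if (!inherits(erf, "erf_waveform")) stop("`erf` must be an erf_waveform",
                                           call. = FALSE)
  tt <- erf$times
  tol <- 0.5 / erf$sampling_rate
  if (min(tt) > -0.2 + tol || max(tt) < 0.2 - tol) {
    stop("the ERF window must cover [-0.2, 0.2] s", call. = FALSE)
  }
  pre <- erf$data[, tt < 0 & tt >= -0.2, drop = FALSE]
  post <- erf$data[, tt >= 0 & tt <= 0.2, drop = FALSE]
  rms_pre <- rms(pre)
  if (rms_pre == 0) stop("zero pre-stimulus RMS", call. = FALSE)
  20 * log10(rms(post) / rms_pre)
}
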