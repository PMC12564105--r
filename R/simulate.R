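# Synthetic OPM-MEG sessions with ground truth.
#
# The generator emulates the acquisition paradigm the pipeline is designed
# for: an auditory oddball-free beep protocol (1 kHz tones of 200-300 ms,
# 2 s inter-stimulus interval) recorded by a 32-channel magnetometer array
# plus one ocular magnetic reference (MOG), one cardiac magnetic reference
# (MCG) and a trigger line, all sampled at 1000 Hz. Blink and cardiac
# artifact sources are mixed into the MEG array through random topographies
# so every downstream stage can be tested against known ground truth.

#' Simulation configuration
#'
#' @param n_meg_channels number of MEG magnetometer channels.
#' @param sampling_rate sampling rate in Hz.
#' @param duration session length in seconds (>= 10 so at least one 10-s
#'   epoch exists).
#' @param blink_mode `"normal"` (spontaneous blinking, ~0.2-0.5 events/s) or
#'   `"rapid"` (instructed fast blinking, 1-3 events/s).
#' @param blink_rate expected blink events per second; defaults to 0.4 for
#'   `"normal"` (~24 blinks/min, typical for seated spontaneous blinking)
#'   and 2 for `"rapid"`, and must lie inside the mode's band.
#' @param cardiac_period_range inter-beat interval range in ms, a subset of
#'   600-1200 ms (resting heart rate); successive intervals are drawn
#'   uniformly from it.
#' @param n_trials number of auditory trials; `NULL` fits as many trials as
#'   the duration allows, starting 1 s into the session.
#' @param tone_duration_range tone length range in ms.
#' @param isi inter-stimulus interval in seconds.
#' @param artifact_amplitude_scales named numeric vector with elements
#'   `blink` and `cardiac`: gain of each artifact source relative to the
#'   unit-RMS background sources. Blink fields dominate the background,
#'   cardiac fields are clearly visible.
#' @param erf_amplitude gain of the trial-locked evoked source; kept below
#'   the single-trial noise floor (the response only emerges after
#'   averaging), as in real auditory recordings.
#' @param noise_scale gain of the neural background sources.
#' @param blink_rise_ms,blink_decay_ms blink waveform rise / decay widths.
#' @param ref_noise independent noise on the reference channels as a
#'   fraction of the source RMS (references are near-source sensors, so
#'   their SNR is high).
#' @param seed master seed; all draws derive deterministically from it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_meg_channels = 32,
                       sampling_rate = 1000,
                       duration = 60,
                       blink_mode = c("normal", "rapid"),
                       blink_rate = NULL,
                       cardiac_period_range = c(900, 1000),
                       n_trials = NULL,
                       tone_duration_range = c(200, 300),
                       isi = 2,
                       artifact_amplitude_scales = c(blink = 5, cardiac = 3),
                       erf_amplitude = 0.6,
                       noise_scale = 1,
                       blink_rise_ms = 100,
                       blink_decay_ms = 200,
                       ref_noise = 0.05,
                       seed = 1) {
  blink_mode <- match.arg(blink_mode)
  band <- blink_rate_band(blink_mode)
  if (is.null(blink_rate)) {
    blink_rate <- if (blink_mode == "normal") 0.4 else 2
  }
  if (blink_rate < band[1] || blink_rate > band[2]) {
    stop(sprintf("blink_rate %.3g outside the %s band [%g, %g] events/s",
                 blink_rate, blink_mode, band[1], band[2]), call. = FALSE)
  }
  stopifnot_scalar(duration, "duration")
  if (duration < 10) {
    stop("duration must be >= 10 s so at least one full epoch exists",
         call. = FALSE)
  }
  check_period_range(cardiac_period_range)
  if (length(tone_duration_range) != 2 ||
      tone_duration_range[1] > tone_duration_range[2]) {
    stop("tone_duration_range must be c(min, max) in ms", call. = FALSE)
  }
  need <- c("blink", "cardiac")
  if (!all(need %in% names(artifact_amplitude_scales))) {
    stop("artifact_amplitude_scales needs named entries blink and cardiac",
         call. = FALSE)
  }
  structure(
    list(n_meg_channels = n_meg_channels, sampling_rate = sampling_rate,
         duration = duration, blink_mode = blink_mode,
         blink_rate = blink_rate,
         cardiac_period_range = cardiac_period_range,
         n_trials = n_trials, tone_duration_range = tone_duration_range,
         isi = isi,
         artifact_amplitude_scales = artifact_amplitude_scales[need],
         erf_amplitude = erf_amplitude,
         noise_scale = noise_scale, blink_rise_ms = blink_rise_ms,
         blink_decay_ms = blink_decay_ms, ref_noise = ref_noise,
         seed = seed),
    class = "sim_config"
  )
}

blink_rate_band <- function(mode) {
  if (mode == "rapid") c(1, 3) else c(0.2, 0.5)
}

check_period_range <- function(pr) {
  if (length(pr) != 2 || pr[1] > pr[2]) {
    stop("cardiac_period_range must be c(min, max) with min <= max",
         call. = FALSE)
  }
  if (pr[1] < 600 || pr[2] > 1200) {
    stop("cardiac_period_range must lie within [600, 1200] ms", call. = FALSE)
  }
  invisible(pr)
}

# Asymmetric biphasic blink waveform: a fast-rising, slower-decaying positive
# lobe followed by a shallow undershoot. Sampled at fs, returns the template.
blink_template <- function(fs, rise_ms = 100, decay_ms = 200) {
  sd_r <- rise_ms / 2000     # seconds
  sd_d <- decay_ms / 2000
  tp <- 3 * sd_r
  t_end <- tp + 0.3 + 3 * 0.09
  tt <- seq(0, t_end, by = 1 / fs)
  lobe <- ifelse(tt < tp,
                 exp(-(tt - tp)^2 / (2 * sd_r^2)),
                 exp(-(tt - tp)^2 / (2 * sd_d^2)))
  under <- -0.35 * exp(-(tt - (tp + 0.28))^2 / (2 * 0.09^2))
  lobe + under
}

# Three-lobe piecewise-Gaussian Q-R-S shape, total width ~100 ms.
qrs_template <- function(fs) {
  tt <- seq(-0.06, 0.07, by = 1 / fs)
  q <- -0.25 * exp(-(tt + 0.030)^2 / (2 * 0.008^2))
  r <- 1.00 * exp(-(tt)^2 / (2 * 0.011^2))
  s <- -0.35 * exp(-(tt - 0.028)^2 / (2 * 0.009^2))
  q + r + s
}

# Add `template` into `x` with its reference point at sample `at`
# (1-based; for templates with negative support pass `origin` = index of the
# template sample aligned with `at`). Edges are clipped.
add_template <- function(x, template, at, origin = 1L) {
  n <- length(x)
  start <- at - (origin - 1L)
  idx <- seq.int(start, start + length(template) - 1L)
  keep <- idx >= 1L & idx <= n
  if (any(keep)) x[idx[keep]] <- x[idx[keep]] + template[keep]
  x
}

#' Generate a non-periodic blink artifact source
#'
#' Blink events follow a renewal process with gamma-distributed inter-event
#' intervals (shape 3, mean `1 / rate`): jittered and non-periodic like a
#' Poisson train, but with the refractory regularity of real spontaneous
#' blinking (interval coefficient of variation ~0.6 rather than 1). Each
#' event is an asymmetric biphasic bump (fast ~100 ms rise, slower ~200 ms
#' decay with a shallow undershoot).
#'
#' @param mode `"normal"` or `"rapid"`; controls nothing but validation here
#'   (the event density is set by `rate`), mirroring the two acquisition
#'   conditions.
#' @param duration length in seconds.
#' @param rate expected events per second.
#' @param fs sampling rate in Hz.
#' @param seed integer seed (deterministic output for a fixed seed).
#' @param rise_ms,decay_ms template widths in ms.
#' @return numeric vector of `duration * fs` samples, zero baseline.
#' @export
make_blink_train <- function(mode = c("normal", "rapid"), duration, rate,
                             fs = 1000, seed = 1,
                             rise_ms = 100, decay_ms = 200) {
  if (is.character(mode)) {
    mode <- match.arg(mode)
  } else {
    stop("invalid blink mode", call. = FALSE)
  }
  stopifnot_scalar(duration, "duration")
  stopifnot_scalar(rate, "rate")
  n <- round(duration * fs)
  x <- numeric(n)
  onsets <- with_seed(seed, {
    shape <- 3
    m <- max(20L, ceiling(rate * duration * 3))
    gaps <- stats::rgamma(m, shape = shape, rate = shape * rate)
    while (sum(gaps) < duration) {
      gaps <- c(gaps, stats::rgamma(m, shape = shape, rate = shape * rate))
    }
    tt <- cumsum(gaps)
    tt[tt < duration]
  })
  tmpl <- blink_template(fs, rise_ms, decay_ms)
  for (ev in onsets) x <- add_template(x, tmpl, at = round(ev * fs) + 1L)
  attr(x, "event_times") <- onsets
  x
}

#' Generate a quasi-periodic QRS-like cardiac artifact source
#'
#' Successive inter-beat intervals are drawn uniformly from
#' `period_range` (ms); each beat is a three-lobe Q-R-S template.
#'
#' @param duration length in seconds.
#' @param period_range inter-beat interval range in ms (within 600-1200 ms).
#' @param fs sampling rate in Hz.
#' @param seed integer seed.
#' @return numeric vector of `duration * fs` samples with attribute
#'   `peak_times` (R-peak times in seconds).
#' @export
make_cardiac_train <- function(duration, period_range = c(900, 1000),
                               fs = 1000, seed = 1) {
  stopifnot_scalar(duration, "duration")
  check_period_range(period_range)
  n <- round(duration * fs)
  peaks <- with_seed(seed, {
    tt <- numeric(0)
    t <- 0
    repeat {
      t <- t + stats::runif(1, period_range[1], period_range[2]) / 1000
      if (t >= duration) break
      tt <- c(tt, t)
    }
    tt
  })
  tmpl <- qrs_template(fs)
  origin <- which.max(tmpl)  # align R peak
  x <- numeric(n)
  for (pk in peaks) x <- add_template(x, tmpl, at = round(pk * fs) + 1L,
                                      origin = origin)
  attr(x, "peak_times") <- peaks
  x
}

# M100-like evoked bump peaking 100 ms post-onset, support [0, 0.4] s.
erf_template <- function(fs) {
  tt <- seq(0, 0.4, by = 1 / fs)
  exp(-(tt - 0.100)^2 / (2 * 0.030^2))
}

# One neural background source: band-limited (1.5-40 Hz) Gaussian noise plus
# a bursty alpha-band (8-13 Hz) oscillation whose envelope is rectified slow
# noise, emulating the waxing and waning of cortical alpha. The burstiness
# makes each source clearly non-Gaussian, which both resembles resting MEG
# rhythms and keeps the recording identifiable for ICA. Unit RMS; uses the
# caller's RNG stream.
neural_background <- function(n, fs) {
  bf <- signal::butter(4, c(1.5, 40) / (fs / 2), type = "pass")
  noise <- signal::filtfilt(bf, stats::rnorm(n))
  noise <- noise / rms(noise)
  bf_slow <- signal::butter(2, 1 / (fs / 2), type = "low")
  env <- pmax(signal::filtfilt(bf_slow, stats::rnorm(n)), 0)
  f <- stats::runif(1, 8, 13)
  alpha <- env * sin(2 * pi * f * seq_len(n) / fs + stats::runif(1, 0, 2 * pi))
  alpha <- alpha / rms(alpha)
  x <- 0.6 * noise + 1.5 * alpha
  x / rms(x)
}

unit_rms <- function(x) if (all(x == 0)) x else x / rms(x)

#' Simulate a ground-truthed OPM-MEG session
#'
#' MEG channels are a sum of per-channel neural background (1.5-40 Hz
#' band-limited noise plus a 10 Hz rhythm), and topography-weighted blink,
#' cardiac and trial-locked auditory evoked sources. The MOG/MCG reference
#' channels carry the blink/cardiac source plus a small independent noise;
#' the trigger line carries rectangular pulses spanning each tone.
#'
#' @param config a [sim_config()].
#' @return a list with elements `recording` (a [recording()]) and
#'   `ground_truth` (sources, mixing topographies, trigger onset samples).
#' @export
simulate_session <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop("`config` must be a sim_config()", call. = FALSE)
  }
  fs <- config$sampling_rate
  n <- round(config$duration * fs)
  n_meg <- config$n_meg_channels

  # trial layout: first onset 1 s in, then every isi; evoked support 0.5 s
  t0 <- 1
  max_trials <- floor((config$duration - t0 - 0.5) / config$isi) + 1
  n_trials <- if (is.null(config$n_trials)) max_trials else config$n_trials
  if (n_trials < 1 || n_trials > max_trials) {
    stop(sprintf(
      "duration %.3g s too short for %d trials at isi %.3g s",
      config$duration, n_trials, config$isi), call. = FALSE)
  }
  onset_times <- t0 + (seq_len(n_trials) - 1) * config$isi
  trigger_onsets <- round(onset_times * fs) + 1L

  blink <- unit_rms(make_blink_train(
    config$blink_mode, config$duration, config$blink_rate, fs,
    seed = derive_seed(config$seed, 1),
    rise_ms = config$blink_rise_ms, decay_ms = config$blink_decay_ms))
  cardiac <- unit_rms(make_cardiac_train(
    config$duration, config$cardiac_period_range, fs,
    seed = derive_seed(config$seed, 2)))

  erf <- numeric(n)
  tmpl <- erf_template(fs)
  for (on in trigger_onsets) erf <- add_template(erf, tmpl, at = on)
  erf <- unit_rms(erf)

  # The MEG array is an instantaneous mixture of n_meg independent sources:
  # (n_meg - 3) neural background sources plus the blink, cardiac and evoked
  # sources, each entering through a random unit-norm topography. A square,
  # full-rank mixture keeps the simulated physics (shared field patterns
  # across sensors) and makes the recording identifiable for ICA.
  if (n_meg < 4) stop("at least 4 MEG channels are required", call. = FALSE)
  n_bg <- n_meg - 3L
  background <- with_seed(derive_seed(config$seed, 3), {
    t(vapply(seq_len(n_bg), function(i) neural_background(n, fs),
             numeric(n)))
  })

  topo_all <- with_seed(derive_seed(config$seed, 4), {
    A <- matrix(stats::rnorm(n_meg * n_meg), n_meg)
    apply(A, 2, function(g) g / sqrt(sum(g^2)))
  })
  topo <- list(blink = topo_all[, n_bg + 1], cardiac = topo_all[, n_bg + 2],
               erf = topo_all[, n_bg + 3])

  sc <- config$artifact_amplitude_scales
  meg <- config$noise_scale *
    (topo_all[, seq_len(n_bg), drop = FALSE] %*% background) +
    sc[["blink"]] * topo$blink %o% as.numeric(blink) +
    sc[["cardiac"]] * topo$cardiac %o% as.numeric(cardiac) +
    config$erf_amplitude * topo$erf %o% erf

  refs <- with_seed(derive_seed(config$seed, 6), {
    list(mog = as.numeric(blink) + config$ref_noise * stats::rnorm(n),
         mcg = as.numeric(cardiac) + config$ref_noise * stats::rnorm(n))
  })

  trigger <- numeric(n)
  tone_ms <- with_seed(derive_seed(config$seed, 5),
                       stats::runif(n_trials, config$tone_duration_range[1],
                                    config$tone_duration_range[2]))
  for (k in seq_len(n_trials)) {
    i0 <- trigger_onsets[k]
    i1 <- min(n, i0 + round(tone_ms[k] / 1000 * fs))
    trigger[i0:i1] <- 1
  }

  data <- rbind(meg, refs$mog, refs$mcg, trigger)
  roles <- c(rep("MEG", n_meg), "MOG_REF", "MCG_REF", "TRIGGER")
  rec <- recording(data, fs, roles)

  ground_truth <- list(
    blink_source = as.numeric(blink),
    cardiac_source = as.numeric(cardiac),
    erf_source = erf,
    mixing_topographies = topo,
    trigger_onsets = trigger_onsets,
    blink_event_times = attr(blink, "event_times"),
    cardiac_peak_times = attr(cardiac, "peak_times")
  )
  list(recording = rec, ground_truth = ground_truth)
}
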