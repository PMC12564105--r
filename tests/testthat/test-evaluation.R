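# Metrics, ERF averaging, SNR, and cleaning plumbing.

test_that("metrics match hand-computed values on a known confusion", {
  # true:  0 0 0 0 1 1 1 2 2 2
  # pred:  0 0 1 0 1 1 2 2 2 2
  true <- c(0, 0, 0, 0, 1, 1, 1, 2, 2, 2)
  pred <- c(0, 0, 1, 0, 1, 1, 2, 2, 2, 2)
  mt <- compute_metrics(true, pred)
  expect_equal(sum(mt$confusion), 10)
  expect_equal(mt$accuracy, 80)
  pc <- mt$per_class
  expect_equal(pc$precision[pc$class == "cardiac"], 100)          # 3/3
  expect_equal(pc$recall[pc$class == "cardiac"], 75)              # 3/4
  expect_equal(pc$precision[pc$class == "blink"], 100 * 2 / 3)
  expect_equal(pc$recall[pc$class == "blink"], 100 * 2 / 3)
  expect_equal(pc$precision[pc$class == "none"], 75)              # 3/4
  expect_equal(pc$recall[pc$class == "none"], 100)
  expect_equal(pc$f1[pc$class == "cardiac"],
               f1_score(100, 75))
  expect_equal(mt$macro$f1, mean(pc$f1))
  expect_equal(mt$macro$precision, mean(pc$precision))

  perfect <- compute_metrics(0:2, 0:2)
  expect_equal(perfect$accuracy, 100)
  expect_true(all(perfect$per_class$f1 == 100))
  expect_equal(perfect$macro$f1, 100)

  expect_warning(compute_metrics(c(0, 1, 2), c(1, 1, 2)), "zero denominator")
  expect_error(compute_metrics(integer(0), integer(0)), "non-empty")
  expect_error(compute_metrics(c(0, 5), c(0, 1)), "labels")
})

test_that("F1 is the harmonic mean of precision and recall", {
  expect_equal(f1_score(100, 100), 100)
  expect_equal(f1_score(50, 100), 200 / 3)
  expect_equal(f1_score(0, 0), 0)
  expect_equal(f1_score(c(100, 0), c(100, 50)), c(100, 0))
})

trial_recording <- function(template, n_trials, noise_sd, fs = 1000,
                            isi = 1, seed = 1) {
  set.seed(seed)
  n <- (n_trials + 1) * isi * fs
  onsets <- (seq_len(n_trials) - 1) * isi * fs + 0.5 * fs + 1
  meg <- matrix(stats::rnorm(2 * n, 0, noise_sd), 2)
  for (on in onsets) {
    idx <- on:(on + length(template) - 1)
    meg[, idx] <- meg[, idx] + rep(template, each = 2)
  }
  trig <- numeric(n)
  for (on in onsets) trig[on:(on + 100)] <- 1
  recording(rbind(meg, 0, 0, trig), fs,
            c("MEG", "MEG", "MOG_REF", "MCG_REF", "TRIGGER"))
}

test_that("ERF averaging is baseline-corrected and reduces noise as 1/sqrt(N)", {
  fs <- 1000
  tmpl <- exp(-(seq(0, 0.3, by = 1 / fs) - 0.1)^2 / (2 * 0.03^2))

  # identical noise-free trials: the ERF is the (baseline-corrected) trial;
  # the pre-stimulus window is silent, so the baseline is zero
  rec0 <- trial_recording(tmpl, n_trials = 5, noise_sd = 0)
  erf0 <- erf_average(rec0, window = c(-0.2, 0.4))
  expect_equal(erf0$n_trials, 5)
  post <- erf0$data[1, erf0$times >= 0 & erf0$times <= 0.3]
  expect_equal(post, tmpl[seq_along(post)], tolerance = 1e-9)
  expect_equal(unname(rowMeans(erf0$data[, erf0$times < 0])), c(0, 0),
               tolerance = 1e-12)

  # trial-locked signal + noise: residual shrinks like 1/sqrt(N)
  n_tr <- 200
  rec <- trial_recording(tmpl, n_trials = n_tr, noise_sd = 1, seed = 2)
  erf <- erf_average(rec, window = c(-0.2, 0.4))
  resid <- erf$data[1, erf$times >= 0 & erf$times <= 0.3] -
    tmpl[seq_along(post)]
  expect_lt(abs(opmclean:::rms(resid) * sqrt(n_tr) - 1), 0.25)

  expect_error(erf_average(rec0, window = c(0.1, 0.4)), "onset")
})

test_that("SNR follows its closed form and is scale-invariant", {
  mk_erf <- function(pre, post, fs = 1000) {
    times <- seq(-0.2, 0.3, by = 1 / fs)
    data <- matrix(0, 2, length(times))
    data[, times < 0] <- pre
    data[, times >= 0 & times <= 0.2] <- post
    structure(list(data = data, times = times, n_trials = 10,
                   sampling_rate = fs), class = "erf_waveform")
  }
  expect_equal(snr_db(mk_erf(1, 1)), 0)
  expect_equal(snr_db(mk_erf(1, 10)), 20)
  e <- mk_erf(0.5, 4)
  e2 <- e
  e2$data <- 7.3 * e$data
  expect_equal(snr_db(e2), snr_db(e))
  zero <- mk_erf(0, 1)
  expect_error(snr_db(zero), "zero pre-stimulus")
  narrow <- mk_erf(1, 1)
  narrow$times <- narrow$times / 10
  expect_error(snr_db(narrow), "cover")
})

test_that("a model that never flags leaves the filtered recording untouched", {
  ses <- small_session(seed = 12, duration = 10)
  cfg <- ca_seqnet_config(input_length = 500,
                          conv_channels = c(4, 4, 4, 4, 4, 4, 4),
                          frd_hidden = c(8, 4))
  model <- ca_seqnet_init(cfg, seed = 1)
  # bias the final layer so every component is predicted non-artifact
  model$params$fc3_W[] <- 0
  model$params$fc3_b <- c(-10, -10, 10)
  out <- clean_recording(ses$recording, model, ica_seed = 4)
  expect_true(all(lengths(out$removed) == 0))
  expect_lt(opmclean:::rms(out$recording$data - out$filtered$data) /
              opmclean:::rms(out$filtered$data), 1e-6)
  # reference and trigger channels pass through the cleaning stage untouched
  refs <- which(ses$recording$channel_roles != "MEG")
  expect_identical(out$recording$data[refs, ], out$filtered$data[refs, ])
})
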