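# Synthetic session generator: event statistics, recording contract,
# reproducibility.

test_that("blink trains match the requested event density and are seeded", {
  counts <- vapply(1:200, function(s) {
    length(attr(make_blink_train("rapid", 10, 2, seed = s), "event_times"))
  }, numeric(1))
  expect_true(abs(mean(counts) - 20) < 1.5)
  expect_true(all(counts >= 10 & counts <= 30))

  # vanishing rate: almost surely no event in 10 s
  quiet <- make_blink_train("normal", 10, 1e-4, seed = 1)
  expect_true(all(quiet == 0))

  expect_identical(make_blink_train("rapid", 10, 2, seed = 7),
                   make_blink_train("rapid", 10, 2, seed = 7))
  expect_error(make_blink_train("sideways", 10, 2), "one of")
  expect_error(make_blink_train("rapid", 10, 0), "rate")
})

test_that("cardiac trains are quasi-periodic within the period range", {
  n_peaks <- vapply(1:50, function(s) {
    length(attr(make_cardiac_train(10, c(900, 1000), seed = s), "peak_times"))
  }, numeric(1))
  expect_true(all(n_peaks %in% c(10, 11)))

  exact <- make_cardiac_train(10, c(1000, 1000), seed = 3)
  gaps <- diff(attr(exact, "peak_times"))
  expect_equal(gaps, rep(1, length(gaps)), tolerance = 1e-12)

  expect_identical(make_cardiac_train(10, seed = 5),
                   make_cardiac_train(10, seed = 5))
  expect_error(make_cardiac_train(10, c(1000, 900)), "min <= max")
  expect_error(make_cardiac_train(10, c(200, 900)), "600")
})

test_that("simulated sessions satisfy the recording contract", {
  ses <- small_session(seed = 2, duration = 12, n_trials = 5)
  rec <- ses$recording
  expect_s3_class(rec, "recording")
  expect_equal(sum(rec$channel_roles == "MOG_REF"), 1)
  expect_equal(sum(rec$channel_roles == "MCG_REF"), 1)
  expect_equal(sum(rec$channel_roles == "TRIGGER"), 1)
  expect_equal(ncol(rec$data), 12000)

  # exactly 5 trigger pulses spaced >= isi
  onsets <- detect_trigger_onsets(rec)
  expect_equal(length(onsets), 5)
  expect_true(all(diff(onsets) >= 2 * rec$sampling_rate))
  expect_equal(onsets, ses$ground_truth$trigger_onsets)

  # every topography has nonzero gain
  expect_true(all(vapply(ses$ground_truth$mixing_topographies,
                         function(g) any(g != 0), logical(1))))

  expect_error(sim_config(duration = 8), ">= 10")
  expect_error(simulate_session(sim_config(duration = 10, n_trials = 50)),
               "too short")
  expect_error(sim_config(blink_mode = "rapid", blink_rate = 0.2), "band")
})

test_that("zero artifact gains leave MEG clean while references keep sources", {
  ses <- small_session(seed = 4,
                       artifact_amplitude_scales = c(blink = 0, cardiac = 0))
  meg <- channel_data(ses$recording, "MEG")
  blink <- ses$ground_truth$blink_source
  # no MEG channel carries the blink source
  cors <- abs(apply(meg, 1, stats::cor, y = blink))
  expect_true(all(cors < 0.1))
  # the reference still does
  expect_gt(stats::cor(channel_data(ses$recording, "MOG_REF"), blink), 0.9)
})

test_that("blink and cardiac sources are uncorrelated by construction", {
  cors <- vapply(1:100, function(s) {
    b <- make_blink_train("normal", 10, 0.4, seed = s)
    h <- make_cardiac_train(10, seed = s + 5000)
    abs(stats::cor(as.numeric(b), as.numeric(h)))
  }, numeric(1))
  expect_gte(mean(cors < 0.2), 0.95)
})

test_that("evoked energy is confined to the post-onset window", {
  ses <- small_session(seed = 6, duration = 14)
  erf <- ses$ground_truth$erf_source
  fs <- ses$recording$sampling_rate
  inside <- rep(FALSE, length(erf))
  for (on in ses$ground_truth$trigger_onsets) {
    inside[on:min(length(erf), on + 0.5 * fs)] <- TRUE
  }
  expect_equal(sum(erf[!inside]^2), 0)
})

test_that("sessions are bit-reproducible for a fixed seed", {
  a <- small_session(seed = 11)
  b <- small_session(seed = 11)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$ground_truth, b$ground_truth)
})
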