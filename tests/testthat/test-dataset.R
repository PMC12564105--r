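# Threshold labeling, balanced assembly, inversion augmentation, splitting.

score_table <- function(mog, mcg, epoch = 1L) {
  data.frame(epoch_id = epoch, component_id = seq_along(mog),
             rdc_mog = mog, rdc_mcg = mcg)
}

test_that("threshold labeling follows the delta/lambda rule", {
  tab <- label_components(score_table(c(0.72, 0.10, 0.05),
                                      c(0.05, 0.65, 0.04)),
                          delta = 0.3, lambda = 0.2)
  expect_equal(tab$label, c(1L, 0L, 2L))

  # gap component stays unlabeled
  gap <- label_components(score_table(0.25, 0.10), delta = 0.3, lambda = 0.2)
  expect_true(is.na(gap$label))

  # only the highest-scoring component above delta gets the artifact label
  two <- label_components(score_table(c(0.5, 0.4), c(0.05, 0.04)),
                          delta = 0.3, lambda = 0.2)
  expect_equal(two$label, c(1L, NA_integer_))

  # epochs are labeled independently
  multi <- rbind(score_table(c(0.6, 0.05), c(0.05, 0.5), epoch = 1L),
                 score_table(c(0.05, 0.7), c(0.6, 0.05), epoch = 2L))
  lab <- label_components(multi, 0.3, 0.2)$label
  expect_equal(lab, c(1L, 0L, 0L, 1L))

  expect_error(label_components(score_table(0.5, 0.5), 0.2, 0.3), "delta")
})

test_that("a double-threshold component takes the larger score and the loser falls back", {
  # component 1 tops both references; mcg score is larger -> cardiac,
  # blink falls back to component 2
  tab <- label_components(score_table(c(0.55, 0.45), c(0.70, 0.05)),
                          0.3, 0.2)
  expect_equal(tab$label[1], 0L)
  expect_equal(tab$label[2], 1L)

  # exact tie breaks toward cardiac
  tie <- label_components(score_table(0.5, 0.5), 0.3, 0.2)
  expect_equal(tie$label, 0L)
})

test_that("assembly enforces the 1:1:4 ratio and reports deficits", {
  set.seed(1)
  waves <- matrix(stats::rnorm(80 * 50), 80)
  labels <- c(rep(1L, 12), rep(0L, 10), rep(2L, 55), rep(NA_integer_, 3))
  ds <- assemble_dataset(waves, labels, seed = 3)
  expect_equal(unname(ds$class_counts), c(10, 10, 40))
  expect_equal(nrow(ds$waveforms), 60)
  # standardized storage
  expect_equal(apply(ds$waveforms, 1, stats::sd), rep(1, 60),
               tolerance = 1e-8)
  expect_equal(rowMeans(ds$waveforms), rep(0, 60), tolerance = 1e-12)
  # deterministic subsampling
  ds2 <- assemble_dataset(waves, labels, seed = 3)
  expect_identical(ds$waveforms, ds2$waveforms)

  few_none <- c(rep(1L, 10), rep(0L, 10), rep(2L, 35))
  expect_error(assemble_dataset(matrix(stats::rnorm(55 * 50), 55), few_none),
               "need 40, have 35")
})

test_that("inversion augmentation doubles the corpus with sign twins", {
  ds <- toy_dataset(n_per = 10)
  aug <- augment_invert(ds)
  expect_equal(nrow(aug$waveforms), 2 * nrow(ds$waveforms))
  expect_equal(unname(aug$class_counts), unname(2 * ds$class_counts))
  n <- nrow(ds$waveforms)
  expect_equal(aug$waveforms[n + 3, ], -aug$waveforms[3, ])
  expect_equal(aug$labels[n + 3], aug$labels[3])
  expect_equal(aug$provenance$group[n + 3], aug$provenance$group[3])
  # augmenting again quadruples the original
  expect_equal(nrow(augment_invert(aug)$waveforms), 4 * n)
})

test_that("the split is stratified and keeps sign twins together", {
  aug <- augment_invert(toy_dataset(n_per = 25))
  sp <- split_dataset(aug, train_frac = 0.8, seed = 4)
  expect_equal(nrow(sp$train$waveforms), 120)
  expect_equal(nrow(sp$test$waveforms), 30)
  for (cls in 0:2) {
    expect_equal(sum(sp$train$labels == cls), 40)
    expect_equal(sum(sp$test$labels == cls), 10)
  }
  # twin co-partitioning: no provenance group straddles the split
  expect_length(intersect(sp$train$provenance$group,
                          sp$test$provenance$group), 0)
  # no waveform appears in both partitions up to sign
  key <- function(w) apply(abs(w), 1, function(r) paste(signif(r[1:5], 6),
                                                        collapse = ","))
  expect_length(intersect(key(sp$train$waveforms), key(sp$test$waveforms)), 0)
  # deterministic
  sp2 <- split_dataset(aug, train_frac = 0.8, seed = 4)
  expect_identical(sp$train$waveforms, sp2$train$waveforms)
})

test_that("component scores are invariant to reference rescaling", {
  set.seed(2)
  n <- 3000
  src <- rbind(stats::rnorm(n), stats::rnorm(n), stats::rnorm(n))
  src[1, ] <- make_blink_train("rapid", 3, 2, seed = 1)[1:n] + 0.1 * src[1, ]
  dec <- structure(list(sources = src, n_components = 3L),
                   class = "ica_decomposition")
  mog <- src[1, ] + 0.05 * stats::rnorm(n)
  mcg <- stats::rnorm(n)
  p <- rdc_params(seed = 5)
  t1 <- score_components(dec, mog, mcg, p)
  t2 <- score_components(dec, 10 * mog, 10 * mcg, p)
  expect_identical(t1$rdc_mog, t2$rdc_mog)
  expect_identical(t1$rdc_mcg, t2$rdc_mcg)
  # the contaminated component wins the ocular reference
  expect_equal(which.max(t1$rdc_mog), 1L)
  expect_error(score_components(dec, mog[-1], mcg, p), "length")
})
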