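test_that("baseline z-scoring divides each channel by one pooled scalar", {
  ep <- make_tiny_epochs(n_trials = 6, n_channels = 2, n_samples = 20, sfreq = 40, t0 = -250)
  ep$data[, 2, ] <- ep$data[, 2, ] * 2 # channel 2 gets SD ~2x channel 2's own scale
  base_idx <- time_mask(ep, -500, 0)
  sd2 <- stats::sd(as.vector(ep$data[, 2, base_idx]))
  z <- baseline_zscore(ep)
  expect_equal(z$data[, 2, ], ep$data[, 2, ] / sd2)
  # pooled baseline SD is 1 per channel afterwards
  for (j in 1:2) {
    expect_equal(stats::sd(as.vector(z$data[, j, base_idx])), 1, tolerance = 1e-12)
  }
})

test_that("z-scoring is idempotent and matches a brute-force recomputation", {
  ep <- make_tiny_epochs(n_trials = 5, n_channels = 3, sfreq = 40, t0 = -200)
  z1 <- baseline_zscore(ep, baseline = c(-200, 0))
  z2 <- baseline_zscore(z1, baseline = c(-200, 0))
  expect_equal(z1$data, z2$data, tolerance = 1e-12)
  # brute force: loop over channels, pooled SD over all trials
  keep <- which(ep$times >= -200 & ep$times < 0)
  manual <- ep$data
  for (j in 1:3) {
    manual[, j, ] <- manual[, j, ] / stats::sd(as.vector(ep$data[, j, keep]))
  }
  expect_equal(z1$data, manual)
})

test_that("z-scoring flags zero-SD channels by name and commutes with channel subsetting", {
  ep <- make_tiny_epochs(n_trials = 4, n_channels = 3)
  flat <- ep
  flat$data[, 2, ] <- 7
  expect_error(baseline_zscore(flat, baseline = c(-100, 0)), "ch2")
  a <- subset_epochs(baseline_zscore(ep, baseline = c(-100, 0)), channels = c(1, 3))
  b <- baseline_zscore(subset_epochs(ep, channels = c(1, 3)), baseline = c(-100, 0))
  expect_equal(a$data, b$data)
})

test_that("pass-band content survives filtering and stop-band is attenuated >= 20 dB", {
  sfreq <- 1000
  n <- 2500
  tt <- (seq_len(n) - 1) / sfreq
  x5 <- sin(2 * pi * 5 * tt)
  x45 <- sin(2 * pi * 45 * tt)
  mk <- function(x) {
    epoch_set(
      array(rep(x, each = 2), dim = c(1, 2, n)),
      times = -500 + (seq_len(n) - 1) * 1000 / sfreq, sfreq = sfreq,
      channels = tibble::tibble(name = c("a", "b"), type = "eeg"),
      trials = make_trials(1)
    )
  }
  interior <- 300:2200 # judge amplitude away from the epoch edges
  f5 <- resample_lowpass(mk(x5), 30, 1000) # no decimation, filter only
  amp5 <- max(abs(f5$data[1, 1, interior]))
  expect_lt(abs(amp5 - 1), 0.01)
  f45 <- resample_lowpass(mk(x45), 30, 1000)
  amp45 <- max(abs(f45$data[1, 1, interior]))
  expect_lt(20 * log10(amp45), -20)
})

test_that("decimation keeps exactly every sfreq/target-th sample", {
  sfreq <- 1000
  n <- 2000
  ep <- epoch_set(
    array(stats::rnorm(2 * 2 * n), dim = c(2, 2, n)),
    times = -500 + (seq_len(n) - 1) * 1000 / sfreq, sfreq = sfreq,
    channels = tibble::tibble(name = c("a", "b"), type = "eeg"),
    trials = make_trials(2)
  )
  out <- resample_lowpass(ep, 30, 125)
  expect_equal(dim(out$data)[3], n / 8)
  expect_equal(out$sfreq, 125)
  expect_equal(diff(out$times)[1], 8)
  expect_identical(out$trials, ep$trials)
  expect_error(resample_lowpass(ep, 70, 125), "Nyquist")
  expect_error(resample_lowpass(ep, 30, 3000), "must not exceed")
})

test_that("select_subset filters channels/trials and never fabricates trials", {
  beh <- make_trials(30, seen = rep(c(TRUE, FALSE), 15))
  rec <- signal_recipe(n_trials = 30, n_channels = 10, n_eog = 2, seed = 3)
  ep <- generate_epochs(rec, beh)
  eog <- select_subset(ep, channels = type == "eog")
  expect_true(all(eog$channels$type == "eog"))
  expect_equal(nrow(eog$channels), 2)
  seen_only <- select_subset(ep, trials = seen)
  im <- attr(seen_only, "index_map")
  expect_true(all(im$trial_index %in% which(beh$seen)))
  expect_false(anyDuplicated(im$trial_index) > 0)
  expect_identical(seen_only$data[1, , ], ep$data[im$trial_index[1], , ])
})

test_that("balancing equalizes cells at the minimum count, reproducibly", {
  n <- 60
  beh <- make_trials(n)
  beh$seen <- rep(c(TRUE, TRUE, FALSE), length.out = n) # unbalanced visibility
  rec <- signal_recipe(n_trials = n, n_channels = 12, seed = 3)
  ep <- generate_epochs(rec, beh)
  ep$trials$hemifield <- as.character(hemifield_labels(ep$trials$location))
  bal <- select_subset(ep, balance = c("hemifield", "seen"), seed = 11)
  counts <- dplyr::count(bal$trials, hemifield, seen)
  expect_equal(nrow(counts), 4)
  expect_true(all(counts$n == min(dplyr::count(ep$trials, hemifield, seen)$n)))
  bal2 <- select_subset(ep, balance = c("hemifield", "seen"), seed = 11)
  expect_identical(attr(bal, "index_map"), attr(bal2, "index_map"))
  expect_error(select_subset(ep, balance = c("hemifield", "seen")), "seed")
  # empty cell is a named error
  ep2 <- ep
  ep2$trials$seen <- ep2$trials$location != 1 # no (hemifield=left... seen=FALSE beyond loc1)
  expect_error(
    select_subset(ep2, trials = location %in% c(1, 5), balance = c("location", "seen"), seed = 1),
    "empty cell"
  )
})
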