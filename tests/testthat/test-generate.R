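test_that("recipe validation catches inconsistent stage/chain geometry", {
  expect_error(signal_recipe(sfreq = 0), "sfreq")
  expect_error(
    signal_recipe(stage_windows = list(s1 = c(0, 100), s2 = c(50, 200), s3 = c(200, 300), s4 = c(300, 800))),
    "disjoint"
  )
  expect_error(
    signal_recipe(chain_states = 12, state_duration_ms = 160),
    "does not fit"
  )
  expect_error(
    signal_recipe(stage_windows = list(s1 = c(-600, 0), s2 = c(0, 100), s3 = c(100, 200), s4 = c(200, 800))),
    "inside the epoch window"
  )
})

test_that("identical seeds give bitwise-identical epoch sets", {
  beh <- make_trials(24)
  rec <- signal_recipe(n_trials = 24, n_channels = 12, seed = 42)
  e1 <- generate_epochs(rec, beh)
  e2 <- generate_epochs(rec, beh)
  expect_identical(e1$data, e2$data)
  rec2 <- signal_recipe(n_trials = 24, n_channels = 12, seed = 43)
  expect_false(identical(generate_epochs(rec2, beh)$data, e1$data))
})

test_that("zero pattern amplitude leaves pure stationary noise", {
  beh <- make_trials(40)
  rec <- signal_recipe(n_trials = 40, n_channels = 10, pattern_snr = 0, seed = 5)
  ep <- generate_epochs(rec, beh)
  # mean power identical across stage windows (no stimulus-locked energy)
  pw <- vapply(stage_windows(), function(w) {
    mean(ep$data[, , time_mask(ep, w[1], w[2])]^2)
  }, numeric(1))
  expect_true(all(abs(pw - 1) < 0.05))
  # and no dependence on location: class means are noise-level
  vals <- ep$data[, , time_mask(ep, 115, 162)]
  expect_lt(abs(mean(vals)), 4 / sqrt(length(vals)))
})

test_that("noiseless epochs are separable by nearest-pattern readout in stage 2", {
  beh <- make_trials(8) # one trial per location
  rec <- signal_recipe(
    n_trials = 8, n_channels = 12, noise_sd = 0,
    pattern_snr = 1, seed = 9
  )
  ep <- generate_epochs(rec, beh)
  sel <- which(time_mask(ep, 120, 162))
  for (t in sel) {
    X <- ep$data[, , t]
    if (all(abs(X) < 1e-12)) next # before the ramp has risen
    # each trial is a pure location template; nearest-template readout
    # (max inner product) must recover its own location with certainty
    sim <- X %*% t(X)
    pred <- apply(sim, 1, which.max)
    expect_equal(pred, 1:8, ignore_attr = TRUE)
  }
})

test_that("the early decoding envelope peaks at the sample nearest 147 ms", {
  beh <- make_trials(8)
  rec <- signal_recipe(n_trials = 8, n_channels = 12, noise_sd = 0, seed = 2)
  ep <- generate_epochs(rec, beh)
  # signal power over trials/channels per sample
  pw <- apply(ep$data^2, 3, mean)
  stage23 <- which(time_mask(ep, 115, 271))
  peak_sample <- stage23[which.max(pw[stage23])]
  expect_equal(peak_sample, nearest_sample(ep, 147))
})

test_that("seen trials superpose chain codes on the lingering code; unseen do not", {
  n <- 16
  beh <- make_trials(n, seen = rep(c(TRUE, FALSE), each = 8))
  rec <- signal_recipe(n_trials = n, n_channels = 16, noise_sd = 0, seed = 4)
  ep <- generate_epochs(rec, beh)
  s4 <- which(time_mask(ep, 300, 431)) # inside chain state 1
  pw_seen <- mean(ep$data[beh$seen, , s4]^2)
  pw_unseen <- mean(ep$data[!beh$seen, , s4]^2)
  expect_gt(pw_seen, 2 * pw_unseen)
  # stages 2-3 identical across visibility (shared code only)
  s23 <- which(time_mask(ep, 115, 271))
  expect_equal(ep$data[1, , s23], ep$data[9, , s23]) # same location, seen vs unseen
})

test_that("downstream decodability is monotone in pattern SNR", {
  beh <- make_trials(64)
  acc <- vapply(c(0, 0.6, 1.8), function(snr) {
    rec <- signal_recipe(n_trials = 64, n_channels = 12, pattern_snr = snr, seed = 31)
    ep <- generate_epochs(rec, beh)
    ep <- if (snr > 0) baseline_zscore(ep) else ep
    ep <- crop_epochs(ep, 130, 165)
    res <- decode_timecourse(ep, "location", k = 4, seed = 8)
    mean(correct_class_matrix(res))
  }, numeric(1))
  expect_true(all(diff(acc) > 0))
  expect_lt(abs(acc[1] - 0.125), 0.02)
})

test_that("ROI epochs respect onset latencies and workspace amplification", {
  beh <- make_trials(16, seen = rep(c(TRUE, FALSE), each = 8))
  rec <- signal_recipe(
    n_trials = 16, n_channels = 16, roi_n_channels = 12, noise_sd = 0, seed = 6,
    roi_onsets_ms = c(pericalcarine = 115, superior_parietal = 115, rostral_medial_frontal = 365)
  )
  rois <- generate_roi_epochs(rec, beh)
  expect_named(rois, c("pericalcarine", "superior_parietal", "rostral_medial_frontal"))
  rmf <- rois$rostral_medial_frontal
  before <- time_mask(rmf, -500, 365)
  expect_true(all(rmf$data[, , before] == 0))
  expect_false(all(rmf$data[, , !before] == 0))
  # chain component = seen minus unseen trial of the same location; its
  # workspace vs non-workspace amplitude ratio is exactly seen_gain
  s4 <- which(time_mask(rmf, 300, 431))
  chain_ws <- rois$superior_parietal$data[1, , s4] - rois$superior_parietal$data[9, , s4]
  chain_nw <- rois$pericalcarine$data[1, , s4] - rois$pericalcarine$data[9, , s4]
  keep <- abs(chain_nw) > 1e-9
  expect_true(any(keep))
  expect_true(all(abs(chain_ws[keep] / chain_nw[keep] - rec$seen_gain) < 1e-9))
  # empty ROI map gives an empty named list
  rec0 <- signal_recipe(roi_onsets_ms = stats::setNames(numeric(0), character(0)))
  expect_length(generate_roi_epochs(rec0, beh), 0)
  expect_error(
    generate_roi_epochs(signal_recipe(roi_onsets_ms = c(x = 3000)), beh),
    "outside the epoch window"
  )
})
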