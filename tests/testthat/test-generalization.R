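# build a generalization_matrix by hand
make_gm <- function(values, sfreq = 64, t0 = 0) {
  structure(
    list(
      values = values,
      times = t0 + (seq_len(nrow(values)) - 1) * 1000 / sfreq,
      sfreq = sfreq, folds = NULL,
      train_cond = "all", test_cond = "all", n_classes = 8
    ),
    class = "generalization_matrix"
  )
}

test_that("the matrix diagonal reproduces the decoding curve with shared folds", {
  beh <- make_trials(32)
  rec <- signal_recipe(n_trials = 32, n_channels = 12, pattern_snr = 1.5, seed = 17)
  ep <- crop_epochs(baseline_zscore(generate_epochs(rec, beh)), 100, 260)
  folds <- assign_folds(32, k = 4, seed = 5)
  y <- hemifield_labels(ep$trials$location)
  tgm <- temporal_generalization_matrix(ep, y, folds = folds)
  res <- decode_timecourse(ep, y, folds = folds)
  curve <- correct_class_series(res)
  expect_identical(diag(tgm$values), curve$mean)
})

test_that("self-transfer reproduces the within curve; overlap errors out", {
  beh <- make_trials(32)
  rec <- signal_recipe(n_trials = 32, n_channels = 12, pattern_snr = 1.5, seed = 19)
  ep <- crop_epochs(baseline_zscore(generate_epochs(rec, beh)), 100, 200)
  y <- hemifield_labels(ep$trials$location)
  mask <- rep(TRUE, 32)
  curves <- cross_condition_curves(ep, y, mask, mask, k = 4, seed = 2)
  wide <- tidyr::pivot_wider(
    curves[c("curve", "time_ms", "mean")],
    names_from = "curve", values_from = "mean"
  )
  expect_equal(wide$within, wide$transfer)
  half <- mask
  half[1:10] <- FALSE
  expect_error(cross_condition_curves(ep, y, mask, half, k = 4, seed = 2), "overlap")
})

test_that("lag recentering matches brute-force re-indexing and keeps the diagonal at lag 0", {
  v <- matrix(stats::runif(25), 5, 5)
  gm <- make_gm(v, sfreq = 1000) # 1 ms steps for easy lag arithmetic
  lags <- recenter_by_lag(gm)
  lag0 <- dplyr::arrange(dplyr::filter(lags, lag_samples == 0), train_ms)
  expect_equal(lag0$value, diag(v))
  # exhaustive loop oracle
  for (t in 1:5) {
    for (tp in 1:5) {
      got <- dplyr::filter(
        lags,
        train_ms == gm$times[t], lag_samples == tp - t
      )$value
      expect_equal(got, v[t, tp])
    }
  }
  # out-of-range lags are missing
  expect_true(all(is.na(dplyr::filter(lags, train_ms == gm$times[1], lag_samples < 0)$value)))
  # symmetric matrix gives a lag surface symmetric in +/- lag after averaging
  vs <- (v + t(v)) / 2
  lsym <- recenter_by_lag(make_gm(vs, sfreq = 1000)) |>
    dplyr::filter(!is.na(value)) |>
    dplyr::summarise(m = mean(value), .by = lag_samples)
  m <- setNames(lsym$m, lsym$lag_samples)
  for (l in 1:4) expect_equal(m[[as.character(l)]], m[[as.character(-l)]])
})

test_that("classification endurance counts contiguous half-excess runs", {
  # hand-countable: diag excess 0.08, forward excesses .07 .05 .03 .01
  chance <- 0.125
  v <- matrix(chance, 5, 5)
  diag(v) <- chance + 0.08
  v[1, 2:5] <- chance + c(0.07, 0.05, 0.03, 0.01)
  prof <- classification_endurance(make_gm(v), chance)
  expect_equal(prof$ce_forward[1], 2L) # .07, .05 >= .04; .03 breaks the run
  expect_equal(prof$ce_backward[1], 0L)
  # flat above-chance matrix: endurance runs to the epoch edges
  flat <- make_gm(matrix(chance + 0.05, 6, 6))
  pf <- classification_endurance(flat, chance)
  expect_equal(pf$ce_forward, c(5:0))
  expect_equal(pf$ce_backward, c(0:5))
  expect_equal(pf$ce_forward_ms, pf$ce_forward * 1000 / 64)
  # at/below-chance training times are flagged undefined, not zeroed
  v2 <- matrix(chance + 0.05, 4, 4)
  v2[2, 2] <- chance
  p2 <- classification_endurance(make_gm(v2), chance)
  expect_false(p2$defined[2])
  expect_true(is.na(p2$ce_forward[2]))
  # an isolated sub-threshold dip terminates the run
  v3 <- matrix(chance, 5, 5)
  diag(v3) <- chance + 0.1
  v3[1, 2:5] <- chance + c(0.09, 0.02, 0.09, 0.09)
  expect_equal(classification_endurance(make_gm(v3), chance)$ce_forward[1], 1L)
})

test_that("endurance equals an exhaustive run-length oracle and shift invariance holds", {
  oracle_ce <- function(v, chance) {
    n <- nrow(v)
    t(vapply(seq_len(n), function(t) {
      e <- v[t, t] - chance
      if (e <= 0) {
        return(c(NA_integer_, NA_integer_))
      }
      fw <- 0L
      for (i in seq_len(n - t)) {
        if (v[t, t + i] - chance >= e / 2) fw <- i else break
      }
      bw <- 0L
      for (i in seq_len(t - 1L)) {
        if (v[t, t - i] - chance >= e / 2) bw <- i else break
      }
      c(fw, bw)
    }, integer(2)))
  }
  withr::with_seed(31, {
    for (rep in 1:50) {
      n <- sample(3:10, 1)
      v <- matrix(stats::runif(n * n, 0.05, 0.35), n, n)
      prof <- classification_endurance(make_gm(v), 0.125)
      orc <- oracle_ce(v, 0.125)
      expect_identical(cbind(prof$ce_forward, prof$ce_backward), unname(orc))
      # invariance: shifting matrix and chance together changes nothing
      prof2 <- classification_endurance(make_gm(v + 0.2), 0.125 + 0.2)
      expect_identical(prof$ce_forward, prof2$ce_forward)
      expect_identical(prof$ce_backward, prof2$ce_backward)
    }
  })
})

test_that("timeframe binning averages defined training times in five late bins", {
  n <- 64
  v <- matrix(0.125 + 0.05, n, n)
  gm <- make_gm(v, sfreq = 64, t0 = 0)
  prof <- classification_endurance(gm, 0.125)
  tf <- ce_timeframes(prof, window = c(272, 800), n_bins = 5)
  expect_equal(nrow(tf), 5)
  expect_equal(tf$from_ms, seq(272, 800, length.out = 6)[1:5])
  # flat matrix endurance decreases toward the epoch end, so binned
  # forward endurance must decrease across timeframes
  expect_true(all(diff(tf$ce_forward_ms) < 0))
})

test_that("endurance ANOVA: balanced input required, effects and contrasts recovered", {
  grid <- tidyr::expand_grid(
    replicate = 1:10,
    visibility = c("seen", "unseen"),
    direction = c("forward", "backward"),
    timeframe = paste0("tf", 1:5)
  )
  # zero-variance table: every F reported as no effect
  flat <- dplyr::mutate(grid, ce_ms = 100)
  a0 <- ce_anova(flat)
  expect_true(all(a0$effects$F == 0))
  expect_true(all(a0$effects$p == 1))
  # injected visibility main effect, small noise: significant at 0.01,
  # and the planned forward contrast points the right way
  withr::with_seed(12, {
    tab <- dplyr::mutate(grid,
      ce_ms = 100 + ifelse(visibility == "unseen", 40, 0) +
        stats::rnorm(dplyr::n(), 0, 4) + rep(stats::rnorm(10, 0, 6), each = 20)
    )
  })
  a1 <- ce_anova(tab)
  vis <- dplyr::filter(a1$effects, term == "visibility")
  expect_lt(vis$p, 0.01)
  expect_equal(vis$df1, 1)
  expect_equal(vis$df2, 9)
  fwd <- dplyr::filter(a1$contrasts, startsWith(contrast, "forward"))
  expect_lt(fwd$p, 0.05)
  expect_error(ce_anova(tab[-1, ]), "balanced")
})

test_that("permuting condition labels within replicate gives uniform ANOVA p-values", {
  grid <- tidyr::expand_grid(
    replicate = 1:8,
    visibility = c("seen", "unseen"),
    direction = c("forward", "backward"),
    timeframe = paste0("tf", 1:3)
  )
  pvals <- withr::with_seed(77, {
    vapply(1:200, function(i) {
      tab <- dplyr::mutate(grid, ce_ms = stats::rnorm(nrow(grid), 100, 10))
      a <- ce_anova(tab)
      dplyr::filter(a$effects, term == "visibility")$p
    }, numeric(1))
  })
  ks <- stats::ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.01)
})
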