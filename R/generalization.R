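#' Cross-condition generalization curves
#'
#' The asymmetry test: per time sample, a decoder is trained on the k-1
#' training folds of one perceptual condition and evaluated on (a) the
#' held-out fold of the same condition (the *within* curve) and (b) the
#' trials of the other condition (the *transfer* curve, with every
#' transfer trial scored by each of the k fold models and the k posteriors
#' averaged). Training on unseen-correct trials transferring fully to
#' seen-correct trials, while the converse drops late, is the signature of
#' conscious codes containing the unconscious ones plus more.
#'
#' Conditions must be disjoint trial sets. As a degenerate check,
#' `cond_test` identical to `cond_train` is allowed: transfer is then
#' evaluated on the held-out folds only (self-transfer) and reproduces the
#' within curve.
#'
#' @param epochs An `epoch_set`.
#' @param labels As in [decode_timecourse()] (class per trial of `epochs`).
#' @param cond_train,cond_test Logical trial masks over `epochs` selecting
#'   the training and transfer conditions.
#' @param folds Optional [assign_folds()] over the *training-condition*
#'   trials; default built from `k` and `seed`.
#' @param k,seed Fold parameters.
#' @param tolerance SMO tolerance, as in [decode_timecourse()].
#' @return A tibble with columns `curve` (`"within"`/`"transfer"`),
#'   `time_ms`, `mean`, `sem`, `n`.
#' @export
cross_condition_curves <- function(epochs, labels, cond_train, cond_test,
                                   folds = NULL, k = 15, seed = 1L,
                                   tolerance = 0.01) {
  y <- resolve_labels(epochs, labels)
  idx_train <- which(cond_train)
  idx_test <- which(cond_test)
  self_transfer <- identical(idx_train, idx_test)
  if (!self_transfer && length(intersect(idx_train, idx_test))) {
    stop("`cond_train` and `cond_test` overlap; conditions must be disjoint",
      call. = FALSE
    )
  }
  if (!length(idx_train) || !length(idx_test)) {
    stop("both conditions must select at least one trial", call. = FALSE)
  }
  y_train <- droplevels(y[idx_train])
  y_test <- factor(as.character(y[idx_test]), levels = levels(y_train))
  if (anyNA(y_test)) stop("`cond_test` contains classes unseen in `cond_train`", call. = FALSE)
  if (is.null(folds)) folds <- assign_folds(length(idx_train), k = k, seed = seed)
  if (length(folds$fold) != length(idx_train)) {
    stop("`folds` must be assigned over the training-condition trials", call. = FALSE)
  }
  check_fold_coverage(y_train, folds)
  n_t <- length(epochs$times)
  within <- matrix(NA_real_, length(idx_train), n_t)
  transfer <- matrix(0, length(idx_test), n_t)
  ci_train <- as.integer(y_train)
  ci_test <- as.integer(y_test)
  for (t in seq_len(n_t)) {
    Xt <- epochs$data[, , t, drop = TRUE]
    if (is.null(dim(Xt))) Xt <- matrix(Xt, ncol = 1L)
    for (f in seq_len(folds$k)) {
      ho <- folds$fold == f
      fit <- fit_calibrated_svm(
        Xt[idx_train[!ho], , drop = FALSE], y_train[!ho],
        tolerance = tolerance
      )
      Pw <- predict_calibrated(fit, Xt[idx_train[ho], , drop = FALSE])
      within[ho, t] <- Pw[cbind(seq_len(sum(ho)), ci_train[ho])]
      if (self_transfer) {
        transfer[ho, t] <- within[ho, t]
      } else {
        Pt <- predict_calibrated(fit, Xt[idx_test, , drop = FALSE])
        transfer[, t] <- transfer[, t] +
          Pt[cbind(seq_along(idx_test), ci_test)] / folds$k
      }
    }
  }
  curve_tbl <- function(m, nm) {
    tibble::tibble(
      curve = nm,
      time_ms = epochs$times,
      mean = colMeans(m),
      sem = apply(m, 2L, stats::sd) / sqrt(nrow(m)),
      n = nrow(m)
    )
  }
  dplyr::bind_rows(curve_tbl(within, "within"), curve_tbl(transfer, "transfer"))
}

#' Temporal generalization matrix
#'
#' Trains a calibrated decoder at every time sample `t` (on the k-1
#' training folds) and tests it at every sample `t'` on the held-out fold,
#' yielding a train-time x test-time surface of mean correct-class
#' probability. A sustained static code produces a square above-chance
#' block; a chain of transient codes confines generalization to a diagonal
#' band. The matrix diagonal reproduces the [decode_timecourse()] curve
#' exactly when given the same folds.
#'
#' @inheritParams decode_timecourse
#' @return An object of class `generalization_matrix`: list with `values`
#'   (train x test matrix), `times`, `sfreq`, `folds`, `train_cond`,
#'   `test_cond`.
#' @param train_cond,test_cond Optional condition names stored for
#'   bookkeeping (e.g. `"seen"` -> `"seen"`).
#' @export
temporal_generalization_matrix <- function(epochs, labels, folds = NULL,
                                           k = 15, seed = 1L, tolerance = 0.01,
                                           train_cond = "all", test_cond = train_cond) {
  y <- resolve_labels(epochs, labels)
  if (nlevels(y) < 2L) stop("need at least 2 classes", call. = FALSE)
  n <- n_trials(epochs)
  if (is.null(folds)) folds <- assign_folds(n, k = k, seed = seed)
  check_fold_coverage(y, folds)
  n_t <- length(epochs$times)
  ci <- as.integer(y)
  values <- matrix(NA_real_, n_t, n_t)
  for (t in seq_len(n_t)) {
    Xt <- epochs$data[, , t, drop = TRUE]
    if (is.null(dim(Xt))) Xt <- matrix(Xt, ncol = 1L)
    cc <- matrix(NA_real_, n, n_t) # correct-class posterior, trials x test time
    for (f in seq_len(folds$k)) {
      ho <- which(folds$fold == f)
      tr <- which(folds$fold != f)
      fit <- fit_calibrated_svm(Xt[tr, , drop = FALSE], y[tr], tolerance = tolerance)
      # stack the held-out trials at every test sample into one prediction
      Xte <- matrix(
        aperm(epochs$data[ho, , , drop = FALSE], c(1L, 3L, 2L)),
        nrow = length(ho) * n_t
      )
      P <- predict_calibrated(fit, Xte)
      pc <- P[cbind(seq_len(nrow(P)), rep(ci[ho], times = n_t))]
      cc[ho, ] <- matrix(pc, nrow = length(ho))
    }
    values[t, ] <- colMeans(cc)
  }
  structure(
    list(
      values = values, times = epochs$times, sfreq = epochs$sfreq,
      folds = folds, train_cond = train_cond, test_cond = test_cond,
      n_classes = nlevels(y)
    ),
    class = "generalization_matrix"
  )
}

#' @export
print.generalization_matrix <- function(x, ...) {
  cat(sprintf(
    "<generalization_matrix> %d x %d samples, train `%s` -> test `%s`\n",
    nrow(x$values), ncol(x$values), x$train_cond, x$test_cond
  ))
  invisible(x)
}

#' Re-index a generalization matrix by lag
#'
#' Re-expresses the train x test surface as a function of training time
#' and the signed temporal distance `lag = t' - t` from it; lags that fall
#' outside the epoch are `NA`. The lag-0 column equals the matrix
#' diagonal.
#'
#' @param matrix A `generalization_matrix`.
#' @return A tibble with columns `train_ms`, `lag_samples`, `lag_ms`,
#'   `value`.
#' @export
recenter_by_lag <- function(matrix) {
  v <- matrix$values
  n_t <- nrow(v)
  step <- 1000 / matrix$sfreq
  purrr::map_dfr(seq_len(n_t), function(t) {
    lag <- seq_len(n_t) - t
    tibble::tibble(
      train_ms = matrix$times[t],
      lag_samples = (1L - t):(n_t - t),
      lag_ms = lag * step,
      value = v[t, ]
    )
  }) |>
    tidyr::complete(
      train_ms = matrix$times,
      lag_samples = (1L - n_t):(n_t - 1L)
    ) |>
    dplyr::mutate(lag_ms = .data$lag_samples * step)
}

#' Classification Endurance: the decoder half-life
#'
#' For each training time `t`, the number of *contiguous* samples forward
#' (and backward) in time over which off-diagonal decoding stays above 50%
#' of the diagonal's above-chance excess: with excess
#' `e(t) = values[t, t] - chance`, the forward endurance is the largest
#' `n` such that `values[t, t + i] - chance >= e(t) / 2` for every
#' `1 <= i <= n`. Measuring on the above-chance excess (not the raw
#' probability) is essential: half of a raw 8-class probability is below
#' chance, which would make a raw-level half-life infinite. Training times
#' whose diagonal is at or below chance have no defined half-life and are
#' flagged, not zeroed.
#'
#' @param matrix A `generalization_matrix`.
#' @param chance Chance probability (1/8 for the 8-class scheme, 1/2 for
#'   hemifield).
#' @return A tibble (class `endurance_profile`) with columns `train_ms`,
#'   `diag`, `excess`, `defined`, `ce_forward`, `ce_backward` (samples),
#'   `ce_forward_ms`, `ce_backward_ms`.
#' @export
classification_endurance <- function(matrix, chance) {
  v <- matrix$values
  n_t <- nrow(v)
  step <- 1000 / matrix$sfreq
  dg <- diag(v)
  excess <- dg - chance
  fw <- bw <- rep(NA_integer_, n_t)
  for (t in seq_len(n_t)) {
    if (excess[t] <= 0) next
    thr <- excess[t] / 2
    n <- 0L
    while (t + n + 1L <= n_t && v[t, t + n + 1L] - chance >= thr) n <- n + 1L
    fw[t] <- n
    n <- 0L
    while (t - n - 1L >= 1L && v[t, t - n - 1L] - chance >= thr) n <- n + 1L
    bw[t] <- n
  }
  out <- tibble::tibble(
    train_ms = matrix$times,
    diag = dg,
    excess = excess,
    defined = excess > 0,
    ce_forward = fw,
    ce_backward = bw,
    ce_forward_ms = fw * step,
    ce_backward_ms = bw * step
  )
  class(out) <- c("endurance_profile", class(out))
  out
}

#' Bin endurance values into the five late timeframes
#'
#' Averages a per-training-time endurance profile within 5 equal-width
#' half-open bins of the late window (272--800 ms by default), the
#' timeframe factor of the endurance ANOVA. Undefined training times are
#' dropped from the averages.
#'
#' @param profile An [classification_endurance()] profile.
#' @param window Late window in ms (default `c(272, 800)`).
#' @param n_bins Number of equal timeframes (default 5).
#' @return A tibble with columns `timeframe` (factor `tf1..tf5`),
#'   `from_ms`, `to_ms`, `ce_forward_ms`, `ce_backward_ms` (means).
#' @export
ce_timeframes <- function(profile, window = c(272, 800), n_bins = 5L) {
  edges <- seq(window[1L], window[2L], length.out = n_bins + 1L)
  purrr::map_dfr(seq_len(n_bins), function(b) {
    sub <- dplyr::filter(
      profile,
      .data$train_ms >= edges[b], .data$train_ms < edges[b + 1L], .data$defined
    )
    tibble::tibble(
      timeframe = factor(paste0("tf", b), levels = paste0("tf", seq_len(n_bins))),
      from_ms = edges[b],
      to_ms = edges[b + 1L],
      ce_forward_ms = mean(sub$ce_forward_ms),
      ce_backward_ms = mean(sub$ce_backward_ms)
    )
  })
}

#' Repeated-measures ANOVA on Classification Endurance
#'
#' Three-way within-subject ANOVA of endurance with factors Visibility
#' (seen/unseen), Direction (forward/backward) and Timeframe (the 5 late
#' bins), on a balanced full-factorial replicate table, plus the two
#' planned contrasts: forward seen vs unseen and backward seen vs unseen
#' (paired t).
#'
#' @param ce_table Tibble with columns `replicate`, `visibility`,
#'   `direction`, `timeframe`, `ce_ms`; must be a complete balanced
#'   factorial (one cell value per replicate x condition).
#' @return A list of class `ce_anova` with `effects` (tibble: `term`,
#'   `df1`, `df2`, `F`, `p`) and `contrasts` (tibble: `contrast`, `mean_seen`,
#'   `mean_unseen`, `t`, `df`, `p`).
#' @export
ce_anova <- function(ce_table) {
  need <- c("replicate", "visibility", "direction", "timeframe", "ce_ms")
  stopifnot(all(need %in% names(ce_table)))
  tab <- dplyr::mutate(
    ce_table,
    replicate = factor(.data$replicate),
    visibility = factor(.data$visibility),
    direction = factor(.data$direction),
    timeframe = factor(.data$timeframe)
  )
  counts <- dplyr::count(tab, .data$visibility, .data$direction, .data$timeframe)
  n_rep <- nlevels(tab$replicate)
  if (n_rep < 2L) stop("need at least 2 replicates", call. = FALSE)
  if (nrow(counts) != nlevels(tab$visibility) * nlevels(tab$direction) *
    nlevels(tab$timeframe) || any(counts$n != n_rep)) {
    stop("`ce_table` must be a complete balanced factorial (no imputation is done)",
      call. = FALSE
    )
  }
  if (anyNA(tab$ce_ms)) stop("`ce_ms` contains NA; aggregate or drop before testing", call. = FALSE)
  if (stats::var(tab$ce_ms) == 0) {
    # fully degenerate table: every effect is exactly null; report as such
    # rather than letting 0/0 mean-square ratios surface as spurious F's
    terms <- c(
      "visibility", "direction", "timeframe",
      "visibility:direction", "visibility:timeframe",
      "direction:timeframe", "visibility:direction:timeframe"
    )
    eff <- tibble::tibble(
      term = terms, df1 = NA_real_, df2 = NA_real_, F = 0, p = 1
    )
    planned <- tibble::tibble(
      contrast = paste0(levels(tab$direction), ": zero-variance"),
      mean_a = mean(tab$ce_ms), mean_b = mean(tab$ce_ms),
      t = 0, df = n_rep - 1L, p = 1
    )
    return(structure(list(effects = eff, contrasts = planned), class = "ce_anova"))
  }
  fit <- stats::aov(
    ce_ms ~ visibility * direction * timeframe +
      Error(replicate / (visibility * direction * timeframe)),
    data = tab
  )
  eff <- purrr::map_dfr(summary(fit), function(stratum) {
    st <- stratum[[1L]]
    terms <- trimws(rownames(st))
    keep <- terms != "Residuals"
    if (!any(keep)) {
      return(tibble::tibble())
    }
    resid_df <- st[terms == "Residuals", "Df"]
    tibble::tibble(
      term = terms[keep],
      df1 = st[keep, "Df"],
      df2 = resid_df,
      F = st[keep, "F value"],
      p = st[keep, "Pr(>F)"]
    )
  })
  eff <- dplyr::filter(eff, !is.na(.data$df1))
  # zero-variance degenerate tables: no resolvable effects
  eff$F[is.nan(eff$F)] <- 0
  eff$p[is.nan(eff$p) | is.na(eff$p) & eff$F == 0] <- 1

  planned <- purrr::map_dfr(levels(tab$direction), function(dir) {
    wide <- tab |>
      dplyr::filter(.data$direction == dir) |>
      dplyr::group_by(.data$replicate, .data$visibility) |>
      dplyr::summarise(ce_ms = mean(.data$ce_ms), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "visibility", values_from = "ce_ms")
    vis <- setdiff(names(wide), "replicate")
    res <- paired_t(wide[[vis[1L]]], wide[[vis[2L]]], "two.sided")
    tibble::tibble(
      contrast = paste0(dir, ": ", vis[1L], " vs ", vis[2L]),
      mean_a = mean(wide[[vis[1L]]]),
      mean_b = mean(wide[[vis[2L]]]),
      t = res[["t"]],
      df = nrow(wide) - 1L,
      p = res[["p"]]
    )
  })
  structure(list(effects = eff, contrasts = planned), class = "ce_anova")
}

#' @export
print.ce_anova <- function(x, ...) {
  cat("<ce_anova> within-subject Visibility x Direction x Timeframe\n")
  print(x$effects)
  cat("planned contrasts:\n")
  print(x$contrasts)
  invisible(x)
}
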