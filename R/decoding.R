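#' Random non-overlapping fold assignment
#'
#' Partitions trials into `k` non-overlapping folds of as-equal-as-possible
#' size (sizes differ by at most one), uniformly at random, deterministic
#' given `seed`.
#'
#' @param n_trials Number of trials (must be at least `k`).
#' @param k Number of folds (default 15).
#' @param seed Integer seed.
#' @return An object of class `fold_assignment`: list with `fold`
#'   (integer vector over trials, values in `1..k`), `k`, `seed`.
#' @export
assign_folds <- function(n_trials, k = 15, seed) {
  if (n_trials < k) {
    stop("`n_trials` (", n_trials, ") must be at least `k` (", k, ")", call. = FALSE)
  }
  fold <- with_seed(seed, sample(rep(seq_len(k), length.out = n_trials)))
  structure(list(fold = fold, k = as.integer(k), seed = as.integer(seed)),
    class = "fold_assignment"
  )
}

# internal: resolve a labels argument (trial-table column name or vector)
# to a factor over trials
resolve_labels <- function(epochs, labels) {
  y <- if (is.character(labels) && length(labels) == 1L) {
    if (!labels %in% names(epochs$trials)) {
      stop("`labels` column `", labels, "` not in the trial table", call. = FALSE)
    }
    epochs$trials[[labels]]
  } else {
    labels
  }
  if (length(y) != n_trials(epochs)) {
    stop("`labels` must have one value per trial", call. = FALSE)
  }
  if (anyNA(y)) stop("`labels` contains missing values; filter those trials first", call. = FALSE)
  droplevels(as.factor(y))
}

# internal: check every fold-complement contains every class
check_fold_coverage <- function(y, folds) {
  for (f in seq_len(folds$k)) {
    ytr <- y[folds$fold != f]
    absent <- setdiff(levels(y), unique(as.character(ytr)))
    if (length(absent)) {
      stop("class(es) ", paste(absent, collapse = ", "),
        " absent from the training set of fold ", f,
        "; rebalance the trial selection (see `select_subset()`)",
        call. = FALSE
      )
    }
  }
  invisible(TRUE)
}

#' Per-timepoint cross-validated decoding
#'
#' Trains an independent calibrated linear SVM (C = 1) at every time
#' sample, using the z-scored channel vector at that single sample as the
#' feature set, under k-fold cross-validation: for each fold, the machine
#' is fitted on the other `k - 1` folds and scores the held-out trials, so
#' every trial receives, at every sample, calibrated class posteriors from
#' a model that was never trained on it.
#'
#' @param epochs An `epoch_set` (normally after [baseline_zscore()]).
#' @param labels Trial-table column name, or a vector/factor of per-trial
#'   class labels (e.g. `"location"`, or [hemifield_labels()] output).
#' @param folds A [assign_folds()] result, or `NULL` to create one from
#'   `k` and `seed`.
#' @param k,seed Fold parameters used when `folds` is `NULL`.
#' @param tolerance SMO convergence tolerance passed to the SVM (see the
#'   methods vignette for the numerical rationale).
#' @return An object of class `decoding_result`: list with `posteriors`
#'   (trials x classes x time array), `classes`, `labels` (the factor
#'   used), `folds`, `times`, `sfreq`, `classifier_spec`.
#' @export
decode_timecourse <- function(epochs, labels, folds = NULL, k = 15, seed = 1L,
                              tolerance = 0.01) {
  y <- resolve_labels(epochs, labels)
  if (nlevels(y) < 2L) stop("need at least 2 classes", call. = FALSE)
  n <- n_trials(epochs)
  if (is.null(folds)) folds <- assign_folds(n, k = k, seed = seed)
  if (length(folds$fold) != n) stop("`folds` does not match the trial count", call. = FALSE)
  check_fold_coverage(y, folds)
  n_t <- length(epochs$times)
  kc <- nlevels(y)
  post <- array(NA_real_, dim = c(n, kc, n_t), dimnames = list(NULL, levels(y), NULL))
  for (t in seq_len(n_t)) {
    Xt <- epochs$data[, , t, drop = TRUE]
    if (is.null(dim(Xt))) Xt <- matrix(Xt, ncol = 1L)
    for (f in seq_len(folds$k)) {
      te <- which(folds$fold == f)
      tr <- which(folds$fold != f)
      fit <- fit_calibrated_svm(Xt[tr, , drop = FALSE], y[tr], tolerance = tolerance)
      post[te, , t] <- predict_calibrated(fit, Xt[te, , drop = FALSE])
    }
  }
  structure(
    list(
      posteriors = post, classes = levels(y), labels = y, folds = folds,
      times = epochs$times, sfreq = epochs$sfreq,
      classifier_spec = list(
        kernel = "linear", cost = 1, calibration = "platt+pairwise-coupling",
        tolerance = tolerance
      )
    ),
    class = "decoding_result"
  )
}

#' @export
print.decoding_result <- function(x, ...) {
  d <- dim(x$posteriors)
  cat(sprintf(
    "<decoding_result> %d trials, %d classes (%s), %d samples, k = %d\n",
    d[1L], d[2L], paste(x$classes, collapse = ", "), d[3L], x$folds$k
  ))
  invisible(x)
}

# internal: trials x time matrix of the posterior assigned to each trial's
# true class
correct_class_matrix <- function(result) {
  ci <- match(as.character(result$labels), result$classes)
  n <- dim(result$posteriors)[1L]
  n_t <- dim(result$posteriors)[3L]
  out <- matrix(NA_real_, n, n_t)
  for (i in seq_len(n)) out[i, ] <- result$posteriors[i, ci[i], ]
  out
}

#' Correct-class probability time series by condition
#'
#' The classifier's assigned probability for the true class of each trial,
#' averaged within conditions: the basic decoding curve, split e.g. into
#' seen-correct and unseen-correct trials.
#'
#' @param result A [decode_timecourse()] result.
#' @param conditions Named list of logical trial masks (each of length
#'   `n_trials`); `NULL` gives a single `"all"` condition.
#' @return A tibble with columns `condition`, `time_ms`, `mean`, `sem`, `n`.
#' @export
correct_class_series <- function(result, conditions = NULL) {
  cc <- correct_class_matrix(result)
  if (is.null(conditions)) conditions <- list(all = rep(TRUE, nrow(cc)))
  if (is.null(names(conditions)) || any(!nzchar(names(conditions)))) {
    stop("`conditions` must be a named list", call. = FALSE)
  }
  purrr::map_dfr(names(conditions), function(nm) {
    mask <- conditions[[nm]]
    if (!any(mask)) stop("condition `", nm, "` selects no trials", call. = FALSE)
    m <- cc[mask, , drop = FALSE]
    tibble::tibble(
      condition = nm,
      time_ms = result$times,
      mean = colMeans(m),
      sem = apply(m, 2L, stats::sd) / sqrt(nrow(m)),
      n = nrow(m)
    )
  })
}

#' Posterior mass by circular distance from the true location
#'
#' For the 8-class circular location scheme, groups each trial's posterior
#' mass by the circular distance (0--4 steps of 45 degrees) between a class
#' and the trial's true location; the two symmetric neighbors at distances
#' 1, 2 and 3 are pooled (summed), so a flat posterior yields the mass
#' profile (0.125, 0.25, 0.25, 0.25, 0.125).
#'
#' @param result A [decode_timecourse()] result whose classes are the 8
#'   locations `1..8`.
#' @return A tibble with columns `distance`, `time_ms`, `mean`, `sem`.
#' @export
distance_profile <- function(result) {
  if (!identical(sort(result$classes), as.character(1:8))) {
    stop("`distance_profile()` requires the 8 circular location classes 1..8",
      call. = FALSE
    )
  }
  cls <- as.integer(result$classes)
  truth <- as.integer(as.character(result$labels))
  n <- dim(result$posteriors)[1L]
  n_t <- dim(result$posteriors)[3L]
  mass <- array(0, dim = c(n, 5L, n_t))
  for (i in seq_len(n)) {
    dd <- abs(cls - truth[i])
    dd <- pmin(dd, 8L - dd)
    for (d in 0:4) {
      sel <- which(dd == d)
      mass[i, d + 1L, ] <- if (length(sel) == 1L) {
        result$posteriors[i, sel, ]
      } else {
        colSums(result$posteriors[i, sel, , drop = TRUE])
      }
    }
  }
  purrr::map_dfr(0:4, function(d) {
    m <- mass[, d + 1L, , drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, nrow = n)
    tibble::tibble(
      distance = d,
      time_ms = result$times,
      mean = colMeans(m),
      sem = apply(m, 2L, stats::sd) / sqrt(n)
    )
  })
}

#' Chance correction of the correct-trial decoding curve
#'
#' On unseen trials a fraction of correct responses are lucky guesses, and
#' those trials presumably carry only incorrect-trial-level stimulus
#' information. Assuming guesses land on the correct location with
#' probability `1/n_classes`, the number of guess trials among the
#' responses is estimated as `g = n_incorrect * n_classes / (n_classes - 1)`,
#' of which `g / n_classes` contaminate the correct set; their expected
#' contribution (at the incorrect-trial decoding level) is subtracted:
#' `corrected = (n_correct * correct - (g/n_classes) * incorrect) /
#' (n_correct - g/n_classes)`.
#'
#' @param series_correct,series_incorrect Numeric decoding series (same
#'   length) for correct and incorrect trials of the condition.
#' @param n_correct,n_incorrect Trial counts behind the two series.
#' @param n_classes Number of response classes (default 8).
#' @return Numeric vector: the corrected series for informed trials.
#' @export
chance_corrected_mean <- function(series_correct, series_incorrect,
                                  n_correct, n_incorrect, n_classes = 8) {
  if (n_correct <= 0 || n_incorrect < 0) stop("counts must be positive", call. = FALSE)
  if (length(series_correct) != length(series_incorrect)) {
    stop("series must have equal length", call. = FALSE)
  }
  if (n_incorrect == 0) {
    return(series_correct)
  }
  lucky <- n_incorrect / (n_classes - 1) # = g / n_classes
  informed <- n_correct - lucky
  if (informed <= 0) {
    stop("estimated lucky-guess count (", round(lucky, 2),
      ") is not below `n_correct` (", n_correct, "); correction is degenerate",
      call. = FALSE
    )
  }
  (n_correct * series_correct - lucky * series_incorrect) / informed
}

#' Stage-window statistics of decoding curves
#'
#' Collapses per-replicate decoding curves into the named analysis windows
#' and tests them against chance (one-sample t) and against each other
#' (paired t for requested condition pairs).
#'
#' @param series Tibble with columns `replicate`, `condition`, `time_ms`,
#'   `value` -- one decoding curve per replicate and condition.
#' @param windows Named list of half-open ms windows (default
#'   [stage_windows()]).
#' @param chance Chance probability (e.g. 1/8 or 1/2).
#' @param contrasts List of length-2 character vectors naming condition
#'   pairs for paired tests (e.g. `list(c("seen", "unseen"))`).
#' @param alternative Test sidedness for the paired contrasts, passed to
#'   [stats::t.test()] (`"two.sided"` default; one-tailed use is flagged in
#'   the output).
#' @return A tibble with one row per (window, condition) and per
#'   (window, contrast): columns `window`, `condition`, `mean`, `sem`,
#'   `df`, `t`, `p`, `test`, `alternative`.
#' @export
window_stats <- function(series, windows = stage_windows(), chance,
                         contrasts = NULL, alternative = "two.sided") {
  stopifnot(all(c("replicate", "condition", "time_ms", "value") %in% names(series)))
  if (dplyr::n_distinct(series$replicate) < 2L) {
    stop("need at least 2 replicates", call. = FALSE)
  }
  rng <- range(series$time_ms)
  per_window <- purrr::map_dfr(names(windows), function(w) {
    win <- windows[[w]]
    if (win[1L] > rng[2L] || win[2L] <= rng[1L]) {
      stop("window `", w, "` [", win[1L], ", ", win[2L],
        ") lies outside the series time range",
        call. = FALSE
      )
    }
    sub <- dplyr::filter(series, .data$time_ms >= win[1L], .data$time_ms < win[2L])
    means <- dplyr::summarise(
      dplyr::group_by(sub, .data$replicate, .data$condition),
      value = mean(.data$value), .groups = "drop"
    )
    means$window <- w
    means
  })

  one_sample <- function(x) {
    n <- length(x)
    s <- stats::sd(x)
    if (s == 0) {
      if (isTRUE(all.equal(mean(x), chance))) {
        return(c(t = 0, p = 1))
      }
      warning("zero variance across replicates; reporting t = Inf, p = 0")
      return(c(t = sign(mean(x) - chance) * Inf, p = 0))
    }
    ht <- stats::t.test(x, mu = chance)
    c(t = unname(ht$statistic), p = ht$p.value)
  }

  vs_chance <- per_window |>
    dplyr::group_by(.data$window, .data$condition) |>
    dplyr::group_modify(function(g, key) {
      res <- one_sample(g$value)
      tibble::tibble(
        mean = mean(g$value),
        sem = stats::sd(g$value) / sqrt(nrow(g)),
        df = nrow(g) - 1L,
        t = res[["t"]], p = res[["p"]]
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(test = "vs_chance", alternative = "two.sided")

  rows <- list(vs_chance)
  for (ct in contrasts %||% list()) {
    wide <- per_window |>
      dplyr::filter(.data$condition %in% ct) |>
      tidyr::pivot_wider(names_from = "condition", values_from = "value")
    if (!all(ct %in% names(wide))) {
      stop("contrast condition(s) missing from `series`: ", paste(ct, collapse = " vs "),
        call. = FALSE
      )
    }
    paired <- wide |>
      dplyr::group_by(.data$window) |>
      dplyr::group_modify(function(g, key) {
        res <- paired_t(g[[ct[1L]]], g[[ct[2L]]], alternative)
        d <- g[[ct[1L]]] - g[[ct[2L]]]
        tibble::tibble(
          mean = mean(d),
          sem = stats::sd(d) / sqrt(nrow(g)),
          df = nrow(g) - 1L,
          t = res[["t"]], p = res[["p"]]
        )
      }) |>
      dplyr::ungroup() |>
      dplyr::mutate(
        condition = paste(ct, collapse = " - "),
        test = "paired", alternative = alternative
      )
    rows <- c(rows, list(paired))
  }
  dplyr::bind_rows(rows)
}

# internal: paired t with the degenerate zero-variance case handled
paired_t <- function(a, b, alternative) {
  d <- a - b
  if (stats::sd(d) == 0) {
    if (isTRUE(all.equal(mean(d), 0)) || mean(d) == 0) {
      return(c(t = 0, p = 1))
    }
    warning("zero variance of paired differences; reporting t = Inf, p = 0")
    return(c(t = sign(mean(d)) * Inf, p = 0))
  }
  ht <- stats::t.test(a, b, paired = TRUE, alternative = alternative)
  c(t = unname(ht$statistic), p = ht$p.value)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
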