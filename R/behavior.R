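#' Simulated observer for masked-location detection
#'
#' Parameterizes the behavioral model of a participant in the masked
#' spatial-localization task: a logistic psychometric function mapping mask
#' contrast to the probability of reporting the target as seen, and
#' separate localization accuracies for seen and unseen reports. Unseen
#' accuracy far above the 1/8 guessing level is the blindsight regime the
#' analysis depends on.
#'
#' @param contrast_threshold Mask contrast (0--255 pixel-intensity scale) at
#'   which `p(seen) = 0.5`. Stronger masks (higher contrast) yield fewer
#'   seen reports.
#' @param psychometric_slope Scale (in contrast units) of the logistic;
#'   smaller is steeper.
#' @param p_correct_seen Probability of correct localization on seen trials.
#' @param p_correct_unseen Probability of correct localization on unseen
#'   trials; must satisfy `p_correct_seen >= p_correct_unseen >= 1/8`
#'   unless `guess_uniform`.
#' @param guess_uniform If `TRUE` the observer localizes by guessing
#'   uniformly over the 8 responses on every trial (accuracy 1/8);
#'   `p_correct_*` are ignored.
#' @param p_detect_error Probability that, on a seen but mislocalized
#'   trial, the observer detects the localization error (used by the
#'   staircase's definition of a calibration "seen" trial).
#'
#' @return An object of class `observer_model`.
#' @export
observer_model <- function(contrast_threshold = 131,
                           psychometric_slope = 20,
                           p_correct_seen = 0.866,
                           p_correct_unseen = 0.507,
                           guess_uniform = FALSE,
                           p_detect_error = 1) {
  probs <- c(p_correct_seen, p_correct_unseen, p_detect_error)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]", call. = FALSE)
  if (!guess_uniform && !(p_correct_seen >= p_correct_unseen && p_correct_unseen >= 1 / 8)) {
    stop("blindsight regime requires p_correct_seen >= p_correct_unseen >= 1/8",
      call. = FALSE
    )
  }
  if (guess_uniform) p_correct_unseen <- 1 / 8
  structure(
    list(
      contrast_threshold = contrast_threshold,
      psychometric_slope = psychometric_slope,
      p_correct_seen = p_correct_seen,
      p_correct_unseen = p_correct_unseen,
      guess_uniform = guess_uniform,
      p_detect_error = p_detect_error
    ),
    class = "observer_model"
  )
}

#' Psychometric function: probability of a seen report
#'
#' Logistic in mask contrast, decreasing: at `contrast_threshold` the
#' probability is exactly 0.5, and stronger masks push it toward 0.
#'
#' @param observer An [observer_model()].
#' @param contrast Mask contrast value(s) on the 0--255 scale.
#' @return Probability vector.
#' @export
p_seen <- function(observer, contrast) {
  stats::plogis(-(contrast - observer$contrast_threshold) / observer$psychometric_slope)
}

#' Simulate behavioral trials
#'
#' Draws one trial table from the observer model at a fixed mask contrast:
#' a uniform stimulus location in 1..8, a Bernoulli seen report from the
#' psychometric function, and a localization response that is correct with
#' the visibility-specific accuracy and otherwise uniform over the 7
#' remaining locations. An optional fraction of target-absent catch trials
#' carries no stimulus (`location = NA`) and a uniform guessed response.
#'
#' @param observer An [observer_model()].
#' @param contrast Mask contrast in `[0, 255]`.
#' @param n_trials Number of trials (> 0).
#' @param seed Integer seed; the draw is deterministic given it.
#' @param p_absent Proportion of target-absent catch trials (default 0).
#' @return A tibble with columns `trial`, `location`, `seen`, `response`,
#'   `correct`, `target_present`, `detected_error`.
#' @export
simulate_behavior <- function(observer, contrast, n_trials, seed, p_absent = 0) {
  if (contrast < 0 || contrast > 255) {
    stop("`contrast` must lie in the 0..255 intensity range", call. = FALSE)
  }
  if (n_trials <= 0) stop("`n_trials` must be positive", call. = FALSE)
  with_seed(seed, {
    present <- stats::runif(n_trials) >= p_absent
    location <- ifelse(present, sample(1:8, n_trials, replace = TRUE), NA_integer_)
    seen <- ifelse(present, stats::runif(n_trials) < p_seen(observer, contrast), FALSE)
    response <- integer(n_trials)
    if (observer$guess_uniform) {
      response <- sample(1:8, n_trials, replace = TRUE)
    } else {
      p_corr <- ifelse(seen, observer$p_correct_seen, observer$p_correct_unseen)
      hit <- stats::runif(n_trials) < p_corr
      for (i in seq_len(n_trials)) {
        if (!present[i]) {
          response[i] <- sample(1:8, 1L)
        } else if (hit[i]) {
          response[i] <- location[i]
        } else {
          response[i] <- sample(setdiff(1:8, location[i]), 1L)
        }
      }
    }
    correct <- ifelse(present, response == location, NA)
    detected_error <- ifelse(
      present & seen & !is.na(correct) & !correct,
      stats::runif(n_trials) < observer$p_detect_error,
      FALSE
    )
    tibble::tibble(
      trial = seq_len(n_trials),
      location = as.integer(location),
      seen = as.logical(seen),
      response = as.integer(response),
      correct = as.logical(correct),
      target_present = as.logical(present),
      detected_error = as.logical(detected_error)
    )
  })
}

#' Behavioral confusion matrices by visibility
#'
#' The derived 8 x 8 location-by-response view of a trial table, split by
#' visibility report. Rows (true locations) are normalized to sum to 1, so
#' a diagonal-dominant unseen matrix is the behavioral signature of
#' blindsight.
#'
#' @param trials Trial table from [simulate_behavior()] (target-absent
#'   trials are excluded).
#' @param normalize Divide each row by its count (default `TRUE`).
#' @return A tibble with columns `seen`, `location`, `response`, `n`,
#'   `prop` (long form; use [tidyr::pivot_wider()] for matrices).
#' @export
behavioral_confusion <- function(trials, normalize = TRUE) {
  tr <- dplyr::filter(trials, .data$target_present)
  grid <- tidyr::expand_grid(
    seen = c(FALSE, TRUE), location = 1:8, response = 1:8
  )
  counts <- dplyr::count(tr, .data$seen, .data$location, .data$response)
  out <- dplyr::left_join(grid, counts, by = c("seen", "location", "response"))
  out$n[is.na(out$n)] <- 0L
  out <- dplyr::group_by(out, .data$seen, .data$location)
  out <- dplyr::mutate(out, prop = if (normalize) .data$n / max(1L, sum(.data$n)) else .data$n)
  dplyr::ungroup(out)
}
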