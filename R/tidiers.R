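#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a decoding result into a long tibble
#'
#' @param x A [decode_timecourse()] result.
#' @param ... Unused.
#' @return A tibble with columns `trial`, `time_ms`, `class`, `posterior`,
#'   `true_class`, `fold`.
#' @method tidy decoding_result
#' @export
tidy.decoding_result <- function(x, ...) {
  d <- dim(x$posteriors)
  tibble::tibble(
    trial = rep(seq_len(d[1L]), times = d[2L] * d[3L]),
    class = rep(rep(x$classes, each = d[1L]), times = d[3L]),
    time_ms = rep(x$times, each = d[1L] * d[2L]),
    posterior = as.vector(x$posteriors),
    true_class = rep(as.character(x$labels), times = d[2L] * d[3L]),
    fold = rep(x$folds$fold, times = d[2L] * d[3L])
  )
}

#' One-row summary of a decoding result
#'
#' @param x A [decode_timecourse()] result.
#' @param ... Unused.
#' @return A one-row tibble: `n_trials`, `n_classes`, `n_samples`, `k`,
#'   `chance`, `mean_correct` (correct-class posterior averaged over
#'   trials and time).
#' @method glance decoding_result
#' @export
glance.decoding_result <- function(x, ...) {
  d <- dim(x$posteriors)
  tibble::tibble(
    n_trials = d[1L],
    n_classes = d[2L],
    n_samples = d[3L],
    k = x$folds$k,
    chance = 1 / d[2L],
    mean_correct = mean(correct_class_matrix(x))
  )
}

#' Tidy a temporal generalization matrix
#'
#' @param x A [temporal_generalization_matrix()] result.
#' @param ... Unused.
#' @return A tibble with columns `train_ms`, `test_ms`, `value`.
#' @method tidy generalization_matrix
#' @export
tidy.generalization_matrix <- function(x, ...) {
  tibble::tibble(
    train_ms = rep(x$times, times = length(x$times)),
    test_ms = rep(x$times, each = length(x$times)),
    value = as.vector(x$values)
  )
}

#' One-row summary of a generalization matrix
#'
#' @param x A [temporal_generalization_matrix()] result.
#' @param ... Unused.
#' @return A one-row tibble: `n_samples`, `train_cond`, `test_cond`,
#'   `chance`, `mean_diag`, `mean_offdiag`.
#' @method glance generalization_matrix
#' @export
glance.generalization_matrix <- function(x, ...) {
  dg <- diag(x$values)
  off <- x$values[row(x$values) != col(x$values)]
  tibble::tibble(
    n_samples = nrow(x$values),
    train_cond = x$train_cond,
    test_cond = x$test_cond,
    chance = 1 / x$n_classes,
    mean_diag = mean(dg),
    mean_offdiag = mean(off)
  )
}

#' Tidy endurance ANOVA effects
#'
#' @param x A [ce_anova()] result.
#' @param ... Unused.
#' @return The effects tibble (`term`, `df1`, `df2`, `F`, `p`).
#' @method tidy ce_anova
#' @export
tidy.ce_anova <- function(x, ...) x$effects

#' Tidy a cluster permutation result
#'
#' @param x A [cluster_permutation_test()] result.
#' @param ... Unused.
#' @return The cluster tibble (empty when no cluster formed).
#' @method tidy cluster_result
#' @export
tidy.cluster_result <- function(x, ...) x$clusters
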