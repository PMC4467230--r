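#' Epoched MEG/EEG data container
#'
#' An `epoch_set` bundles a trials x channels x time numeric tensor with its
#' time base, sampling rate, channel metadata and an aligned trial table. It
#' is the common currency of every stage of the pipeline: the synthetic
#' generator produces one, preprocessing transforms one, and the decoders
#' consume one.
#'
#' @param data Numeric array with dimensions trials x channels x time.
#' @param times Numeric vector of sample times in milliseconds, strictly
#'   increasing and uniformly spaced at `1000 / sfreq`.
#' @param sfreq Sampling frequency in Hz.
#' @param channels Data frame with one row per channel and columns `name`,
#'   `type` (one of `"mag"`, `"grad"`, `"eeg"`, `"eog"`) and optionally
#'   `roi` (region-of-interest label for source-space data; `NA` otherwise).
#' @param trials Data frame with one row per trial. The conventional columns
#'   are `location` (stimulus position, 1--8 around the circle), `seen`
#'   (logical visibility report), `response` (localization response 1--8),
#'   `correct` (logical, `response == location`) and `target_present`
#'   (logical; on target-absent catch trials `location` and `correct` are
#'   `NA`). Extra columns are preserved.
#'
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, times, sfreq, channels, trials) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3-d array (trials x channels x time)", call. = FALSE)
  }
  channels <- tibble::as_tibble(channels)
  trials <- tibble::as_tibble(trials)
  if (!"roi" %in% names(channels)) channels$roi <- NA_character_
  x <- structure(
    list(
      data = data,
      times = as.numeric(times),
      sfreq = as.numeric(sfreq),
      channels = channels,
      trials = trials
    ),
    class = "epoch_set"
  )
  validate_epoch_set(x)
}

#' Validate an epoch_set
#'
#' Checks the structural invariants: tensor dimensions agree with the
#' lengths of `times`, `channels` and `trials`; times are strictly
#' increasing and uniformly spaced at `1/sfreq`; on target-present trials
#' `location` and `response` lie in 1..8 and `correct` equals
#' `response == location`.
#'
#' @param x An `epoch_set`.
#' @return `x`, invisibly unchanged, or an error.
#' @export
validate_epoch_set <- function(x) {
  d <- dim(x$data)
  if (d[1L] != nrow(x$trials)) {
    stop("trial dimension (", d[1L], ") does not match trial table (",
      nrow(x$trials), " rows)",
      call. = FALSE
    )
  }
  if (d[2L] != nrow(x$channels)) {
    stop("channel dimension (", d[2L], ") does not match channel table (",
      nrow(x$channels), " rows)",
      call. = FALSE
    )
  }
  if (d[3L] != length(x$times)) {
    stop("time dimension (", d[3L], ") does not match times (",
      length(x$times), ")",
      call. = FALSE
    )
  }
  if (x$sfreq <= 0) stop("`sfreq` must be positive", call. = FALSE)
  if (length(x$times) > 1L) {
    dt <- diff(x$times)
    if (any(dt <= 0)) stop("`times` must be strictly increasing", call. = FALSE)
    step <- 1000 / x$sfreq
    if (max(abs(dt - step)) > 1e-6 * step) {
      stop("`times` must be uniformly spaced at 1000/sfreq ms", call. = FALSE)
    }
  }
  tr <- x$trials
  if (all(c("location", "response", "target_present") %in% names(tr))) {
    present <- which(!is.na(tr$target_present) & tr$target_present)
    loc <- tr$location[present]
    if (length(present) && (anyNA(loc) || any(loc < 1L | loc > 8L))) {
      stop("`location` must be in 1..8 on target-present trials", call. = FALSE)
    }
    if ("correct" %in% names(tr)) {
      bad <- tr$correct[present] != (tr$response[present] == loc)
      if (any(bad, na.rm = TRUE)) {
        stop("`correct` must equal `response == location` on target-present trials",
          call. = FALSE
        )
      }
    }
  }
  invisible(x)
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set> %d trials x %d channels x %d samples @ %g Hz (%.1f..%.1f ms)\n",
    d[1L], d[2L], d[3L], x$sfreq, x$times[1L], x$times[length(x$times)]
  ))
  tys <- table(x$channels$type)
  cat("  channels:", paste(sprintf("%s=%d", names(tys), tys), collapse = ", "), "\n")
  cat("  trial columns:", paste(names(x$trials), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.epoch_set <- function(x) dim(x$data)

#' Number of trials in an epoch_set
#' @param x An `epoch_set`.
#' @return Integer trial count.
#' @export
n_trials <- function(x) dim(x$data)[1L]

#' Index of the sample nearest a time point
#'
#' @param x An `epoch_set`.
#' @param ms Time in milliseconds.
#' @return Integer sample index.
#' @export
nearest_sample <- function(x, ms) which.min(abs(x$times - ms))

#' Logical mask of samples falling in a half-open time window
#'
#' Windows are half-open, `[from, to)`: the sample sitting exactly on a
#' boundary belongs to the earlier window, so adjacent stage windows
#' partition the samples with no overlap.
#'
#' @param x An `epoch_set` (or any list with a `times` field).
#' @param from,to Window edges in milliseconds.
#' @return Logical vector over samples.
#' @export
time_mask <- function(x, from, to) x$times >= from & x$times < to

#' Subset an epoch_set by trial and/or channel index
#'
#' Low-level positional subsetting; see [select_subset()] for the
#' filter/balance interface used by the analyses.
#'
#' @param x An `epoch_set`.
#' @param trials Integer (or logical) trial indices; `NULL` keeps all.
#' @param channels Integer (or logical) channel indices; `NULL` keeps all.
#' @param samples Integer (or logical) sample indices; `NULL` keeps all.
#' @return A new `epoch_set`.
#' @export
subset_epochs <- function(x, trials = NULL, channels = NULL, samples = NULL) {
  ti <- if (is.null(trials)) seq_len(dim(x$data)[1L]) else trials
  ci <- if (is.null(channels)) seq_len(dim(x$data)[2L]) else channels
  si <- if (is.null(samples)) seq_len(dim(x$data)[3L]) else samples
  if (is.logical(ti)) ti <- which(ti)
  if (is.logical(ci)) ci <- which(ci)
  if (is.logical(si)) si <- which(si)
  epoch_set(
    data = x$data[ti, ci, si, drop = FALSE],
    times = x$times[si],
    sfreq = x$sfreq,
    channels = x$channels[ci, , drop = FALSE],
    trials = x$trials[ti, , drop = FALSE]
  )
}

#' Crop an epoch_set to a time window
#'
#' Keeps the samples in the half-open window `[from, to)`.
#'
#' @param x An `epoch_set`.
#' @param from,to Window edges in ms.
#' @return A cropped `epoch_set`.
#' @export
crop_epochs <- function(x, from, to) {
  keep <- time_mask(x, from, to)
  if (!any(keep)) stop("crop window [", from, ", ", to, ") contains no samples", call. = FALSE)
  subset_epochs(x, samples = keep)
}

#' Left/right hemifield labels from circular locations
#'
#' The eight stimulus locations sit on a circle at 45 degree spacing;
#' locations 1--4 are taken as the left hemifield and 5--8 as the right.
#'
#' @param location Integer vector of locations in 1..8 (NA allowed).
#' @return Factor with levels `"left"`, `"right"`.
#' @export
hemifield_labels <- function(location) {
  stopifnot(all(is.na(location) | (location >= 1 & location <= 8)))
  factor(ifelse(location <= 4, "left", "right"), levels = c("left", "right"))
}

#' The four processing-stage windows
#'
#' Named half-open windows (ms) of the canonical stage segmentation of the
#' post-stimulus epoch: an at-chance first stage, an early peak stage, a
#' transition stage, and the late stage where conscious and unconscious
#' trials diverge.
#'
#' @return A named list of `c(from, to)` pairs in ms.
#' @export
stage_windows <- function() {
  list(
    stage1 = c(0, 115),
    stage2 = c(115, 162),
    stage3 = c(162, 271),
    stage4 = c(271, 800)
  )
}

# internal: restore-on-exit seeded evaluation
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}
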