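#' Baseline z-scoring of epochs
#'
#' Normalizes heterogeneous channel types (magnetometers, gradiometers,
#' EEG) onto a common scale: for each channel, the standard deviation of
#' its baseline samples pooled across *all* trials is estimated, and every
#' sample of that channel is divided by this one scalar. No mean is
#' subtracted by default (set `demean = TRUE` to also remove the pooled
#' baseline mean first). After one pass each channel's pooled baseline SD
#' is 1, so the operation is idempotent.
#'
#' @param epochs An `epoch_set`.
#' @param baseline Baseline window in ms, half-open `[from, to)`; default
#'   the full pre-stimulus period `c(-500, 0)`. Must contain at least two
#'   samples.
#' @param demean Also subtract the pooled baseline mean (default `FALSE`).
#' @return A normalized `epoch_set`.
#' @export
baseline_zscore <- function(epochs, baseline = c(-500, 0), demean = FALSE) {
  keep <- time_mask(epochs, baseline[1L], baseline[2L])
  if (sum(keep) < 2L) {
    stop("baseline window [", baseline[1L], ", ", baseline[2L],
      ") must contain at least 2 samples",
      call. = FALSE
    )
  }
  n_ch <- dim(epochs$data)[2L]
  out <- epochs$data
  for (j in seq_len(n_ch)) {
    base <- as.vector(epochs$data[, j, keep])
    s <- stats::sd(base)
    if (!is.finite(s) || s == 0) {
      stop("channel `", epochs$channels$name[j], "` has zero baseline SD", call. = FALSE)
    }
    if (demean) out[, j, ] <- out[, j, ] - mean(base)
    out[, j, ] <- out[, j, ] / s
  }
  epochs$data <- out
  epochs
}

#' Zero-phase low-pass filtering and downsampling
#'
#' Applies a zero-phase FIR low-pass (Hamming-window design, transition
#' bandwidth 25% of the cutoff) along the time axis of every
#' trial x channel series, then decimates to the target rate. The
#' filter is linear-phase and applied with its group delay compensated and
#' reflection padding at the edges, so no phase distortion is introduced.
#' The trial table is unchanged; the time base is re-derived from the kept
#' samples.
#'
#' @param epochs An `epoch_set`.
#' @param cutoff_hz Low-pass cutoff in Hz (default 30).
#' @param target_sfreq Output sampling rate in Hz (default 64); must divide
#'   the current rate and satisfy `cutoff_hz < target_sfreq / 2`.
#' @return A filtered, downsampled `epoch_set`.
#' @export
resample_lowpass <- function(epochs, cutoff_hz = 30, target_sfreq = 64) {
  fs <- epochs$sfreq
  if (target_sfreq > fs) stop("`target_sfreq` must not exceed the current rate", call. = FALSE)
  if (cutoff_hz >= target_sfreq / 2) {
    stop("`cutoff_hz` (", cutoff_hz, ") must be below the target Nyquist (",
      target_sfreq / 2, " Hz)",
      call. = FALSE
    )
  }
  ratio <- fs / target_sfreq
  if (abs(ratio - round(ratio)) > 1e-9) {
    stop("`sfreq` (", fs, ") must be an integer multiple of `target_sfreq` (",
      target_sfreq, ")",
      call. = FALSE
    )
  }
  ratio <- as.integer(round(ratio))
  if (ratio > 1L || cutoff_hz < fs / 2) {
    h <- design_lowpass_fir(cutoff_hz, fs)
    epochs$data <- filter_time_axis(epochs$data, h)
  }
  if (ratio > 1L) {
    keep <- seq(1L, dim(epochs$data)[3L], by = ratio)
    epochs$data <- epochs$data[, , keep, drop = FALSE]
    epochs$times <- epochs$times[keep]
    epochs$sfreq <- target_sfreq
  }
  validate_epoch_set(epochs)
  epochs
}

# internal: Hamming-window FIR low-pass, transition bandwidth 25% of cutoff
design_lowpass_fir <- function(cutoff_hz, sfreq) {
  trans <- 0.25 * cutoff_hz
  # Hamming window: transition width ~ 3.3 / N in normalized frequency
  n_taps <- ceiling(3.3 * sfreq / trans)
  if (n_taps %% 2L == 0L) n_taps <- n_taps + 1L # odd length -> integer delay
  signal::fir1(n_taps - 1L, cutoff_hz / (sfreq / 2), type = "low")
}

# internal: zero-phase FIR along dim 3 of a (trials x channels x time)
# array, via FFT convolution with reflection padding and delay removal
filter_time_axis <- function(data, h) {
  d <- dim(data)
  n_t <- d[3L]
  delay <- (length(h) - 1L) / 2L
  pad <- min(n_t - 1L, length(h))
  # series in columns: (time) x (trial*channel)
  x <- matrix(aperm(data, c(3L, 1L, 2L)), nrow = n_t)
  top <- x[pad:1L, , drop = FALSE]
  bot <- x[n_t:(n_t - pad + 1L), , drop = FALSE]
  xp <- rbind(2 * rep(1, pad) %o% x[1L, ] - top, x, 2 * rep(1, pad) %o% x[n_t, ] - bot)
  n_p <- nrow(xp)
  nfft <- stats::nextn(n_p + length(h) - 1L, 2L)
  H <- stats::fft(c(h, numeric(nfft - length(h))))
  X <- stats::mvfft(rbind(xp, matrix(0, nfft - n_p, ncol(xp))))
  y <- Re(stats::mvfft(X * H, inverse = TRUE)) / nfft
  y <- y[pad + delay + seq_len(n_t), , drop = FALSE]
  aperm(array(y, dim = c(n_t, d[1L], d[2L])), c(2L, 3L, 1L))
}

#' Subset and balance an epoch_set
#'
#' Tidy filtering of channels and trials plus seeded balancing. Channel and
#' trial filters are data-masked expressions evaluated in the channel and
#' trial tables. When `balance` names one or more trial factors, trials are
#' subsampled *without replacement* so that every factor cell retains
#' exactly the minimum cell count -- the procedure used to match trial
#' numbers across hemifield and visibility classes before the binary
#' decoders. The returned object carries an index map back to the input.
#'
#' @param epochs An `epoch_set`.
#' @param channels Filter expression on the channel table (e.g.
#'   `type == "eog"`); missing keeps all channels.
#' @param trials Filter expression on the trial table (e.g.
#'   `seen & correct`); missing keeps all trials.
#' @param balance Character vector of trial-table column names to balance
#'   over (each combination becomes a cell), or `NULL`.
#' @param seed Integer seed for the balancing subsample (required when
#'   `balance` is given).
#' @return An `epoch_set` with attribute `index_map`: a list with
#'   `trial_index` and `channel_index` giving, for each kept row, its index
#'   in the input object.
#' @export
select_subset <- function(epochs, channels, trials, balance = NULL, seed = NULL) {
  ch_idx <- seq_len(nrow(epochs$channels))
  tr_idx <- seq_len(nrow(epochs$trials))
  if (!missing(channels)) {
    keep <- rlang::eval_tidy(rlang::enquo(channels), data = epochs$channels)
    ch_idx <- ch_idx[keep %in% TRUE]
  }
  if (!missing(trials)) {
    keep <- rlang::eval_tidy(rlang::enquo(trials), data = epochs$trials)
    tr_idx <- tr_idx[keep %in% TRUE]
  }
  if (!is.null(balance)) {
    if (is.null(seed)) stop("`seed` is required when balancing", call. = FALSE)
    missing_cols <- setdiff(balance, names(epochs$trials))
    if (length(missing_cols)) {
      stop("balance column(s) not in trial table: ", paste(missing_cols, collapse = ", "),
        call. = FALSE
      )
    }
    tab <- epochs$trials[tr_idx, balance, drop = FALSE]
    cell <- interaction(tab, drop = FALSE, lex.order = TRUE)
    counts <- table(cell)
    empty <- names(counts)[counts == 0L]
    if (length(empty)) {
      stop("empty cell(s) under balancing: ", paste(empty, collapse = ", "), call. = FALSE)
    }
    m <- min(counts)
    tr_idx <- with_seed(seed, {
      picked <- unlist(lapply(split(tr_idx, cell), function(ix) {
        if (length(ix) == m) ix else sample(ix, m)
      }), use.names = FALSE)
      sort(picked)
    })
  }
  if (length(tr_idx) == 0L) stop("trial filter removed every trial", call. = FALSE)
  if (length(ch_idx) == 0L) stop("channel filter removed every channel", call. = FALSE)
  out <- subset_epochs(epochs, trials = tr_idx, channels = ch_idx)
  attr(out, "index_map") <- list(trial_index = tr_idx, channel_index = ch_idx)
  out
}
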