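# Shared fixtures, built in code.

# deterministic trial table: every location equally often
make_trials <- function(n, seen = TRUE, correct = TRUE) {
  loc <- rep(1:8, length.out = n)
  tibble::tibble(
    trial = seq_len(n),
    location = loc,
    seen = rep_len(seen, n),
    response = ifelse(rep_len(correct, n), loc, (loc %% 8L) + 1L),
    correct = rep_len(correct, n),
    target_present = TRUE
  )
}

# tiny epoch set with hand-set data
make_tiny_epochs <- function(n_trials = 8, n_channels = 3, n_samples = 20,
                             sfreq = 40, t0 = -100, data = NULL, trials = NULL) {
  if (is.null(data)) {
    data <- array(
      stats::rnorm(n_trials * n_channels * n_samples),
      dim = c(n_trials, n_channels, n_samples)
    )
  }
  epoch_set(
    data = data,
    times = t0 + (seq_len(n_samples) - 1L) * 1000 / sfreq,
    sfreq = sfreq,
    channels = tibble::tibble(
      name = paste0("ch", seq_len(n_channels)),
      type = rep(c("mag", "eeg"), length.out = n_channels),
      roi = NA_character_
    ),
    trials = if (is.null(trials)) make_trials(n_trials) else trials
  )
}

# hand-built decoding_result with specified posterior array
make_decoding_result <- function(posteriors, labels, times = NULL, sfreq = 64) {
  classes <- dimnames(posteriors)[[2]]
  structure(
    list(
      posteriors = posteriors,
      classes = classes,
      labels = factor(labels, levels = classes),
      folds = assign_folds(dim(posteriors)[1], k = 2, seed = 1),
      times = times %||% (seq_len(dim(posteriors)[3]) - 1) * 1000 / sfreq,
      sfreq = sfreq,
      classifier_spec = list()
    ),
    class = "decoding_result"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
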