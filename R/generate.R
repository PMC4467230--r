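#' Recipe for synthetic staged-location epochs
#'
#' Describes the neural structure the analysis assumes, so that epochs can
#' be synthesized with known ground truth. The model is a sequence of
#' location-specific spatial codes superposed on white channel noise:
#'
#' * **Stage 1** (0--115 ms): noise only; decoding sits at chance.
#' * **Stage 2** (115--162 ms): a location-specific spatial pattern ramps
#'   up linearly to a sharp peak at `early_peak_ms`, then relaxes to the
#'   sustained level.
#' * **Stage 3** (162--271 ms): the same pattern at the reduced sustained
#'   amplitude (`sustain_level` of peak).
#' * **Stage 4** (from 271 ms): on *all* trials the stage-3 pattern lingers
#'   while decaying exponentially with time constant `linger_decay_tau_ms`;
#'   on *seen* trials a chain of `chain_states` distinct metastable
#'   patterns, each active `state_duration_ms`, is additionally superposed
#'   at `seen_gain` times the sustained amplitude. Unseen trials carry only
#'   the single lingering code, so the set of codes active on unseen trials
#'   is a subset of those on seen trials.
#'
#' Spatial patterns are circularly tuned: each code stage has a pair of
#' random orthonormal "axis" maps, and the pattern of the location at
#' polar angle `theta` is the unit-norm combination
#' `cos(theta) A1 + sin(theta) A2 + kappa V_loc` with a location-unique
#' component `V_loc` weighted by `pattern_uniqueness`. Neighboring
#' locations are therefore more confusable than opposite ones (the
#' distance-graded confusion profile of real location codes) and the two
#' hemifields have linearly separable class means. Axis maps are
#' orthogonalized across code stages so successive metastable codes are
#' decodably distinct. All randomness is a pure function of `seed`.
#'
#' @param n_trials Default trial count when behavior is simulated inline.
#' @param n_channels Sensor channel count (excluding EOG channels).
#' @param sfreq Sampling rate in Hz.
#' @param epoch_window Epoch limits in ms, `c(from, to)`.
#' @param stage_windows Named list of half-open ms windows; see
#'   [stage_windows()] for the default segmentation.
#' @param early_peak_ms Latency of the sharp early decoding peak.
#' @param pattern_snr Peak signal amplitude in units of the nominal noise
#'   SD (0 gives pure noise).
#' @param noise_sd SD of the i.i.d. Gaussian channel noise (default 1;
#'   0 gives noiseless epochs for separability checks).
#' @param pattern_uniqueness Weight of the location-unique pattern
#'   component relative to the circular-tuning axes (see Details).
#' @param sustain_level Sustained (stage 3) amplitude as a fraction of the
#'   stage-2 peak.
#' @param seen_gain Multiplicative amplification of the stage-4 chain codes
#'   on seen trials, relative to the sustained amplitude.
#' @param chain_states Number of metastable codes in the seen stage-4 chain.
#' @param state_duration_ms Duration of each chain state in ms. The chain
#'   starts at the stage-4 onset and must fit inside the epoch.
#' @param linger_decay_tau_ms Exponential decay time constant of the
#'   lingering code in stage 4.
#' @param unseen_incorrect_snr Multiplier on the stimulus-locked signal for
#'   unseen-incorrect trials (1 = same signal as unseen-correct; the data
#'   do not constrain this, so it is exposed rather than assumed).
#' @param n_eog Number of EOG channels appended after the sensors.
#' @param eog_snr Amplitude of the weak location signal on EOG channels
#'   (identical for seen and unseen trials).
#' @param eog_window_ms Window in which the EOG location signal is active.
#' @param roi_onsets_ms Named vector mapping ROI name to the first latency
#'   at which that ROI carries location information (used by
#'   [generate_roi_epochs()]).
#' @param roi_n_channels Virtual source channels per ROI.
#' @param workspace_rois ROIs in which the seen-trial chain amplification
#'   applies (fronto-parietal "workspace" areas).
#' @param seed Integer seed governing patterns and noise.
#'
#' @return An object of class `signal_recipe`.
#' @export
signal_recipe <- function(n_trials = 400,
                          n_channels = 40,
                          sfreq = 64,
                          epoch_window = c(-500, 2000),
                          stage_windows = NULL,
                          early_peak_ms = 147,
                          pattern_snr = 1,
                          noise_sd = 1,
                          pattern_uniqueness = 0.5,
                          sustain_level = 0.5,
                          seen_gain = 2,
                          chain_states = 4,
                          state_duration_ms = 160,
                          linger_decay_tau_ms = 600,
                          unseen_incorrect_snr = 1,
                          n_eog = 0,
                          eog_snr = 0.25,
                          eog_window_ms = c(250, 1000),
                          roi_onsets_ms = c(
                            pericalcarine = 115,
                            superior_parietal = 115,
                            superior_frontal = 194,
                            rostral_medial_frontal = 365
                          ),
                          roi_n_channels = 12,
                          workspace_rois = c("superior_parietal", "superior_frontal"),
                          seed = 1L) {
  # NB: the argument shadows the helper's name, but R's call lookup skips
  # non-function bindings, so this resolves to the exported default.
  if (is.null(stage_windows)) stage_windows <- stage_windows()
  r <- structure(
    list(
      n_trials = n_trials, n_channels = n_channels, sfreq = sfreq,
      epoch_window = epoch_window, stage_windows = stage_windows,
      early_peak_ms = early_peak_ms, pattern_snr = pattern_snr,
      noise_sd = noise_sd, pattern_uniqueness = pattern_uniqueness,
      sustain_level = sustain_level, seen_gain = seen_gain,
      chain_states = chain_states, state_duration_ms = state_duration_ms,
      linger_decay_tau_ms = linger_decay_tau_ms,
      unseen_incorrect_snr = unseen_incorrect_snr,
      n_eog = n_eog, eog_snr = eog_snr, eog_window_ms = eog_window_ms,
      roi_onsets_ms = roi_onsets_ms, roi_n_channels = roi_n_channels,
      workspace_rois = workspace_rois, seed = as.integer(seed)
    ),
    class = "signal_recipe"
  )
  validate_signal_recipe(r)
}

validate_signal_recipe <- function(r) {
  if (r$sfreq <= 0) stop("`sfreq` must be positive", call. = FALSE)
  counts <- c(r$n_trials, r$n_channels, r$chain_states, r$roi_n_channels)
  if (any(counts <= 0)) stop("all counts must be positive", call. = FALSE)
  sw <- r$stage_windows
  edges <- do.call(rbind, sw)
  if (any(edges[, 1L] >= edges[, 2L])) stop("stage windows must be nonempty", call. = FALSE)
  if (any(edges[, 1L] < r$epoch_window[1L]) || any(edges[, 2L] > r$epoch_window[2L])) {
    stop("stage windows must lie inside the epoch window", call. = FALSE)
  }
  ord <- order(edges[, 1L])
  if (any(edges[ord[-1L], 1L] < edges[ord[-nrow(edges)], 2L])) {
    stop("stage windows must be disjoint and ordered", call. = FALSE)
  }
  chain_end <- edges[nrow(edges), 1L] + r$chain_states * r$state_duration_ms
  if (chain_end > r$epoch_window[2L]) {
    stop("chain of ", r$chain_states, " states x ", r$state_duration_ms,
      " ms does not fit between the stage-4 onset and the epoch end",
      call. = FALSE
    )
  }
  invisible(r)
}

# internal: uniformly spaced time base, left-aligned on the epoch start
recipe_times <- function(r) {
  step <- 1000 / r$sfreq
  n <- floor((r$epoch_window[2L] - r$epoch_window[1L]) / step)
  r$epoch_window[1L] + (seq_len(n) - 1L) * step
}

# internal: circularly tuned spatial patterns. One "set" per code stage
# (shared stage-2/3 code, then each chain state). Within a set, the
# pattern of location l at polar angle theta_l is
#   normalize( cos(theta_l) A1 + sin(theta_l) A2 + kappa V_l ),
# with the axis patterns A1, A2 orthonormalized across *all* sets (so
# successive metastable codes are decodably distinct) and V_l a unit-norm
# location-unique vector. The circular tuning makes neighboring locations
# more confusable than opposite ones and gives the two hemifields
# linearly separable class means; kappa sets how idiosyncratic each
# location is on top of that. Pure function of the seed.
# Returns a list over sets of 8 x n_channels matrices.
make_patterns <- function(n_sets, n_channels, seed, kappa = 0.5) {
  if (n_channels < 2L * n_sets) {
    stop("need at least ", 2L * n_sets, " channels for ", n_sets,
      " orthogonal pattern sets",
      call. = FALSE
    )
  }
  theta <- (22.5 + 45 * (0:7)) * pi / 180
  with_seed(seed, {
    axes <- qr.Q(qr(matrix(stats::rnorm(n_channels * 2L * n_sets), n_channels)))
    lapply(seq_len(n_sets), function(s) {
      a1 <- axes[, 2L * s - 1L]
      a2 <- axes[, 2L * s]
      p <- t(vapply(seq_len(8L), function(l) {
        v <- stats::rnorm(n_channels)
        v <- v / sqrt(sum(v^2))
        raw <- cos(theta[l]) * a1 + sin(theta[l]) * a2 + kappa * v
        raw / sqrt(sum(raw^2))
      }, numeric(n_channels)))
      p
    })
  })
}

# internal: shared-code amplitude envelope over `times` (before snr scaling)
shared_envelope <- function(r, times, onset_ms = -Inf) {
  sw <- r$stage_windows
  s2 <- sw[[2L]]
  s4_start <- sw[[length(sw)]][1L]
  peak <- r$early_peak_ms
  a3 <- r$sustain_level
  env <- numeric(length(times))
  i_ramp <- times >= s2[1L] & times <= peak
  env[i_ramp] <- (times[i_ramp] - s2[1L]) / (peak - s2[1L])
  i_fall <- times > peak & times < s2[2L]
  env[i_fall] <- 1 + (a3 - 1) * (times[i_fall] - peak) / (s2[2L] - peak)
  i_sus <- times >= s2[2L] & times < s4_start
  env[i_sus] <- a3
  i_ling <- times >= s4_start
  env[i_ling] <- a3 * exp(-(times[i_ling] - s4_start) / r$linger_decay_tau_ms)
  env[times < onset_ms] <- 0
  env
}

# internal: chain-state indicator envelopes, list of length chain_states
chain_envelopes <- function(r, times, onset_ms = -Inf) {
  s4_start <- r$stage_windows[[length(r$stage_windows)]][1L]
  lapply(seq_len(r$chain_states), function(s) {
    from <- s4_start + (s - 1L) * r$state_duration_ms
    to <- from + r$state_duration_ms
    as.numeric(times >= from & times < to & times >= onset_ms)
  })
}

# internal: core tensor builder shared by sensor- and ROI-level generation
build_epoch_tensor <- function(r, behavior, n_channels, onset_ms, gain, seed) {
  times <- recipe_times(r)
  n_t <- length(times)
  n_tr <- nrow(behavior)
  pats <- make_patterns(1L + r$chain_states, n_channels, seed,
    kappa = r$pattern_uniqueness
  )
  env_sh <- shared_envelope(r, times, onset_ms)
  env_ch <- chain_envelopes(r, times, onset_ms)
  data <- with_seed(seed + 1L, {
    array(stats::rnorm(n_tr * n_channels * n_t, sd = max(r$noise_sd, 0)),
      dim = c(n_tr, n_channels, n_t)
    )
  })
  if (r$pattern_snr > 0) {
    for (i in seq_len(n_tr)) {
      if (!isTRUE(behavior$target_present[i])) next
      loc <- behavior$location[i]
      amp <- r$pattern_snr
      if (!behavior$seen[i] && isFALSE(behavior$correct[i])) {
        amp <- amp * r$unseen_incorrect_snr
      }
      sig <- outer(pats[[1L]][loc, ], env_sh * amp)
      if (isTRUE(behavior$seen[i])) {
        for (s in seq_len(r$chain_states)) {
          sig <- sig + outer(
            pats[[1L + s]][loc, ],
            env_ch[[s]] * (amp * r$sustain_level * gain)
          )
        }
      }
      data[i, , ] <- data[i, , ] + sig
    }
  }
  list(data = data, times = times)
}

#' Generate synthetic sensor-level epochs
#'
#' Builds an [epoch_set()] realizing the staged-code model of
#' [signal_recipe()] for the trials of a behavioral table: location-specific
#' patterns on target-present trials, pure noise on target-absent trials,
#' and (optionally) weak visibility-blind location signal on appended EOG
#' channels. Deterministic given `recipe$seed`.
#'
#' @param recipe A [signal_recipe()].
#' @param behavior Trial table from [simulate_behavior()]; must contain at
#'   least one trial for every location class it uses.
#' @return An `epoch_set` whose trial table is `behavior`.
#' @export
generate_epochs <- function(recipe, behavior) {
  behavior <- tibble::as_tibble(behavior)
  present <- behavior$target_present
  if (!any(present)) stop("`behavior` contains no target-present trials", call. = FALSE)
  core <- build_epoch_tensor(
    recipe, behavior, recipe$n_channels,
    onset_ms = -Inf, gain = recipe$seen_gain, seed = recipe$seed
  )
  data <- core$data
  types <- rep(c("mag", "grad", "eeg"), length.out = recipe$n_channels)
  names_ch <- sprintf("%s%03d", toupper(types), seq_len(recipe$n_channels))
  if (recipe$n_eog > 0) {
    eog <- build_eog_tensor(recipe, behavior, length(core$times))
    data <- abind3(data, eog)
    types <- c(types, rep("eog", recipe$n_eog))
    names_ch <- c(names_ch, sprintf("EOG%03d", seq_len(recipe$n_eog)))
  }
  epoch_set(
    data = data,
    times = core$times,
    sfreq = recipe$sfreq,
    channels = tibble::tibble(name = names_ch, type = types, roi = NA_character_),
    trials = behavior
  )
}

# internal: EOG channels -- weak location signal, blind to visibility
build_eog_tensor <- function(r, behavior, n_t) {
  times <- recipe_times(r)
  n_tr <- nrow(behavior)
  pats <- make_patterns(1L, r$n_eog, r$seed + 7L, kappa = r$pattern_uniqueness)
  env <- as.numeric(times >= r$eog_window_ms[1L] & times < r$eog_window_ms[2L])
  data <- with_seed(r$seed + 8L, {
    array(stats::rnorm(n_tr * r$n_eog * n_t, sd = max(r$noise_sd, 0)),
      dim = c(n_tr, r$n_eog, n_t)
    )
  })
  if (r$eog_snr > 0) {
    for (i in seq_len(n_tr)) {
      if (!isTRUE(behavior$target_present[i])) next
      data[i, , ] <- data[i, , ] +
        outer(pats[[1L]][behavior$location[i], ], env * r$eog_snr)
    }
  }
  data
}

# internal: bind two (trials x channels x time) arrays along channels
abind3 <- function(a, b) {
  da <- dim(a)
  db <- dim(b)
  out <- array(0, dim = c(da[1L], da[2L] + db[2L], da[3L]))
  out[, seq_len(da[2L]), ] <- a
  out[, da[2L] + seq_len(db[2L]), ] <- b
  out
}

#' Generate synthetic ROI source-space epochs
#'
#' One `epoch_set` of virtual source channels per region of interest.
#' Location information in an ROI is zero before that ROI's onset latency
#' (`recipe$roi_onsets_ms`) and follows the recipe dynamics after it; the
#' seen-trial chain amplification (`seen_gain`) applies only in the
#' workspace ROIs (`recipe$workspace_rois`), elsewhere the chain enters at
#' the unamplified sustained level. All ROIs share the recipe seed, so
#' patterns and noise are identical across ROIs and amplitude contrasts
#' between them are exact.
#'
#' @param recipe A [signal_recipe()] with a nonempty `roi_onsets_ms`.
#' @param behavior Trial table, as for [generate_epochs()].
#' @return Named list of `epoch_set`, one per ROI (empty list for an empty
#'   ROI map).
#' @export
generate_roi_epochs <- function(recipe, behavior) {
  onsets <- recipe$roi_onsets_ms
  if (length(onsets) == 0L) {
    return(stats::setNames(list(), character(0)))
  }
  if (is.null(names(onsets)) || any(!nzchar(names(onsets)))) {
    stop("`roi_onsets_ms` must be a named vector", call. = FALSE)
  }
  if (any(onsets < recipe$epoch_window[1L] | onsets > recipe$epoch_window[2L])) {
    stop("ROI onset latency outside the epoch window", call. = FALSE)
  }
  behavior <- tibble::as_tibble(behavior)
  out <- lapply(names(onsets), function(roi) {
    gain <- if (roi %in% recipe$workspace_rois) recipe$seen_gain else 1
    core <- build_epoch_tensor(
      recipe, behavior, recipe$roi_n_channels,
      onset_ms = onsets[[roi]], gain = gain, seed = recipe$seed
    )
    epoch_set(
      data = core$data,
      times = core$times,
      sfreq = recipe$sfreq,
      channels = tibble::tibble(
        name = sprintf("%s_%02d", roi, seq_len(recipe$roi_n_channels)),
        type = "source", roi = roi
      ),
      trials = behavior
    )
  })
  stats::setNames(out, names(onsets))
}
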