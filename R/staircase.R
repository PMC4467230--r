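#' Configuration of the adaptive mask-contrast staircase
#'
#' Parameters of the modified-Levitt block staircase used to bring each
#' observer to the 50%-seen mask contrast before the main experiment:
#' blocks of trials are run at a fixed contrast, and after each block the
#' contrast moves by a step proportional to the block's seen proportion
#' minus 0.5, with the maximum step shrinking as blocks accumulate.
#'
#' @param initial_intensity Starting mask contrast (default 230 on the
#'   0--255 pixel-intensity scale).
#' @param max_step Maximum contrast change after a single block (default
#'   80; attained when the block's seen proportion is 0 or 1).
#' @param stop_step Stop once the magnitude of the applied step falls
#'   below this (default 1.5 intensity units).
#' @param max_trials Stop once this many calibration trials have been run
#'   (default 80).
#' @param block_sizes Trial counts of the successive blocks; the last
#'   entry repeats (default `c(4, 4, 6, 8, 10)`: two blocks of four, then
#'   six, then eight, then tens).
#' @param step_decay Multiplicative shrink factor applied to the maximum
#'   step after each completed block (default 0.7).
#' @return An object of class `staircase_config`.
#' @export
staircase_config <- function(initial_intensity = 230,
                             max_step = 80,
                             stop_step = 1.5,
                             max_trials = 80,
                             block_sizes = c(4, 4, 6, 8, 10),
                             step_decay = 0.7) {
  if (initial_intensity < 0 || initial_intensity > 255) {
    stop("`initial_intensity` must lie in [0, 255]", call. = FALSE)
  }
  if (any(block_sizes <= 0)) stop("`block_sizes` must be positive", call. = FALSE)
  if (stop_step >= max_step) stop("`stop_step` must be below `max_step`", call. = FALSE)
  if (step_decay <= 0 || step_decay > 1) stop("`step_decay` must be in (0, 1]", call. = FALSE)
  structure(
    list(
      initial_intensity = initial_intensity, max_step = max_step,
      stop_step = stop_step, max_trials = max_trials,
      block_sizes = block_sizes, step_decay = step_decay
    ),
    class = "staircase_config"
  )
}

#' Size of the b-th staircase block
#' @param config A [staircase_config()].
#' @param block_index Block number (1-based).
#' @return Integer trial count.
#' @export
staircase_block_size <- function(config, block_index) {
  sizes <- config$block_sizes
  sizes[min(block_index, length(sizes))]
}

#' Fresh staircase state
#'
#' @param config A [staircase_config()].
#' @return An object of class `staircase_state`: list with `contrast`,
#'   `block_index` (completed blocks), `trials_done`, `max_step_current`,
#'   `history` (tibble: `block`, `contrast`, `p_seen`, `step`), `stopped`,
#'   `stop_reason`.
#' @export
staircase_init <- function(config) {
  structure(
    list(
      contrast = config$initial_intensity,
      block_index = 0L,
      trials_done = 0L,
      max_step_current = config$max_step,
      history = tibble::tibble(
        block = integer(), contrast = numeric(),
        p_seen = numeric(), step = numeric()
      ),
      stopped = FALSE,
      stop_reason = NA_character_
    ),
    class = "staircase_state"
  )
}

#' Advance the staircase by one completed block
#'
#' Applies the update rule: the contrast step is
#' `max_step_current * (p_seen_block - 0.5) / 0.5`, so a fully seen (or
#' fully unseen) block moves the contrast by the full current maximum and
#' a block at exactly 50% does not move it. More seen trials drive the
#' contrast *up* (a stronger mask), fewer drive it down; the contrast is
#' clipped to `[0, 255]`. After the block the maximum step shrinks by
#' `step_decay`, and the staircase stops when the applied step magnitude
#' falls below `stop_step` or the cumulative trial count reaches
#' `max_trials`.
#'
#' @param state A running [staircase_init()] state (stepping a stopped
#'   state is an error).
#' @param p_seen_block Proportion of seen trials in the completed block,
#'   in `[0, 1]`.
#' @param config The [staircase_config()].
#' @return The updated `staircase_state`.
#' @export
staircase_step <- function(state, p_seen_block, config) {
  if (state$stopped) stop("staircase already stopped (", state$stop_reason, ")", call. = FALSE)
  if (p_seen_block < 0 || p_seen_block > 1) {
    stop("`p_seen_block` must be in [0, 1]", call. = FALSE)
  }
  block <- state$block_index + 1L
  n_block <- staircase_block_size(config, block)
  step <- state$max_step_current * (p_seen_block - 0.5) / 0.5
  step <- max(min(step, state$max_step_current), -state$max_step_current)
  new_contrast <- max(0, min(255, state$contrast + step))
  state$history <- dplyr::bind_rows(
    state$history,
    tibble::tibble(
      block = block, contrast = state$contrast,
      p_seen = p_seen_block, step = step
    )
  )
  state$contrast <- new_contrast
  state$block_index <- block
  state$trials_done <- state$trials_done + n_block
  state$max_step_current <- state$max_step_current * config$step_decay
  if (abs(step) < config$stop_step) {
    state$stopped <- TRUE
    state$stop_reason <- "step_below_threshold"
  } else if (state$trials_done >= config$max_trials) {
    state$stopped <- TRUE
    state$stop_reason <- "max_trials"
  }
  state
}

#' @export
print.staircase_state <- function(x, ...) {
  cat(sprintf(
    "<staircase_state> contrast %.1f after %d block(s), %d trials%s\n",
    x$contrast, x$block_index, x$trials_done,
    if (x$stopped) paste0(" [stopped: ", x$stop_reason, "]") else ""
  ))
  invisible(x)
}

#' Run a full simulated calibration
#'
#' Alternates simulated behavioral blocks with staircase updates until the
#' staircase stops. A trial counts as "seen" for calibration purposes if
#' the observer reported it seen and localized it correctly, or reported
#' it seen, mislocalized, but detected the localization error.
#'
#' @param observer An [observer_model()].
#' @param config A [staircase_config()].
#' @param seed Integer seed; blocks use derived sub-seeds so the whole run
#'   is reproducible.
#' @return A list with `final_contrast`, `state` (the stopped
#'   `staircase_state`) and `trials` (all simulated calibration trials
#'   with their block number).
#' @export
run_calibration <- function(observer, config = staircase_config(), seed = 1L) {
  state <- staircase_init(config)
  all_trials <- list()
  b <- 0L
  while (!state$stopped) {
    b <- b + 1L
    n_block <- staircase_block_size(config, b)
    beh <- simulate_behavior(observer, state$contrast, n_block, seed = seed + 1000L * b)
    beh$block <- b
    all_trials[[b]] <- beh
    seen_calib <- beh$seen & (beh$correct | beh$detected_error)
    state <- staircase_step(state, mean(seen_calib), config)
  }
  list(
    final_contrast = state$contrast,
    state = state,
    trials = dplyr::bind_rows(all_trials)
  )
}
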