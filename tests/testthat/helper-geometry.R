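# geometry measurement utilities shared by the generalization checks

# average lag profile of a generalization matrix over a train-time window
tgm_lag_profile <- function(tgm, train_win = c(280, 780), max_lag_ms = 400) {
  recenter_by_lag(tgm) |>
    dplyr::filter(
      train_ms >= train_win[1], train_ms < train_win[2],
      !is.na(value), abs(lag_ms) <= max_lag_ms
    ) |>
    dplyr::summarise(value = mean(value), .by = lag_ms) |>
    dplyr::arrange(lag_ms)
}

# full width at half of the lag-0 above-chance excess, with linear
# interpolation of the two half-crossings
profile_fwhm_ms <- function(profile, chance) {
  ex <- profile$value - chance
  L <- profile$lag_ms
  i0 <- which(L == 0)
  half <- ex[i0] / 2
  right <- i0
  while (right < length(L) && ex[right + 1] >= half) right <- right + 1
  left <- i0
  while (left > 1 && ex[left - 1] >= half) left <- left - 1
  xr <- if (right < length(L)) {
    L[right] + (L[right + 1] - L[right]) * (ex[right] - half) / (ex[right] - ex[right + 1])
  } else {
    L[right]
  }
  xl <- if (left > 1) {
    L[left] - (L[left] - L[left - 1]) * (ex[left] - half) / (ex[left] - ex[left - 1])
  } else {
    L[left]
  }
  xr - xl
}
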