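#' Condition-average evoked response
#'
#' Averages the epochs of one condition (and optionally one channel type)
#' into a channels x time evoked field/potential.
#'
#' @param epochs An `epoch_set`.
#' @param trials Logical trial mask (default all trials).
#' @param channel_type Optional channel type to restrict to (e.g. `"mag"`).
#' @return An object of class `evoked`: list with `data`
#'   (channels x time), `times`, `sfreq`, `channels`, `n_trials`.
#' @export
compute_evoked <- function(epochs, trials = NULL, channel_type = NULL) {
  ti <- if (is.null(trials)) seq_len(n_trials(epochs)) else which(trials)
  if (!length(ti)) stop("`trials` selects no trials", call. = FALSE)
  ci <- seq_len(nrow(epochs$channels))
  if (!is.null(channel_type)) {
    ci <- which(epochs$channels$type == channel_type)
    if (!length(ci)) stop("no channels of type `", channel_type, "`", call. = FALSE)
  }
  dat <- epochs$data[ti, ci, , drop = FALSE]
  structure(
    list(
      data = apply(dat, c(2L, 3L), mean),
      times = epochs$times,
      sfreq = epochs$sfreq,
      channels = epochs$channels[ci, , drop = FALSE],
      n_trials = length(ti)
    ),
    class = "evoked"
  )
}

#' Global field power
#'
#' The standard deviation across channels of the evoked values at each
#' time sample -- the classic reference-free summary used to locate
#' component windows. The population form (divide by the channel count) is
#' used, as in the original definition, so two channels at `+a`/`-a` give
#' a GFP of exactly `|a|`.
#'
#' @param evoked An [compute_evoked()] result (at least 2 channels).
#' @return A tibble with columns `time_ms`, `gfp`.
#' @export
global_field_power <- function(evoked) {
  if (nrow(evoked$data) < 2L) {
    stop("global field power requires at least 2 channels", call. = FALSE)
  }
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  tibble::tibble(
    time_ms = evoked$times,
    gfp = apply(evoked$data, 2L, pop_sd)
  )
}

#' GFP-guided component windows
#'
#' Selects analysis windows around the largest global-field-power lobes
#' after a minimum latency: local GFP maxima are ranked, the top `n_windows`
#' peaks (separated by at least `min_separation_ms`) are kept, and each is
#' wrapped in a window of the requested width. This is the usual
#' data-driven way of placing e.g. N2-like and P3-like windows before
#' cluster testing.
#'
#' @param gfp Tibble from [global_field_power()] (or any `time_ms`/`gfp`
#'   table; average across replicates first for group-level windows).
#' @param n_windows Number of windows (default 2).
#' @param after_ms Ignore peaks before this latency (default 150 ms).
#' @param widths_ms Numeric vector (recycled) of window widths in ms.
#' @param min_separation_ms Minimum peak separation (default 80 ms).
#' @return A tibble with columns `peak_ms`, `from_ms`, `to_ms`, ordered by
#'   peak latency.
#' @export
gfp_peak_windows <- function(gfp, n_windows = 2L, after_ms = 150,
                             widths_ms = c(36, 300), min_separation_ms = 80) {
  g <- dplyr::arrange(dplyr::filter(gfp, .data$time_ms >= after_ms), .data$time_ms)
  v <- g$gfp
  n <- length(v)
  if (n < 3L) stop("too few samples after `after_ms`", call. = FALSE)
  is_peak <- c(FALSE, v[2:(n - 1L)] >= v[1:(n - 2L)] & v[2:(n - 1L)] >= v[3:n], FALSE)
  cand <- order(v, decreasing = TRUE)
  cand <- cand[is_peak[cand] | cand %in% c(1L, n)] # allow edge maxima
  picked <- integer(0)
  for (i in cand) {
    if (length(picked) == n_windows) break
    if (all(abs(g$time_ms[i] - g$time_ms[picked]) >= min_separation_ms)) {
      picked <- c(picked, i)
    }
  }
  if (length(picked) < n_windows) {
    stop("could not find ", n_windows, " separated GFP peaks", call. = FALSE)
  }
  widths <- rep_len(widths_ms, n_windows)
  ord <- order(g$time_ms[picked])
  tibble::tibble(
    peak_ms = g$time_ms[picked][ord],
    from_ms = g$time_ms[picked][ord] - widths[ord] / 2,
    to_ms = g$time_ms[picked][ord] + widths[ord] / 2
  )
}

#' k-nearest-neighbor channel adjacency
#'
#' Builds a symmetric channel adjacency from 2-D sensor coordinates by
#' connecting each channel to its `k` nearest neighbors. When no layout is
#' available (synthetic data), coordinates are drawn uniformly in the unit
#' square from `seed`.
#'
#' @param n_channels Number of channels.
#' @param k Neighbors per channel (default 4).
#' @param coords Optional `n_channels` x 2 coordinate matrix; drawn at
#'   random when `NULL`.
#' @param seed Seed for random coordinates.
#' @return A logical `n_channels` x `n_channels` symmetric adjacency
#'   matrix with `FALSE` diagonal.
#' @export
knn_adjacency <- function(n_channels, k = 4L, coords = NULL, seed = 1L) {
  if (is.null(coords)) {
    coords <- with_seed(seed, matrix(stats::runif(n_channels * 2L), ncol = 2L))
  }
  stopifnot(nrow(coords) == n_channels)
  d <- as.matrix(stats::dist(coords))
  adj <- matrix(FALSE, n_channels, n_channels)
  for (i in seq_len(n_channels)) {
    nb <- order(d[i, ])[2:(min(k, n_channels - 1L) + 1L)]
    adj[i, nb] <- TRUE
  }
  adj <- adj | t(adj)
  diag(adj) <- FALSE
  adj
}

# internal: connected components of supra-threshold (channel, sample)
# points under channel adjacency + temporal contiguity, within one sign.
# `mask` is a channels x samples logical matrix; returns an integer label
# matrix (0 = sub-threshold).
label_clusters <- function(mask, adjacency) {
  nc <- nrow(mask)
  ns <- ncol(mask)
  lab <- matrix(0L, nc, ns)
  cur <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[[1L]]
      queue <- queue[-1L]
      ch <- (p - 1L) %% nc + 1L
      sm <- (p - 1L) %/% nc + 1L
      nbrs <- integer(0)
      if (sm > 1L) nbrs <- c(nbrs, p - nc)
      if (sm < ns) nbrs <- c(nbrs, p + nc)
      adj_ch <- which(adjacency[ch, ])
      nbrs <- c(nbrs, (sm - 1L) * nc + adj_ch)
      nbrs <- nbrs[mask[nbrs] & lab[nbrs] == 0L]
      lab[nbrs] <- cur
      queue <- c(queue, nbrs)
    }
  }
  lab
}

# internal: maximum cluster mass (sum of t) over both signs for one t-map
max_cluster_mass <- function(tmap, thr, adjacency) {
  best <- 0
  for (sgn in c(1, -1)) {
    mask <- sgn * tmap > thr
    if (!any(mask)) next
    lab <- label_clusters(mask, adjacency)
    if (max(lab) == 0L) next
    masses <- abs(vapply(
      seq_len(max(lab)),
      function(l) sum(tmap[lab == l]), numeric(1)
    ))
    best <- max(best, masses)
  }
  best
}

#' Cluster-based permutation test on paired evoked responses
#'
#' Compares two paired sets of per-replicate evoked responses inside a
#' time window with familywise error control: a paired t statistic is
#' computed per (channel, sample); samples exceeding the cluster-forming
#' threshold are joined into spatio-temporal clusters (channel adjacency
#' plus temporal contiguity, within one sign); each cluster's mass is the
#' sum of its t values; and the null distribution of the maximum cluster
#' mass is built by randomly sign-flipping the replicate difference maps.
#' Cluster p-values are `(1 + #{null >= observed}) / (1 + n_perm)`.
#'
#' @param evoked_a,evoked_b Lists of [compute_evoked()] objects, one per
#'   replicate, pairwise aligned (same channels and times).
#' @param window Analysis window in ms, half-open.
#' @param adjacency Logical channel adjacency matrix (see
#'   [knn_adjacency()]); must cover all channels and be connected enough
#'   to be meaningful -- a fully disconnected adjacency is an error.
#' @param n_perm Number of sign-flip permutations (default 1000; fewer
#'   than 100 draws a warning).
#' @param forming_p Two-tailed cluster-forming p threshold on the paired t
#'   (default 0.05).
#' @param seed Seed for the permutation draws.
#' @return An object of class `cluster_result`: list with `clusters`
#'   (tibble: `cluster`, `sign`, `mass`, `p`, `n_points`, `from_ms`,
#'   `to_ms`, `channels`), `n_perm`, `forming_t`, `window`.
#' @export
cluster_permutation_test <- function(evoked_a, evoked_b, window, adjacency,
                                     n_perm = 1000L, forming_p = 0.05,
                                     seed = 1L) {
  stopifnot(length(evoked_a) == length(evoked_b), length(evoked_a) >= 2L)
  if (n_perm < 100L) warning("fewer than 100 permutations gives coarse p-values")
  nc <- nrow(evoked_a[[1L]]$data)
  if (!is.matrix(adjacency) || nrow(adjacency) != nc || ncol(adjacency) != nc) {
    stop("`adjacency` must be a ", nc, " x ", nc, " matrix covering all channels",
      call. = FALSE
    )
  }
  if (!any(adjacency)) stop("`adjacency` has no edges; channel graph is disconnected", call. = FALSE)
  times <- evoked_a[[1L]]$times
  keep <- times >= window[1L] & times < window[2L]
  if (!any(keep)) stop("`window` contains no samples", call. = FALSE)
  n_rep <- length(evoked_a)
  # replicate difference maps, replicates x (channel*sample)
  D <- t(vapply(
    seq_len(n_rep),
    function(r) as.vector(evoked_a[[r]]$data[, keep] - evoked_b[[r]]$data[, keep]),
    numeric(nc * sum(keep))
  ))
  df <- n_rep - 1L
  thr <- stats::qt(1 - forming_p / 2, df)
  tmap_of <- function(Dm) {
    mu <- colMeans(Dm)
    se <- sqrt((colMeans(Dm^2) - mu^2) * n_rep / df) / sqrt(n_rep)
    tv <- mu / se
    tv[se == 0] <- 0
    matrix(tv, nrow = nc)
  }
  t_obs <- tmap_of(D)
  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      flips <- sample(c(-1, 1), n_rep, replace = TRUE)
      max_cluster_mass(tmap_of(D * flips), thr, adjacency)
    }, numeric(1))
  })
  clusters <- list()
  idx <- 0L
  win_times <- times[keep]
  for (sgn in c(1, -1)) {
    mask <- sgn * t_obs > thr
    if (!any(mask)) next
    lab <- label_clusters(mask, adjacency)
    for (l in seq_len(max(lab))) {
      pts <- lab == l
      mass <- sum(t_obs[pts])
      idx <- idx + 1L
      clusters[[idx]] <- tibble::tibble(
        cluster = idx,
        sign = ifelse(sgn > 0, "pos", "neg"),
        mass = mass,
        p = (1 + sum(null_max >= abs(mass))) / (1 + n_perm),
        n_points = sum(pts),
        from_ms = min(win_times[colSums(pts) > 0]),
        to_ms = max(win_times[colSums(pts) > 0]),
        channels = list(which(rowSums(pts) > 0))
      )
    }
  }
  structure(
    list(
      clusters = if (idx) dplyr::bind_rows(clusters) else tibble::tibble(),
      n_perm = n_perm,
      forming_t = thr,
      window = window
    ),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf(
    "<cluster_result> window [%g, %g) ms, forming |t| > %.2f, %d permutations\n",
    x$window[1L], x$window[2L], x$forming_t, x$n_perm
  ))
  if (nrow(x$clusters)) print(x$clusters) else cat("  no supra-threshold clusters\n")
  invisible(x)
}
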