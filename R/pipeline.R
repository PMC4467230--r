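#' Full-analysis run configuration
#'
#' Bundles every choice of a full pipeline run: the synthetic recipe and
#' observer, the mask contrast, fold schemes, analysis toggles and the
#' master seed. All stochastic stages derive their seeds from `seed`, so a
#' configuration reproduces its report byte for byte.
#'
#' @param recipe A [signal_recipe()].
#' @param observer An [observer_model()].
#' @param contrast Mask contrast of the simulated session.
#' @param p_absent Proportion of target-absent catch trials (default 1/9).
#' @param k_location Folds for the location decoders (default 15).
#' @param k_visibility Folds for the visibility decoder (default 10).
#' @param n_replicates Simulated subjects (replicates); replicate-level
#'   statistics (window tests, endurance ANOVA, cluster tests) require at
#'   least 2.
#' @param decode_window Time window (ms) analysed by the decoders; the
#'   full epoch by default.
#' @param eog_control,absent_control,visibility_decoder,roi_decoding,cluster_stats
#'   Toggles for the corresponding report sections.
#' @param tolerance SMO tolerance forwarded to the decoders.
#' @param seed Master integer seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(recipe = signal_recipe(),
                       observer = observer_model(),
                       contrast = observer$contrast_threshold,
                       p_absent = 1 / 9,
                       k_location = 15,
                       k_visibility = 10,
                       n_replicates = 1L,
                       decode_window = NULL,
                       eog_control = TRUE,
                       absent_control = TRUE,
                       visibility_decoder = TRUE,
                       roi_decoding = FALSE,
                       cluster_stats = TRUE,
                       tolerance = 0.01,
                       seed = 1L) {
  structure(
    list(
      recipe = recipe, observer = observer, contrast = contrast,
      p_absent = p_absent, k_location = k_location,
      k_visibility = k_visibility, n_replicates = as.integer(n_replicates),
      decode_window = decode_window,
      eog_control = eog_control, absent_control = absent_control,
      visibility_decoder = visibility_decoder, roi_decoding = roi_decoding,
      cluster_stats = cluster_stats,
      tolerance = tolerance, seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' Read a run configuration from a flat key-value file
#'
#' The file format is plain text with `[section]` headers (`recipe`,
#' `observer`, `run`) and `key = value` lines; values may be numbers,
#' `TRUE`/`FALSE`, or comma-separated numeric pairs for window keys.
#' Unknown sections or keys are errors (fail-fast), so typos cannot
#' silently fall back to defaults.
#'
#' @param path Path to the config file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  section <- NA_character_
  vals <- list(recipe = list(), observer = list(), run = list())
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- sub("^\\[(.+)\\]$", "\\1", ln)
      if (!section %in% names(vals)) {
        stop("unknown config section `[", section, "]`", call. = FALSE)
      }
      next
    }
    if (is.na(section)) stop("config line before any [section]: ", ln, call. = FALSE)
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(kv[1L])
    raw <- trimws(kv[2L])
    val <- if (raw %in% c("TRUE", "FALSE")) {
      as.logical(raw)
    } else if (grepl(",", raw, fixed = TRUE)) {
      as.numeric(trimws(strsplit(raw, ",", fixed = TRUE)[[1L]]))
    } else {
      num <- suppressWarnings(as.numeric(raw))
      if (is.na(num)) raw else num
    }
    vals[[section]][[key]] <- val
  }
  check_known <- function(given, fn, what) {
    ok <- names(formals(fn))
    bad <- setdiff(names(given), ok)
    if (length(bad)) {
      stop("unknown ", what, " config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  check_known(vals$recipe, signal_recipe, "recipe")
  check_known(vals$observer, observer_model, "observer")
  check_known(vals$run, run_config, "run")
  args <- vals$run
  args$recipe <- do.call(signal_recipe, vals$recipe)
  args$observer <- do.call(observer_model, vals$observer)
  do.call(run_config, args)
}

# internal: per-timepoint decoder trained on one epoch set and tested on
# another (no cross-validation; used by the target-absent motor control,
# where train and test trials are disjoint by construction)
decode_train_test <- function(epochs_train, labels_train, epochs_test,
                              labels_test, tolerance = 0.01) {
  y_tr <- resolve_labels(epochs_train, labels_train)
  y_te <- factor(as.character(resolve_labels(epochs_test, labels_test)),
    levels = levels(y_tr)
  )
  if (anyNA(y_te)) stop("test labels contain classes absent from training", call. = FALSE)
  n_t <- length(epochs_train$times)
  ci <- as.integer(y_te)
  out <- matrix(NA_real_, n_trials(epochs_test), n_t)
  for (t in seq_len(n_t)) {
    Xt <- epochs_train$data[, , t, drop = TRUE]
    fit <- fit_calibrated_svm(Xt, y_tr, tolerance = tolerance)
    P <- predict_calibrated(fit, epochs_test$data[, , t, drop = TRUE])
    out[, t] <- P[cbind(seq_len(nrow(P)), ci)]
  }
  tibble::tibble(
    time_ms = epochs_train$times,
    mean = colMeans(out),
    sem = apply(out, 2L, stats::sd) / sqrt(nrow(out)),
    n = nrow(out)
  )
}

# internal: deterministic TSV writer (fixed formatting => byte-stable)
write_tsv_stable <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.10g", df[[j]])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Orchestrates, per replicate: behavior simulation, epoch synthesis,
#' baseline normalization, the 8-class location decoding curves split by
#' visibility and correctness (with blindsight chance correction), the
#' balanced binary hemifield cross-condition asymmetry curves, temporal
#' generalization matrices with Classification Endurance for seen and
#' unseen trials, evoked GFP (and, given at least two replicates, the
#' cluster permutation contrast and the endurance ANOVA), and the control
#' analyses (EOG-only decoding; target-absent response decoding). All
#' tables are written as TSV plus a machine-readable JSON summary keyed by
#' the configuration hash; a rerun with the same config is byte-identical.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @param verbose Print per-stage progress (default `TRUE`).
#' @return Invisibly, a list with the in-memory results (`summary`,
#'   `curves`, `asymmetry`, `endurance`, plus optional sections).
#' @export
run_full_analysis <- function(config, out_dir, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  cfg_hash <- rlang::hash(unclass(config))
  t_start <- Sys.time()

  rep_results <- vector("list", config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    say("replicate %d/%d: simulate + preprocess", r, config$n_replicates)
    rseed <- config$seed + 10000L * (r - 1L)
    recipe <- config$recipe
    recipe$seed <- rseed
    beh <- simulate_behavior(
      config$observer, config$contrast, recipe$n_trials,
      seed = rseed + 1L, p_absent = config$p_absent
    )
    epochs <- baseline_zscore(generate_epochs(recipe, beh))
    if (!is.null(config$decode_window)) {
      epochs <- crop_epochs(epochs, config$decode_window[1L], config$decode_window[2L])
    }
    sensors <- select_subset(epochs, channels = type != "eog")
    present <- select_subset(sensors, trials = target_present)

    say("replicate %d: location decoding", r)
    res8 <- decode_timecourse(present, "location",
      k = config$k_location,
      seed = rseed + 2L, tolerance = config$tolerance
    )
    tr <- present$trials
    conds <- list(
      all = rep(TRUE, nrow(tr)),
      seen_correct = tr$seen & tr$correct,
      unseen_correct = !tr$seen & tr$correct,
      unseen_incorrect = !tr$seen & !tr$correct
    )
    conds <- conds[vapply(conds, any, logical(1))]
    curves <- correct_class_series(res8, conds)
    dist_prof <- distance_profile(res8)
    corrected <- NULL
    if (all(c("unseen_correct", "unseen_incorrect") %in% names(conds))) {
      sc <- dplyr::filter(curves, .data$condition == "unseen_correct")
      si <- dplyr::filter(curves, .data$condition == "unseen_incorrect")
      corrected <- tibble::tibble(
        time_ms = sc$time_ms,
        mean = chance_corrected_mean(
          sc$mean, si$mean,
          n_correct = sum(conds$unseen_correct),
          n_incorrect = sum(conds$unseen_incorrect)
        )
      )
    }

    say("replicate %d: cross-condition asymmetry", r)
    present$trials$hemifield <- as.character(hemifield_labels(present$trials$location))
    present$trials$visibility <- ifelse(present$trials$seen, "seen", "unseen")
    corr <- select_subset(present, trials = correct)
    balanced <- select_subset(corr,
      balance = c("hemifield", "visibility"),
      seed = rseed + 3L
    )
    ytr <- hemifield_labels(balanced$trials$location)
    seen_mask <- balanced$trials$visibility == "seen"
    asym <- dplyr::bind_rows(
      dplyr::mutate(
        cross_condition_curves(balanced, ytr, seen_mask, !seen_mask,
          k = config$k_location, seed = rseed + 4L, tolerance = config$tolerance
        ),
        train = "seen"
      ),
      dplyr::mutate(
        cross_condition_curves(balanced, ytr, !seen_mask, seen_mask,
          k = config$k_location, seed = rseed + 5L, tolerance = config$tolerance
        ),
        train = "unseen"
      )
    )

    say("replicate %d: temporal generalization + endurance", r)
    endur <- purrr::map_dfr(c("seen", "unseen"), function(vis) {
      sub <- select_subset(balanced, trials = visibility == vis)
      tgm <- temporal_generalization_matrix(
        sub, hemifield_labels(sub$trials$location),
        k = config$k_location, seed = rseed + 6L, tolerance = config$tolerance,
        train_cond = vis
      )
      prof <- classification_endurance(tgm, chance = 0.5)
      dplyr::mutate(ce_timeframes(prof), visibility = vis)
    })

    say("replicate %d: evoked responses", r)
    evoked <- lapply(c(seen = TRUE, unseen = FALSE), function(s) {
      compute_evoked(sensors, trials = sensors$trials$target_present &
        sensors$trials$seen == s & sensors$trials$correct %in% TRUE)
    })
    gfp <- dplyr::mutate(
      global_field_power(evoked$seen),
      condition = "seen_correct", replicate = r
    )

    controls <- list()
    if (config$eog_control && any(epochs$channels$type == "eog")) {
      say("replicate %d: EOG-only control", r)
      eog <- select_subset(epochs, channels = type == "eog", trials = target_present)
      res_eog <- decode_timecourse(eog, "location",
        k = config$k_location,
        seed = rseed + 7L, tolerance = config$tolerance
      )
      etr <- eog$trials
      controls$eog <- correct_class_series(res_eog, list(
        seen_correct = etr$seen & etr$correct %in% TRUE,
        unseen_correct = !etr$seen & etr$correct %in% TRUE
      ))
    }
    if (config$absent_control && any(!epochs$trials$target_present)) {
      say("replicate %d: target-absent motor control", r)
      absent <- select_subset(sensors, trials = !target_present)
      controls$absent <- decode_train_test(
        present, "location", absent, absent$trials$response,
        tolerance = config$tolerance
      )
    }
    if (config$visibility_decoder) {
      say("replicate %d: visibility decoder", r)
      vis_bal <- select_subset(corr,
        balance = c("location", "visibility"),
        seed = rseed + 8L
      )
      res_vis <- decode_timecourse(
        vis_bal, vis_bal$trials$visibility,
        k = config$k_visibility, seed = rseed + 9L, tolerance = config$tolerance
      )
      controls$visibility <- correct_class_series(res_vis)
    }
    if (config$roi_decoding) {
      say("replicate %d: ROI decoding", r)
      rois <- generate_roi_epochs(recipe, beh)
      controls$roi <- purrr::map_dfr(names(rois), function(nm) {
        ep <- baseline_zscore(rois[[nm]])
        if (!is.null(config$decode_window)) {
          ep <- crop_epochs(ep, config$decode_window[1L], config$decode_window[2L])
        }
        ep <- select_subset(ep, trials = target_present)
        res <- decode_timecourse(ep, hemifield_labels(ep$trials$location),
          k = config$k_location, seed = rseed + 10L, tolerance = config$tolerance
        )
        dplyr::mutate(correct_class_series(res), roi = nm)
      })
    }

    rep_results[[r]] <- list(
      curves = dplyr::mutate(curves, replicate = r),
      distance = dplyr::mutate(dist_prof, replicate = r),
      corrected = if (!is.null(corrected)) dplyr::mutate(corrected, replicate = r),
      asymmetry = dplyr::mutate(asym, replicate = r),
      endurance = dplyr::mutate(endur, replicate = r),
      gfp = gfp,
      evoked = evoked,
      controls = controls
    )
  }

  bundle <- list(
    curves = purrr::map_dfr(rep_results, "curves"),
    distance = purrr::map_dfr(rep_results, "distance"),
    corrected = purrr::map_dfr(rep_results, function(x) x$corrected %||% tibble::tibble()),
    asymmetry = purrr::map_dfr(rep_results, "asymmetry"),
    endurance = purrr::map_dfr(rep_results, "endurance"),
    gfp = purrr::map_dfr(rep_results, "gfp")
  )

  if (config$n_replicates >= 2L) {
    say("group level: endurance ANOVA")
    ce_tab <- bundle$endurance |>
      tidyr::pivot_longer(c("ce_forward_ms", "ce_backward_ms"),
        names_to = "direction", values_to = "ce_ms"
      ) |>
      dplyr::mutate(direction = ifelse(
        .data$direction == "ce_forward_ms", "forward", "backward"
      ))
    bundle$ce_anova <- tryCatch(
      ce_anova(ce_tab[c("replicate", "visibility", "direction", "timeframe", "ce_ms")]),
      error = function(e) {
        warning("endurance ANOVA skipped: ", conditionMessage(e))
        NULL
      }
    )
    if (config$cluster_stats) {
      say("group level: cluster permutation test")
      n_ch <- nrow(rep_results[[1L]]$evoked$seen$data)
      adj <- knn_adjacency(n_ch, seed = config$seed)
      bundle$clusters <- cluster_permutation_test(
        lapply(rep_results, function(x) x$evoked$seen),
        lapply(rep_results, function(x) x$evoked$unseen),
        window = c(271, 800), adjacency = adj,
        n_perm = 500L, seed = config$seed + 17L
      )
    }
  }
  for (nm in names(rep_results[[1L]]$controls)) {
    bundle[[paste0("control_", nm)]] <- purrr::map_dfr(
      seq_along(rep_results),
      function(r) dplyr::mutate(rep_results[[r]]$controls[[nm]], replicate = r)
    )
  }

  # ---- write the report ----
  for (nm in names(bundle)) {
    obj <- bundle[[nm]]
    if (tibble::is_tibble(obj) && nrow(obj)) {
      obj$config_hash <- cfg_hash
      write_tsv_stable(obj, file.path(out_dir, paste0(nm, ".tsv")))
    }
  }
  if (!is.null(bundle$ce_anova)) {
    eff <- bundle$ce_anova$effects
    eff$config_hash <- cfg_hash
    write_tsv_stable(eff, file.path(out_dir, "ce_anova_effects.tsv"))
  }
  if (!is.null(bundle$clusters) && nrow(bundle$clusters$clusters)) {
    cl <- bundle$clusters$clusters
    cl$channels <- vapply(cl$channels, function(v) paste(v, collapse = ","), character(1))
    cl$config_hash <- cfg_hash
    write_tsv_stable(cl, file.path(out_dir, "clusters.tsv"))
  }
  summary <- list(
    config_hash = cfg_hash,
    seed = config$seed,
    n_replicates = config$n_replicates,
    sections = sort(names(bundle)),
    mean_correct_probability = mean(
      dplyr::filter(bundle$curves, .data$condition == "all")$mean
    )
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  say("done in %.1f s", as.numeric(Sys.time() - t_start, units = "secs"))
  bundle$summary <- summary
  invisible(bundle)
}
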