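# End-to-end orchestration: simulate (or read) -> project -> register ->
# train/apply pixel classifier -> components -> track -> traces -> dF/F0 ->
# pool -> classify -> summarize, with a manifest that reproduces the run.
# Movies whose tracking fails are excluded from pooling and listed in the
# manifest rather than silently dropped.

#' Default pipeline stage parameters
#'
#' @param ... Overrides of any default (e.g. `gate_px = 12`).
#' @return Named list of stage parameters.
#' @export
pipeline_params <- function(...) {
  p <- list(max_shift = 20, score_floor = 0.3,
            feature_transform = feature_bank_config()$transform,
            feature_scale = feature_bank_config()$scale,
            max_depth = 8, min_leaf = 20, min_area = 5,
            expected_count = 2, gate_px = 15, max_gap = 10,
            init_window = 10, n_training_frames = 10,
            n_background_px = 800, subtract_background = TRUE,
            theta_abs = 0.2, theta_high = 0.8, k_sigma = 3, lag_allow = 15)
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad))
    abort(paste0("pipeline_params: unknown parameter(s): ",
                 paste(bad, collapse = ", ")),
          class = "wormtrace_invalid_parameter")
  p[names(ov)] <- ov
  p
}

process_one_movie <- function(scene, condition, params, movie_seed,
                              classifier = NULL) {
  if (inherits(scene, "scene_config")) {
    sim <- simulate_movie(scene)
    stack <- sim$movie
    truth <- sim$truth
  } else {
    stack <- read_stack(scene)
    truth <- NULL
  }
  proj <- max_project(stack)
  reg <- register_movie(proj, params$max_shift, params$score_floor)
  if (is.null(classifier)) {
    if (is.null(truth))
      abort("run_pipeline: file inputs require a trained `classifier` parameter.",
            class = "wormtrace_invalid_parameter")
    ## operator-like frame choice: half spread over the movie, half right
    ## after stimulus onset where the somata are brightest
    Tn <- dim(proj$data)[3]
    n_tf <- min(params$n_training_frames, Tn)
    onset <- stack$stimulus_onset_frame
    dur <- stack$stimulus_duration_frames
    tf_global <- round(seq(0, Tn - 1, length.out = ceiling(n_tf / 2)))
    tf_resp <- if (dur > 0)
      onset + round(seq(1, min(dur, 8), length.out = floor(n_tf / 2)))
    else integer()
    tf <- sort(unique(pmin(c(tf_global, tf_resp), Tn - 1)))
    labels <- training_labels_from_truth(truth, frames = tf,
                                         n_background = params$n_background_px,
                                         seed = movie_seed)
    frames <- lapply(tf + 1L, function(t) proj$data[, , t])
    classifier <- train_pixel_classifier(
      frames, labels,
      feature_config = feature_bank_config(params$feature_transform,
                                           params$feature_scale),
      max_depth = params$max_depth, min_leaf = params$min_leaf,
      seed = movie_seed, frame_ids = tf)
  }
  segs <- segment_movie(reg$movie, classifier, params$min_area,
                        params$expected_count)
  ts <- track_movie(segs, params$expected_count, params$gate_px,
                    params$max_gap, params$init_window)
  if (ts$failed)
    return(list(failed = TRUE, movie_id = stack$source_id, truth = truth,
                shifts = mutate(reg$shifts, movie_id = stack$source_id)))
  if (params$expected_count == 2 && length(ts$tracks) == 2)
    ts <- assign_pair_identity(ts)
  raw <- extract_traces(reg, ts, segs, params$max_gap)
  ntr <- normalize_trace(raw, params$subtract_background)
  calls <- classify_response(ntr, params$theta_abs, params$theta_high,
                             params$k_sigma, params$lag_allow)
  calls$condition <- condition
  list(failed = FALSE, movie_id = stack$source_id, truth = truth,
       shifts = mutate(reg$shifts, movie_id = stack$source_id),
       trace = ntr, calls = calls, condition = condition)
}

#' Run the full analysis pipeline over a batch of movies
#'
#' @param scenes List of [scene_config()] objects (simulated inputs) and/or
#'   TIFF paths (read with [read_stack()]; these require `classifier`).
#' @param conditions Condition label per movie (recycled).
#' @param params [pipeline_params()].
#' @param seed Root seed for everything random outside the scene configs
#'   (training-pixel sampling, tree fitting); per-movie seeds are derived
#'   from it.
#' @param out_dir Optional directory; when given the bundle is written with
#'   [write_bundle()].
#' @param classifier Optional pre-trained `pixel_classifier` applied to all
#'   movies (otherwise one is trained per movie from ground-truth labels).
#' @return A `results_bundle`: tibbles `traces`, `calls`, `shifts`,
#'   `fractions`, a named list `pooled` (one `pooled_response` per
#'   condition), `failed_movies`, and the reproducing `manifest`.
#' @export
run_pipeline <- function(scenes, conditions = "condition_1",
                         params = pipeline_params(), seed = 1L,
                         out_dir = NULL, classifier = NULL) {
  if (inherits(scenes, "scene_config")) scenes <- list(scenes)
  n <- length(scenes)
  conditions <- rep_len(conditions, n)
  res <- vector("list", n)
  errors <- list()
  for (i in seq_len(n)) {
    res[[i]] <- tryCatch(
      process_one_movie(scenes[[i]], conditions[i], params,
                        movie_seed = as.integer(seed) + i, classifier),
      error = function(e) {
        errors[[length(errors) + 1L]] <<- list(movie = i,
                                               message = conditionMessage(e))
        NULL
      })
  }
  ok <- !vapply(res, is.null, logical(1))
  failed <- vapply(res[ok], `[[`, logical(1), "failed")
  good <- res[ok][!failed]
  traces <- bind_rows(lapply(good, `[[`, "trace"))
  calls <- bind_rows(lapply(good, `[[`, "calls"))
  shifts <- bind_rows(lapply(res[ok], `[[`, "shifts"))
  pooled <- list()
  for (cond in unique(conditions)) {
    sel <- good[vapply(good, function(g) g$condition == cond, logical(1))]
    if (length(sel) >= 1) {
      tl <- lapply(sel, `[[`, "trace")
      pooled[[cond]] <- pool_traces(tl)
    }
  }
  fractions <- if (nrow(calls)) summarize_calls(calls) else tibble()
  manifest <- list(
    package = "wormtrace",
    version = as.character(utils::packageVersion("wormtrace")),
    seed = as.integer(seed),
    conditions = conditions,
    params = params,
    scenes = lapply(scenes, function(s)
      if (inherits(s, "scene_config")) serialize_scene(s) else s),
    failed_movies = vapply(res[ok][failed], `[[`, character(1), "movie_id"),
    errors = errors)
  bundle <- structure(list(traces = traces, calls = calls, shifts = shifts,
                           pooled = pooled, fractions = fractions,
                           truths = lapply(res[ok], `[[`, "truth"),
                           manifest = manifest),
                      class = "results_bundle")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

serialize_scene <- function(s) {
  x <- unclass(s)
  x$neurons <- lapply(x$neurons, unclass)
  x
}

deserialize_scene <- function(x) {
  x$neurons <- lapply(x$neurons, function(n)
    neuron_spec(n$neuron_id, unlist(n$centroid), n$radius_px, n$baseline,
                n$amplitude, n$tau_rise_s, n$tau_decay_s, n$onset_lag_s,
                n$true_class))
  do.call(scene_config, x[setdiff(names(x), character())])
}

#' Write a results bundle to a directory
#'
#' Emits `traces.csv`, `calls.csv`, `shifts.csv`, `fractions.csv`,
#' `pooled_<condition>.csv` and `manifest.json`.
#'
#' @param bundle A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_traces(bundle$traces, file.path(dir, "traces.csv"))
  write.csv(bundle$calls, file.path(dir, "calls.csv"), row.names = FALSE)
  write.csv(bundle$shifts, file.path(dir, "shifts.csv"), row.names = FALSE)
  write.csv(bundle$fractions, file.path(dir, "fractions.csv"),
            row.names = FALSE)
  for (cond in names(bundle$pooled))
    write.csv(bundle$pooled[[cond]],
              file.path(dir, paste0("pooled_", cond, ".csv")),
              row.names = FALSE)
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(dir)
}

#' Re-run a pipeline from its recorded manifest
#'
#' Deterministic stages reproduce the original CSV outputs bit-for-bit.
#'
#' @param manifest Path to a `manifest.json` or an already-parsed manifest
#'   list.
#' @param out_dir Optional output directory for the reproduced bundle.
#' @return A `results_bundle`.
#' @export
run_from_manifest <- function(manifest, out_dir = NULL) {
  if (is.character(manifest))
    manifest <- jsonlite::read_json(manifest, simplifyVector = FALSE)
  params <- manifest$params
  params$feature_scale <- vapply(params$feature_scale,
                                 function(v) if (is.null(v) ||
                                                 identical(v, "NA")) NA_real_
                                             else as.numeric(v), 0)
  params <- lapply(params, function(v) if (is.list(v)) unlist(v) else v)
  params <- do.call(pipeline_params, params)
  scenes <- lapply(manifest$scenes, function(s) {
    if (is.character(s)) return(s)        # TIFF path
    deserialize_scene(s)
  })
  run_pipeline(scenes, conditions = unlist(manifest$conditions),
               params = params, seed = unlist(manifest$seed),
               out_dir = out_dir)
}

#' @export
print.results_bundle <- function(x, ...) {
  cat(sprintf("<results_bundle: %d movies (%d failed), %d calls, %d conditions>\n",
              length(x$manifest$scenes), length(x$manifest$failed_movies),
              nrow(x$calls), length(unique(x$manifest$conditions))))
  if (nrow(x$fractions)) print(x$fractions)
  invisible(x)
}
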