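# Per-neuron mean-fluorescence traces, dF/F0 normalization, stimulus-aligned
# pooling and three-level response classification. A trace is a tibble (one
# row per frame) with acquisition metadata carried as attributes
# (frame_interval_s, stimulus_onset_frame, stimulus_duration_frames, F0,
# baseline_sigma).

trace_attr <- function(x, what) attr(x, what, exact = TRUE)

new_trace <- function(df, frame_interval_s, onset, duration, extra = list()) {
  out <- as_tibble(df)
  attr(out, "frame_interval_s") <- frame_interval_s
  attr(out, "stimulus_onset_frame") <- onset
  attr(out, "stimulus_duration_frames") <- duration
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  out
}

# union of component pixels across a segmentation, dilated, as exclusion
# mask for background estimation
background_exclusion <- function(seg, dimhw, dilate_px = 3) {
  m <- matrix(FALSE, dimhw[1], dimhw[2])
  for (p in seg$pixels) m[p] <- TRUE
  if (any(m))
    m <- EBImage::dilate(m * 1, EBImage::makeBrush(2L * dilate_px + 1L, "disc")) > 0
  m
}

#' Extract per-neuron raw traces from a registered movie
#'
#' The trace value at frame `t` is the mean intensity over the tracked
#' component's pixels; the background is the median intensity outside all
#' components (dilated by 3 px), excluding registration zero-fill. Gaps of
#' at most `max_gap` frames are filled by linear interpolation; longer
#' gaps stay missing.
#'
#' @param registration A [register_movie()] result (list with `movie` and
#'   `shifts`), or a bare `projected_movie` (shifts assumed zero).
#' @param track_set A [track_movie()] result (identities assigned or not).
#' @param segmentations The per-frame segmentations used for tracking.
#' @param max_gap Longest gap run to interpolate across.
#' @return Tibble, one row per (neuron, frame): `movie_id, neuron_id, frame,
#'   time_s, raw, background, gap, interpolated`, with stimulus metadata as
#'   attributes. `gap` marks frames still missing after interpolation.
#' @export
extract_traces <- function(registration, track_set, segmentations,
                           max_gap = 10) {
  if (inherits(registration, "projected_movie")) {
    movie <- registration
    shifts <- tibble(frame = 0:(dim(movie$data)[3] - 1), dy = 0L, dx = 0L)
  } else {
    movie <- registration$movie
    shifts <- registration$shifts
  }
  if (isTRUE(track_set$failed))
    abort("extract_traces: tracking failed for this movie.",
          class = "wormtrace_tracking_failure")
  d <- dim(movie$data)
  Tn <- d[3]
  bg <- numeric(Tn)
  for (t in seq_len(Tn)) {
    img <- movie$data[, , t]
    excl <- background_exclusion(segmentations[[t]], d[1:2])
    valid <- registration_validity(d[1:2], shifts$dy[t], shifts$dx[t])
    px <- img[!excl & valid]
    bg[t] <- if (length(px)) median(px) else NA_real_
  }
  out <- lapply(track_set$tracks, function(tr) {
    if (isTRUE(tr$terminated))
      abort("extract_traces: track flagged as failed (gap run exceeded).",
            class = "wormtrace_tracking_failure")
    raw <- rep(NA_real_, Tn)
    for (t in seq_len(Tn)) {
      lab <- tr$data$label[t]
      if (!is.na(lab) && lab <= length(segmentations[[t]]$pixels))
        raw[t] <- mean(movie$data[, , t][segmentations[[t]]$pixels[[lab]]])
    }
    filled <- zoo::na.approx(raw, na.rm = FALSE, maxgap = max_gap)
    was_gap <- is.na(raw)
    tibble(movie_id = movie$source_id,
           neuron_id = if (is.na(tr$identity)) paste0("N", tr$track_id)
                       else tr$identity,
           frame = 0:(Tn - 1),
           time_s = (0:(Tn - 1)) * movie$frame_interval_s,
           raw = filled, background = bg,
           gap = is.na(filled), interpolated = was_gap & !is.na(filled))
  })
  new_trace(bind_rows(out), movie$frame_interval_s,
            movie$stimulus_onset_frame, movie$stimulus_duration_frames)
}

#' @rdname extract_traces
#' @param track A single track (element of `track_set$tracks`).
#' @export
extract_trace <- function(registration, track, segmentations, max_gap = 10) {
  ts <- structure(list(tracks = list(track), failed = FALSE), class = "track_set")
  extract_traces(registration, ts, segmentations, max_gap)
}

#' Normalize a raw trace to dF/F0
#'
#' `F` is the raw trace, background-subtracted when `subtract_background`
#' (the default); `F0` is the mean of `F` over all pre-onset frames and
#' `dff = (F - F0) / F0`. The mean of `dff` over the baseline window is 0
#' by construction.
#'
#' @param raw A trace tibble from [extract_traces()] (a single neuron, or
#'   several; each neuron is normalized independently).
#' @param subtract_background Subtract the per-frame background estimate?
#' @return The tibble with a `dff` column; `F0` and `baseline_sigma` (per
#'   neuron, named) as attributes.
#' @export
normalize_trace <- function(raw, subtract_background = TRUE) {
  onset <- trace_attr(raw, "stimulus_onset_frame")
  dur <- trace_attr(raw, "stimulus_duration_frames")
  dt <- trace_attr(raw, "frame_interval_s")
  if (is.null(onset))
    abort("normalize_trace: input lacks stimulus metadata.",
          class = "wormtrace_invalid_parameter")
  parts <- split(raw, paste(raw$movie_id, raw$neuron_id, sep = "\r"))
  f0s <- c(); sigmas <- c()
  res <- lapply(parts, function(df) {
    df <- df[order(df$frame), ]
    f <- if (subtract_background) df$raw - df$background else df$raw
    pre <- df$frame < onset & !is.na(f)
    if (sum(pre) < 5)
      abort("normalize_trace: fewer than 5 usable baseline frames before onset.",
            class = "wormtrace_degenerate_baseline")
    f0 <- mean(f[pre])
    if (!is.finite(f0) || f0 <= 0)
      abort("normalize_trace: nonpositive baseline F0.",
            class = "wormtrace_degenerate_baseline")
    df$dff <- (f - f0) / f0
    key <- paste(df$movie_id[1], df$neuron_id[1], sep = "\r")
    f0s[key] <<- f0
    sigmas[key] <<- sd(df$dff[pre])
    df
  })
  new_trace(bind_rows(res), dt, onset, dur,
            extra = list(F0 = f0s, baseline_sigma = sigmas))
}

#' Pool normalized traces after stimulus-onset synchronization
#'
#' Traces are re-indexed to `offset = frame - onset` (each trace's own
#' onset) and averaged per offset; offsets covered by fewer than two traces
#' are dropped.
#'
#' @param traces List of normalized trace tibbles (each possibly holding
#'   several neurons; every (movie, neuron) series pools separately).
#' @return Tibble `(offset, time_s, mean, sd, n)` of class
#'   `pooled_response`.
#' @export
pool_traces <- function(traces) {
  if (!length(traces))
    abort("pool_traces: empty input.", class = "wormtrace_invalid_parameter")
  if (is.data.frame(traces)) traces <- list(traces)
  dt <- trace_attr(traces[[1]], "frame_interval_s")
  long <- bind_rows(lapply(traces, function(tr) {
    onset <- trace_attr(tr, "stimulus_onset_frame")
    if (is.null(onset))
      abort("pool_traces: trace lacks an onset frame.",
            class = "wormtrace_invalid_parameter")
    tibble(series = paste(tr$movie_id, tr$neuron_id, sep = "\r"),
           offset = tr$frame - onset, dff = tr$dff)
  }))
  out <- long %>%
    filter(!is.na(.data$dff)) %>%
    group_by(.data$offset) %>%
    summarise(mean = mean(.data$dff), sd = sd(.data$dff), n = n(),
              .groups = "drop") %>%
    filter(.data$n >= 2) %>%
    mutate(time_s = .data$offset * dt) %>%
    select("offset", "time_s", "mean", "sd", "n")
  class(out) <- c("pooled_response", class(out))
  out
}

#' Classify a neuron's stimulus response
#'
#' The response peak is the maximum dF/F0 inside the stimulus window
#' extended by `lag_allow` frames. The call is `absent` when the peak is
#' below `max(k_sigma * baseline_sigma, theta_abs)`, `high` when at least
#' `theta_high`, otherwise `moderate`. Thresholds are recorded in the call.
#'
#' @param trace Normalized trace tibble (possibly several neurons).
#' @param theta_abs Absolute dF/F0 floor below which a response is absent.
#' @param theta_high dF/F0 at or above which a response is high.
#' @param k_sigma Baseline-noise multiple for the absent floor.
#' @param lag_allow Frames past stimulus offset still searched for a peak.
#' @return Tibble, one row per (movie, neuron): class, peak dF/F0, peak
#'   offset, thresholds used, baseline sigma, unclassifiable flag.
#' @export
classify_response <- function(trace, theta_abs = 0.2, theta_high = 0.8,
                              k_sigma = 3, lag_allow = 15) {
  onset <- trace_attr(trace, "stimulus_onset_frame")
  dur <- trace_attr(trace, "stimulus_duration_frames")
  dt <- trace_attr(trace, "frame_interval_s")
  sigmas <- trace_attr(trace, "baseline_sigma")
  parts <- split(trace, paste(trace$movie_id, trace$neuron_id, sep = "\r"))
  bind_rows(lapply(parts, function(df) {
    win <- df$frame >= onset & df$frame <= onset + dur + lag_allow
    dffw <- df$dff[win]
    sig <- unname(sigmas[paste(df$movie_id[1], df$neuron_id[1], sep = "\r")])
    base <- tibble(movie_id = df$movie_id[1], neuron_id = df$neuron_id[1],
                   class = NA_character_, peak_dff = NA_real_,
                   peak_offset_frames = NA_integer_, peak_offset_s = NA_real_,
                   theta_abs = theta_abs, theta_high = theta_high,
                   k_sigma = k_sigma, lag_allow = lag_allow,
                   baseline_sigma = sig, unclassifiable = TRUE)
    if (all(is.na(dffw))) return(base)
    peak <- max(dffw, na.rm = TRUE)
    pf <- df$frame[win][which.max(dffw)]
    cls <- if (peak < max(k_sigma * sig, theta_abs)) "absent"
           else if (peak >= theta_high) "high" else "moderate"
    base$class <- cls
    base$peak_dff <- peak
    base$peak_offset_frames <- as.integer(pf - onset)
    base$peak_offset_s <- (pf - onset) * dt
    base$unclassifiable <- FALSE
    base
  }))
}

#' Tabulate response-class fractions per condition
#'
#' @param calls Tibble of [classify_response()] rows with a grouping
#'   column.
#' @param condition Name of the grouping column.
#' @return Tibble `(condition, class, n, fraction)`; all three classes are
#'   present per condition and fractions sum to 1.
#' @export
summarize_calls <- function(calls, condition = "condition") {
  if (!nrow(calls))
    abort("summarize_calls: at least one call required.",
          class = "wormtrace_invalid_parameter")
  calls$class <- factor(calls$class, levels = c("high", "moderate", "absent"))
  calls %>%
    rename(condition = !!rlang::sym(condition)) %>%
    filter(!is.na(.data$class)) %>%
    count(.data$condition, .data$class, .drop = FALSE) %>%
    group_by(.data$condition) %>%
    mutate(fraction = .data$n / sum(.data$n)) %>%
    ungroup()
}

#' Compartment-ROI traces for single-plane light recordings
#'
#' For immobilized light-response recordings (stream mode, single Z) no
#' tracking is needed: per-frame mean intensity inside each named polygon
#' ROI (anterior neurite, posterior neurite, soma) is normalized to dF/F0
#' with the light-onset frame as the synchronization point.
#'
#' @param movie `projected_movie` or Y by X by T array.
#' @param rois Named list of polygon vertex matrices (0-based
#'   `(row, col)`, one vertex per row).
#' @param onset_frame 0-based light-onset frame.
#' @param frame_interval_s Frame interval (default 0.1 s, 10 fps).
#' @param subtract_background Passed to [normalize_trace()]; defaults off
#'   (no background ROI in this mode).
#' @return Normalized trace tibble with one `neuron_id` per compartment.
#' @export
compartment_traces <- function(movie, rois, onset_frame,
                               frame_interval_s = 0.1,
                               subtract_background = FALSE) {
  data <- if (inherits(movie, "projected_movie")) movie$data else movie
  d <- dim(data)
  Tn <- d[3]
  rows <- lapply(names(rois), function(nm) {
    mask <- rasterize_polygon(rois[[nm]], d[1:2])
    if (!any(mask))
      abort(paste0("compartment_traces: degenerate ROI '", nm, "'."),
            class = "wormtrace_invalid_parameter")
    idx <- which(mask)
    vals <- vapply(seq_len(Tn), function(t) mean(data[, , t][idx]), 0)
    tibble(movie_id = "light", neuron_id = nm, frame = 0:(Tn - 1),
           time_s = (0:(Tn - 1)) * frame_interval_s,
           raw = vals, background = 0, gap = FALSE, interpolated = FALSE)
  })
  raw <- new_trace(bind_rows(rows), frame_interval_s, onset_frame,
                   Tn - onset_frame)
  normalize_trace(raw, subtract_background = subtract_background)
}

#' Per-frame segmentations built from simulator ground truth
#'
#' Wraps the simulator's exact per-neuron masks as `frame_segmentation`
#' objects (component order = neuron order in the config), bypassing the
#' pixel classifier; useful for oracle checks of downstream stages.
#'
#' @param truth A `ground_truth`.
#' @param movie Optional `projected_movie` for component mean intensities.
#' @return List of `frame_segmentation`.
#' @export
truth_segmentations <- function(truth, movie = NULL) {
  cfg <- truth$config
  Tn <- cfg$n_frames
  H <- cfg$height_px
  lapply(seq_len(Tn), function(t) {
    pix <- lapply(truth$masks, function(m) m[[t]])
    comps <- bind_rows(lapply(seq_along(pix), function(i) {
      lin <- pix[[i]]
      tibble(label = i, area = length(lin),
             centroid_row = mean((lin - 1L) %% H),
             centroid_col = mean((lin - 1L) %/% H),
             mean_intensity = if (is.null(movie)) NA_real_
                              else mean(movie$data[, , t][lin]))
    }))
    structure(list(frame = t - 1L, components = comps,
                   pixels = unname(pix)), class = "frame_segmentation")
  })
}

#' Ground-truth track set (one gap-free track per simulated neuron)
#'
#' @param truth A `ground_truth`.
#' @return A `track_set` whose per-frame labels index the components of
#'   [truth_segmentations()].
#' @export
truth_track_set <- function(truth) {
  cfg <- truth$config
  Tn <- cfg$n_frames
  H <- cfg$height_px
  tracks <- lapply(seq_along(truth$masks), function(i) {
    rows <- vapply(truth$masks[[i]], function(lin) mean((lin - 1L) %% H), 0)
    cols <- vapply(truth$masks[[i]], function(lin) mean((lin - 1L) %/% H), 0)
    areas <- vapply(truth$masks[[i]], length, integer(1))
    list(track_id = i, identity = names(truth$masks)[i],
         data = tibble(frame = 0:(Tn - 1), row = rows, col = cols,
                       area = areas, label = i, gap = FALSE),
         terminated = FALSE, gap_run_max = 0L)
  })
  structure(list(tracks = tracks, failed = FALSE, n_frames = Tn),
            class = "track_set")
}
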