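# Multi-object tracking by per-frame globally optimal gated assignment
# ("distance minimization"): maximum-cardinality one-to-one matching between
# coasting track heads and detections, minimum total Euclidean distance among
# those, found by exact branch-and-bound enumeration (detection counts are a
# handful, so enumeration is exact and cheap).

# D: n_heads x n_detections distance matrix; returns det index per head (NA
# = unmatched), maximizing match count then minimizing total distance
gated_assignment <- function(D, gate) {
  nh <- nrow(D); nd <- ncol(D)
  allowed <- D <= gate
  best_count <- -1L; best_cost <- Inf
  best_asg <- rep(NA_integer_, nh)
  used <- logical(nd)
  asg <- rep(NA_integer_, nh)
  rec <- function(i, count, cost) {
    if (count + (nh - i + 1L) < best_count) return()
    if (i > nh) {
      if (count > best_count ||
          (count == best_count && cost < best_cost - 1e-12)) {
        best_count <<- count; best_cost <<- cost; best_asg <<- asg
      }
      return()
    }
    for (j in which(allowed[i, ] & !used)) {
      used[j] <<- TRUE; asg[i] <<- j
      rec(i + 1L, count + 1L, cost + D[i, j])
      used[j] <<- FALSE; asg[i] <<- NA_integer_
    }
    rec(i + 1L, count, cost)
  }
  if (nh > 0 && nd > 0) rec(1L, 0L, 0) else best_count <- 0L
  list(assignment = best_asg, total_distance = if (best_count > 0) best_cost else 0)
}

#' Link one frame's detections to active track heads
#'
#' One-to-one gated assignment minimizing total Euclidean centroid distance
#' (maximum number of matches first). Heads farther than `gate_px` from
#' every detection record a gap; detections matched to no head are reported
#' as unmatched.
#'
#' @param heads Tibble/data frame with columns `row`, `col` (one row per
#'   active track head).
#' @param detections Tibble/data frame with columns `row`, `col`.
#' @param gate_px Gating distance in pixels (> 0).
#' @return List: `assignment` (integer detection index per head, NA for a
#'   gap), `unmatched_detections`, `total_distance`.
#' @export
link_frame <- function(heads, detections, gate_px) {
  if (gate_px <= 0)
    abort("link_frame: gate_px must be positive.",
          class = "wormtrace_invalid_parameter")
  if (!("row" %in% names(heads)) && "centroid_row" %in% names(heads))
    heads <- rename(heads, row = "centroid_row", col = "centroid_col")
  if (!("row" %in% names(detections)) && "centroid_row" %in% names(detections))
    detections <- rename(detections, row = "centroid_row", col = "centroid_col")
  nh <- nrow(heads); nd <- nrow(detections)
  if (nh == 0L || nd == 0L)
    return(list(assignment = rep(NA_integer_, nh),
                unmatched_detections = seq_len(nd), total_distance = 0))
  D <- sqrt(outer(heads$row, detections$row, "-")^2 +
            outer(heads$col, detections$col, "-")^2)
  res <- gated_assignment(matrix(D, nh, nd), gate_px)
  list(assignment = res$assignment,
       unmatched_detections = setdiff(seq_len(nd),
                                      res$assignment[!is.na(res$assignment)]),
       total_distance = res$total_distance)
}

#' Track neurons across a segmented movie
#'
#' Seeds tracks from the first frame inside the initialization window that
#' carries at least `expected_count` components, then links frame by frame
#' with [link_frame()]; unmatched heads coast on their last centroid and
#' record gaps, unmatched detections may open candidate tracks only inside
#' the initialization window, and a track whose gap run exceeds `max_gap`
#' is terminated and flagged. The `expected_count` tracks with the longest
#' coverage are retained.
#'
#' @param segmentations List of `frame_segmentation` (one per frame, in
#'   order), as from [segment_movie()].
#' @param expected_count Number of neurons expected in the field.
#' @param gate_px Assignment gate in pixels.
#' @param max_gap Maximum tolerated gap run in frames.
#' @param init_window Number of leading frames in which tracks may be
#'   opened.
#' @return A `track_set`: list with `tracks` (each a list with `track_id`,
#'   `identity`, `terminated`, `gap_run_max` and `data`, a tibble
#'   `(frame, row, col, area, label, gap)` covering every frame) and
#'   `failed` (TRUE when no frame in the initialization window had
#'   `expected_count` detections).
#' @export
track_movie <- function(segmentations, expected_count = 2, gate_px = 15,
                        max_gap = 10, init_window = 10) {
  if (expected_count < 1)
    abort("track_movie: expected_count must be >= 1.",
          class = "wormtrace_invalid_parameter")
  Tn <- length(segmentations)
  det <- lapply(segmentations, function(s) s$components)
  seed_frame <- NA_integer_
  for (t in seq_len(min(init_window, Tn)))
    if (nrow(det[[t]]) >= expected_count) { seed_frame <- t; break }
  if (is.na(seed_frame))
    return(structure(list(tracks = list(), failed = TRUE, n_frames = Tn),
                     class = "track_set"))

  new_track <- function(t, comp_row) {
    list(head = c(comp_row$centroid_row, comp_row$centroid_col),
         frames = t, rows = comp_row$centroid_row,
         cols = comp_row$centroid_col, areas = comp_row$area,
         labels = comp_row$label, gap_run = 0L, gap_run_max = 0L,
         terminated = FALSE, start = t)
  }
  tracks <- lapply(seq_len(min(expected_count, nrow(det[[seed_frame]]))),
                   function(i) new_track(seed_frame, det[[seed_frame]][i, ]))

  if (seed_frame < Tn) for (t in (seed_frame + 1L):Tn) {
    active <- which(!vapply(tracks, `[[`, logical(1), "terminated"))
    d <- det[[t]]
    hr <- vapply(tracks[active], function(x) x$head[1], 0)
    hc <- vapply(tracks[active], function(x) x$head[2], 0)
    nd <- nrow(d)
    if (length(active) && nd) {
      D <- sqrt(outer(hr, d$centroid_row, "-")^2 +
                outer(hc, d$centroid_col, "-")^2)
      ga <- gated_assignment(matrix(D, length(active), nd), gate_px)
      lk <- list(assignment = ga$assignment,
                 unmatched_detections = setdiff(seq_len(nd),
                   ga$assignment[!is.na(ga$assignment)]))
    } else {
      lk <- list(assignment = rep(NA_integer_, length(active)),
                 unmatched_detections = seq_len(nd))
    }
    for (i in seq_along(active)) {
      tr <- tracks[[active[i]]]
      j <- lk$assignment[i]
      if (!is.na(j)) {
        tr$head <- c(d$centroid_row[j], d$centroid_col[j])
        tr$frames <- c(tr$frames, t)
        tr$rows <- c(tr$rows, d$centroid_row[j])
        tr$cols <- c(tr$cols, d$centroid_col[j])
        tr$areas <- c(tr$areas, d$area[j])
        tr$labels <- c(tr$labels, d$label[j])
        tr$gap_run <- 0L
      } else {
        tr$gap_run <- tr$gap_run + 1L
        tr$gap_run_max <- max(tr$gap_run_max, tr$gap_run)
        if (tr$gap_run > max_gap) tr$terminated <- TRUE
      }
      tracks[[active[i]]] <- tr
    }
    if (t <= init_window && length(lk$unmatched_detections))
      for (j in lk$unmatched_detections)
        tracks[[length(tracks) + 1L]] <- new_track(t, d[j, ])
  }

  coverage <- vapply(tracks, function(x) length(x$frames), integer(1))
  keep <- order(coverage, decreasing = TRUE)[seq_len(min(expected_count,
                                                         length(tracks)))]
  keep <- sort(keep)
  out <- lapply(seq_along(keep), function(i) {
    tr <- tracks[[keep[i]]]
    data <- tibble(frame = 0:(Tn - 1), row = NA_real_, col = NA_real_,
                   area = NA_integer_, label = NA_integer_, gap = TRUE)
    data$row[tr$frames] <- tr$rows
    data$col[tr$frames] <- tr$cols
    data$area[tr$frames] <- tr$areas
    data$label[tr$frames] <- tr$labels
    data$gap[tr$frames] <- FALSE
    list(track_id = i, identity = NA_character_, data = data,
         terminated = tr$terminated, gap_run_max = tr$gap_run_max)
  })
  failed <- length(out) < expected_count ||
    any(vapply(out, `[[`, logical(1), "terminated"))
  structure(list(tracks = out, failed = failed, n_frames = Tn),
            class = "track_set")
}

#' Name a two-track set "left"/"right" by image position
#'
#' The track with the smaller median column becomes `"left"`. Naming is
#' image-frame, not anatomical (trapped animals can face either way); ties
#' on median column are broken by median row and flagged.
#'
#' @param track_set A [track_movie()] result with exactly two retained
#'   tracks.
#' @return The `track_set` with `identity` set on each track (and a
#'   `tie_flag` field).
#' @export
assign_pair_identity <- function(track_set) {
  if (length(track_set$tracks) != 2L)
    abort("assign_pair_identity: exactly two retained tracks required.",
          class = "wormtrace_invalid_parameter")
  med <- vapply(track_set$tracks, function(tr)
    median(tr$data$col[!tr$data$gap]), 0)
  tie <- FALSE
  if (med[1] == med[2]) {
    tie <- TRUE
    med <- med + 1e-9 * vapply(track_set$tracks, function(tr)
      median(tr$data$row[!tr$data$gap]), 0)
  }
  left <- which.min(med)
  track_set$tracks[[left]]$identity <- "left"
  track_set$tracks[[3L - left]]$identity <- "right"
  track_set$tie_flag <- tie
  track_set
}
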