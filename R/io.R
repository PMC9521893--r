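# Movie containers and TIFF/CSV/JSON I/O. In memory an image is a base R
# matrix indexed (row, col) = (y, x); stacks are Y x X x Z x T arrays and
# projections Y x X x T, with frames 0-based in all tabular output. On disk
# a stack is a plain multi-page 16-bit TIFF in T-major page order (page =
# t * n_z + z) with a JSON sidecar carrying the acquisition metadata.

#' Construct a movie stack
#'
#' @param data Y by X by Z by T array of nonnegative integer intensities.
#' @param pixel_size_um,z_step_um,frame_interval_s Acquisition geometry.
#' @param stimulus_onset_frame,stimulus_duration_frames Stimulus window,
#'   0-based frames; must lie within the recording.
#' @param source_id Identifier carried into tabular outputs.
#' @return A `movie_stack` object.
#' @export
movie_stack <- function(data, pixel_size_um, z_step_um, frame_interval_s,
                        stimulus_onset_frame, stimulus_duration_frames,
                        source_id = "movie") {
  d <- dim(data)
  if (length(d) != 4L || any(d < 1L))
    abort("movie_stack: `data` must be a Y x X x Z x T array.",
          class = "wormtrace_invalid_parameter")
  if (frame_interval_s <= 0)
    abort("movie_stack: frame_interval_s must be positive.",
          class = "wormtrace_invalid_parameter")
  if (stimulus_onset_frame < 0 ||
      stimulus_onset_frame + stimulus_duration_frames > d[4])
    abort("movie_stack: stimulus window outside the recording.",
          class = "wormtrace_invalid_parameter")
  structure(list(data = data, pixel_size_um = pixel_size_um,
                 z_step_um = z_step_um, frame_interval_s = frame_interval_s,
                 stimulus_onset_frame = as.integer(stimulus_onset_frame),
                 stimulus_duration_frames = as.integer(stimulus_duration_frames),
                 source_id = source_id),
            class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<movie_stack '%s': %d frames, %d Z, %d x %d px, dt = %gs, stimulus [%d, %d)>\n",
              x$source_id, d[4], d[3], d[1], d[2], x$frame_interval_s,
              x$stimulus_onset_frame,
              x$stimulus_onset_frame + x$stimulus_duration_frames))
  invisible(x)
}

projected_movie <- function(data, parent) {
  structure(list(data = data, pixel_size_um = parent$pixel_size_um,
                 z_step_um = parent$z_step_um,
                 frame_interval_s = parent$frame_interval_s,
                 stimulus_onset_frame = parent$stimulus_onset_frame,
                 stimulus_duration_frames = parent$stimulus_duration_frames,
                 source_id = parent$source_id),
            class = "projected_movie")
}

#' @export
print.projected_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<projected_movie '%s': %d frames, %d x %d px>\n",
              x$source_id, d[3], d[1], d[2]))
  invisible(x)
}

#' Maximum-intensity Z projection
#'
#' Voxel-wise maximum over Z, collapsing a stack to a 2-D movie, as used
#' before registration and segmentation.
#'
#' @param stack A [movie_stack()].
#' @return A `projected_movie`.
#' @export
max_project <- function(stack) {
  if (!inherits(stack, "movie_stack"))
    abort("max_project: input must be a movie_stack.",
          class = "wormtrace_invalid_parameter")
  d <- dim(stack$data)
  proj <- stack$data[, , 1, , drop = TRUE]
  if (d[4] == 1L) proj <- array(proj, dim = d[c(1, 2, 4)])
  if (d[3] > 1L)
    for (z in 2:d[3]) {
      pl <- stack$data[, , z, , drop = TRUE]
      if (d[4] == 1L) pl <- array(pl, dim = d[c(1, 2, 4)])
      proj <- pmax(proj, pl)
    }
  dim(proj) <- d[c(1, 2, 4)]
  projected_movie(proj, stack)
}

#' Write a movie stack as multi-page TIFF plus JSON sidecar
#'
#' @param stack A [movie_stack()].
#' @param path TIFF output path.
#' @param sidecar_path JSON sidecar path; default `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, sidecar_path = paste0(path, ".json")) {
  d <- dim(stack$data)
  pages <- vector("list", d[3] * d[4])
  k <- 1L
  for (t in seq_len(d[4])) for (z in seq_len(d[3])) {
    pages[[k]] <- stack$data[, , z, t] / 65535
    k <- k + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- list(pixel_size_um = stack$pixel_size_um,
               z_step_um = stack$z_step_um,
               frame_interval_s = stack$frame_interval_s,
               stimulus_onset_frame = stack$stimulus_onset_frame,
               stimulus_duration_frames = stack$stimulus_duration_frames,
               n_z = d[3], n_frames = d[4], source_id = stack$source_id)
  jsonlite::write_json(meta, sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a movie stack from multi-page TIFF plus JSON sidecar
#'
#' @param path TIFF path (pages in T-major order, T*Z pages).
#' @param sidecar_path JSON sidecar path.
#' @return A [movie_stack()].
#' @export
read_stack <- function(path, sidecar_path = paste0(path, ".json")) {
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  required <- c("pixel_size_um", "z_step_um", "frame_interval_s",
                "stimulus_onset_frame", "stimulus_duration_frames", "n_z")
  missing <- setdiff(required, names(meta))
  if (length(missing))
    abort(paste0("read_stack: sidecar missing required metadata key(s): ",
                 paste(missing, collapse = ", ")),
          class = "wormtrace_metadata_error")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  nz <- as.integer(meta$n_z)
  if (length(pages) %% nz != 0L)
    abort(sprintf("read_stack: %d TIFF pages not divisible by n_z = %d.",
                  length(pages), nz),
          class = "wormtrace_metadata_error")
  Tn <- length(pages) %/% nz
  d1 <- dim(pages[[1]])
  data <- array(0L, dim = c(d1[1], d1[2], nz, Tn))
  k <- 1L
  for (t in seq_len(Tn)) for (z in seq_len(nz)) {
    data[, , z, t] <- as.integer(pages[[k]])
    k <- k + 1L
  }
  movie_stack(data, meta$pixel_size_um, meta$z_step_um, meta$frame_interval_s,
              meta$stimulus_onset_frame, meta$stimulus_duration_frames,
              source_id = meta$source_id %||% basename(path))
}

#' Write per-neuron traces to CSV
#'
#' One row per (neuron, frame) with columns `movie_id, neuron_id, frame,
#' time_s, raw, background, dff, gap`; gap frames carry empty `raw` and a
#' set gap flag.
#'
#' @param traces Tibble in the trace schema (see [extract_trace()] /
#'   [normalize_trace()]).
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  cols <- c("movie_id", "neuron_id", "frame", "time_s", "raw",
            "background", "dff", "gap")
  for (cn in setdiff(cols, names(traces))) traces[[cn]] <- NA
  write.csv(traces[cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read traces written by [write_traces()]
#' @param path CSV path.
#' @return Tibble in the trace schema.
#' @export
read_traces <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$gap <- as.logical(df$gap)
  as_tibble(df)
}
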