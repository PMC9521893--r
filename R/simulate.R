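# Synthetic movie / static-image generators with exact ground truth.
# Somata are rendered as isotropic Gaussian blobs scaled so that the mean
# over the ground-truth mask (footprint >= 10% of peak) equals
# B * (1 + A * k(t)) * bleach(t); ground-truth traces are then read back
# from the rendered noiseless projection, so simulator and oracle agree
# exactly by construction.

# fold a real walk into [-m, m] by reflection
fold_reflect <- function(x, m) {
  if (m <= 0) return(x * 0)
  abs(((x + m) %% (4 * m)) - 2 * m) - m
}

neuron_patch <- function(spec) {
  sigma <- spec$radius_px
  h <- ceiling(sigma * sqrt(2 * log(10))) + 2
  r0 <- floor(spec$centroid[1]) + 1L
  c0 <- floor(spec$centroid[2]) + 1L
  rows <- (r0 - h):(r0 + h)
  cols <- (c0 - h):(c0 + h)
  dr <- (rows - 1) - spec$centroid[1]
  dc <- (cols - 1) - spec$centroid[2]
  g <- exp(-outer(dr^2, dc^2, "+") / (2 * sigma^2))
  mask <- g >= 0.1 * max(g)
  list(rows = rows, cols = cols, g = g, mask = mask, gbar = mean(g[mask]))
}

quantize_u16 <- function(x) {
  storage <- as.integer(pmin(pmax(round(x), 0), 65535))
  storage
}

#' Simulate a time-lapse recording with full ground truth
#'
#' Renders the scene described by a [scene_config()]: a linear background
#' plane that translates with the whole-field drift walk, Gaussian somata
#' whose in-mask mean follows `B * (1 + A * k(t - onset))`, plane-dependent
#' defocus across Z, optional bleaching, then Poisson shot noise and
#' Gaussian read noise, quantized to unsigned 16-bit.
#'
#' @param config A [scene_config()].
#' @param keep_noiseless Also return the noiseless projected stack in the
#'   ground truth (memory permitting); useful for oracle checks.
#' @return A list with `movie` (a [movie_stack()]) and `truth`, a
#'   `ground_truth` list carrying per-frame integer shifts, per-neuron
#'   per-frame masks (linear pixel indices), noiseless traces, true classes,
#'   the background series and the generating config.
#' @export
simulate_movie <- function(config, keep_noiseless = FALSE) {
  if (!inherits(config, "scene_config"))
    abort("simulate_movie: `config` must be a scene_config.",
          class = "wormtrace_invalid_parameter")
  H <- config$height_px; W <- config$width_px
  Tn <- config$n_frames; Z <- config$n_z
  dt <- config$frame_interval_s
  nn <- length(config$neurons)
  set.seed(config$seed)

  ## whole-field motion: reflected Gaussian walk + integer twitch jumps
  steps <- matrix(rnorm(2 * Tn, 0, config$drift_step_sd_px), Tn, 2)
  steps[1, ] <- 0
  if (config$twitch_prob > 0 && config$twitch_max_px > 0) {
    hit <- runif(Tn) < config$twitch_prob
    hit[1] <- FALSE
    if (any(hit)) {
      jumps <- sample(seq(-config$twitch_max_px, config$twitch_max_px),
                      2 * sum(hit), replace = TRUE)
      steps[hit, ] <- steps[hit, ] + matrix(jumps, sum(hit), 2)
    }
  }
  walk <- apply(steps, 2, cumsum)
  if (Tn == 1) walk <- matrix(walk, 1, 2)
  walk <- fold_reflect(walk, config$drift_max_px)
  shifts <- round(walk)

  prep <- lapply(config$neurons, neuron_patch)
  tvec0 <- 0:(Tn - 1)
  bleach <- exp(-config$bleach_rate_per_frame * tvec0)
  target <- matrix(0, nn, Tn)   # in-mask blob mean, before bleach
  for (i in seq_len(nn)) {
    ns <- config$neurons[[i]]
    tsince <- (tvec0 - config$stimulus_onset_frame) * dt - ns$onset_lag_s
    k <- transient_kernel(tsince, ns$tau_rise_s, ns$tau_decay_s)
    target[i, ] <- ns$baseline * (1 + ns$amplitude * k)
  }
  zf <- ceiling(Z / 2)
  wz <- exp(-((seq_len(Z)) - zf)^2 / (2 * 1.5^2))

  data <- array(0L, dim = c(H, W, Z, Tn))
  masks <- lapply(seq_len(nn), function(i) vector("list", Tn))
  traces <- matrix(NA_real_, Tn, nn)
  clipped <- logical(Tn)
  bg_series <- numeric(Tn)
  noiseless <- if (keep_noiseless) array(0, dim = c(H, W, Tn)) else NULL

  xs0 <- 0:(W - 1)
  for (t in seq_len(Tn)) {
    dy <- shifts[t, 1]; dx <- shifts[t, 2]
    bgv <- config$background_level +
      config$background_gradient * (xs0 - (W - 1) / 2 - dx)
    bg <- bleach[t] * matrix(rep(pmax(bgv, 0), each = H), H, W)
    bg_series[t] <- median(bg)

    ## noiseless max projection (focal weight 1) and ground-truth bookkeeping
    proj <- bg
    patches <- vector("list", nn)
    for (i in seq_len(nn)) {
      p <- prep[[i]]
      rows <- p$rows + dy; cols <- p$cols + dx
      okr <- rows >= 1 & rows <= H
      okc <- cols >= 1 & cols <= W
      amp <- bleach[t] * target[i, t] / p$gbar
      gsub <- p$g[okr, okc, drop = FALSE]
      msub <- p$mask[okr, okc, drop = FALSE]
      if (any(p$mask & !(okr %o% okc))) clipped[t] <- TRUE
      ridx <- rows[okr]; cidx <- cols[okc]
      patches[[i]] <- list(ridx = ridx, cidx = cidx, g = gsub, amp = amp)
      proj[ridx, cidx] <- proj[ridx, cidx] + amp * gsub
      midx <- which(msub)
      lin <- (rep(cidx, each = length(ridx))[midx] - 1L) * H +
             rep(ridx, length(cidx))[midx]
      masks[[i]][[t]] <- as.integer(lin)
    }
    for (i in seq_len(nn)) {
      lin <- masks[[i]][[t]]
      traces[t, i] <- if (length(lin)) mean(proj[lin]) else NA_real_
    }
    if (keep_noiseless) noiseless[, , t] <- proj

    for (z in seq_len(Z)) {
      pl <- bg
      for (i in seq_len(nn)) {
        pc <- patches[[i]]
        if (length(pc$ridx) && length(pc$cidx))
          pl[pc$ridx, pc$cidx] <- pl[pc$ridx, pc$cidx] + wz[z] * pc$amp * pc$g
      }
      v <- as.numeric(pl)
      if (config$shot_noise) v <- as.numeric(rpois(length(v), v))
      if (config$read_noise_sd > 0) v <- v + rnorm(length(v), 0, config$read_noise_sd)
      data[, , z, t] <- quantize_u16(v)
    }
  }

  movie <- movie_stack(data,
                       pixel_size_um = config$pixel_size_um,
                       z_step_um = config$z_step_um,
                       frame_interval_s = dt,
                       stimulus_onset_frame = config$stimulus_onset_frame,
                       stimulus_duration_frames = config$stimulus_duration_frames,
                       source_id = paste0("sim-seed", config$seed))

  ids <- vapply(config$neurons, function(n) n$neuron_id, character(1))
  truth <- structure(list(
    shifts = tibble(frame = tvec0, dy = shifts[, 1], dx = shifts[, 2],
                    clipped = clipped),
    masks = setNames(masks, ids),
    traces = tibble(frame = rep(tvec0, times = nn),
                    neuron_id = rep(ids, each = Tn),
                    value = as.numeric(traces)),
    classes = tibble(neuron_id = ids,
                     class = vapply(config$neurons,
                                    function(n) n$true_class, character(1))),
    background_series = bg_series,
    noiseless_projection = noiseless,
    config = config), class = "ground_truth")
  list(movie = movie, truth = truth)
}

#' Simulate a static Z-stack with known ROI means
#'
#' Fixture generator for background-subtracted fluorescence quantification:
#' renders labelled objects (uniform discs or Gaussian blobs) on a flat or
#' linearly graded background and reports, per object, the exact noiseless
#' background-subtracted mean over its footprint.
#'
#' @param objects List of lists with fields `id`, `centroid` (0-based
#'   `(row, col)`), `radius_px`, `value` (background-subtracted in-footprint
#'   mean, counts) and optional `shape` (`"disc"` default, or `"gaussian"`).
#' @param height_px,width_px,n_z Stack geometry.
#' @param background_level,background_gradient Background plane (counts,
#'   counts/px along columns).
#' @param shot_noise,read_noise_sd Noise controls.
#' @param seed Integer seed.
#' @return List with `stack` (Y by X by Z integer array), `truth` (tibble:
#'   object_id, mean, area), and `masks` (linear pixel indices per object).
#' @export
simulate_static_image <- function(objects, height_px = 128, width_px = 128,
                                  n_z = 1, background_level = 30,
                                  background_gradient = 0,
                                  shot_noise = FALSE, read_noise_sd = 0,
                                  seed = 1L) {
  H <- as.integer(height_px); W <- as.integer(width_px); Z <- as.integer(n_z)
  set.seed(as.integer(seed))
  xs0 <- 0:(W - 1)
  bgv <- background_level + background_gradient * (xs0 - (W - 1) / 2)
  bg <- matrix(rep(pmax(bgv, 0), each = H), H, W)
  proj <- bg
  masks <- list(); truth <- list()
  for (ob in objects) {
    shape <- if (is.null(ob$shape)) "disc" else ob$shape
    r0 <- ob$centroid[1]; c0 <- ob$centroid[2]
    if (r0 < 0 || r0 > H - 1 || c0 < 0 || c0 > W - 1)
      abort("simulate_static_image: object centroid out of bounds.",
            class = "wormtrace_invalid_parameter")
    if (shape == "disc") {
      h <- ceiling(ob$radius_px) + 1
      rows <- max(1, floor(r0) + 1 - h):min(H, floor(r0) + 1 + h)
      cols <- max(1, floor(c0) + 1 - h):min(W, floor(c0) + 1 + h)
      d2 <- outer(((rows - 1) - r0)^2, ((cols - 1) - c0)^2, "+")
      m <- d2 <= ob$radius_px^2
      add <- ob$value * m
    } else {
      p <- neuron_patch(list(centroid = ob$centroid, radius_px = ob$radius_px))
      rows <- p$rows; cols <- p$cols
      keep_r <- rows >= 1 & rows <= H; keep_c <- cols >= 1 & cols <= W
      rows <- rows[keep_r]; cols <- cols[keep_c]
      g <- p$g[keep_r, keep_c, drop = FALSE]
      m <- p$mask[keep_r, keep_c, drop = FALSE]
      add <- (ob$value / p$gbar) * g
    }
    proj[rows, cols] <- proj[rows, cols] + add
    midx <- which(m)
    lin <- (rep(cols, each = length(rows))[midx] - 1L) * H +
           rep(rows, length(cols))[midx]
    masks[[ob$id]] <- as.integer(lin)
    truth[[ob$id]] <- tibble(object_id = ob$id,
                             mean = mean(proj[lin]) - mean(bg[lin]),
                             area = length(lin))
  }
  zf <- ceiling(Z / 2)
  wz <- exp(-((seq_len(Z)) - zf)^2 / (2 * 1.5^2))
  stack <- array(0L, dim = c(H, W, Z))
  for (z in seq_len(Z)) {
    pl <- bg + wz[z] * (proj - bg)
    v <- as.numeric(pl)
    if (isTRUE(shot_noise)) v <- as.numeric(rpois(length(v), v))
    if (read_noise_sd > 0) v <- v + rnorm(length(v), 0, read_noise_sd)
    stack[, , z] <- quantize_u16(v)
  }
  list(stack = stack, truth = bind_rows(truth), masks = masks)
}

#' Draw seeded i.i.d. samples for statistical-test harnesses
#'
#' @param n_groups Number of groups.
#' @param n_per_group Observations per group (>= 3).
#' @param distribution `"gaussian"`, `"lognormal"`, `"uniform"` or
#'   `"exponential"`.
#' @param params Named list of distribution parameters (e.g.
#'   `list(mean = 0, sd = 1)`).
#' @param shift Optional numeric vector of per-group location shifts
#'   (recycled); defaults to 0 (a null configuration).
#' @param seed Integer seed.
#' @return Named list of numeric vectors, one per group.
#' @export
simulate_null_samples <- function(n_groups, n_per_group,
                                  distribution = "gaussian",
                                  params = list(), shift = 0, seed = 1L) {
  if (n_per_group < 3)
    abort("simulate_null_samples: n_per_group must be >= 3.",
          class = "wormtrace_invalid_parameter")
  set.seed(as.integer(seed))
  draw <- switch(distribution,
    gaussian    = function(n) rnorm(n, params$mean %||% 0, params$sd %||% 1),
    lognormal   = function(n) rlnorm(n, params$meanlog %||% 0, params$sdlog %||% 1),
    uniform     = function(n) runif(n, params$min %||% 0, params$max %||% 1),
    exponential = function(n) rexp(n, params$rate %||% 1),
    abort(paste0("simulate_null_samples: unknown distribution '",
                 distribution, "'."),
          class = "wormtrace_invalid_parameter"))
  shift <- rep_len(shift, n_groups)
  out <- lapply(seq_len(n_groups), function(i) draw(n_per_group) + shift[i])
  setNames(out, paste0("group_", seq_len(n_groups)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
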