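make_raw_trace <- function(raw, onset = 10, dur = 20, dt = 2,
                           background = 0, neuron = "left", movie = "m1") {
  n <- length(raw)
  df <- tibble::tibble(movie_id = movie, neuron_id = neuron,
                       frame = 0:(n - 1), time_s = (0:(n - 1)) * dt,
                       raw = raw, background = background,
                       gap = is.na(raw), interpolated = FALSE)
  structure(df, frame_interval_s = dt, stimulus_onset_frame = onset,
            stimulus_duration_frames = dur)
}

test_that("traces from exact masks reproduce the simulator's noiseless traces", {
  sim <- simulate_movie(tiny_scene(seed = 1, n_frames = 40,
                                   shot_noise = FALSE, read_noise_sd = 0))
  proj <- max_project(sim$movie)
  segs <- truth_segmentations(sim$truth, proj)
  ts <- truth_track_set(sim$truth)
  raw <- extract_traces(proj, ts, segs)
  for (nm in names(sim$truth$masks)) {
    got <- raw$raw[raw$neuron_id == nm]
    want <- sim$truth$traces$value[sim$truth$traces$neuron_id == nm]
    # rendered movie is quantized to integer counts: agreement to 1 count
    expect_lt(max(abs(got - want)), 1)
  }
})

test_that("uniform frames give the frame value; short gaps interpolate linearly", {
  data <- array(50, dim = c(16, 16, 5))
  pm <- wormtrace:::projected_movie(
    data, list(pixel_size_um = 1, z_step_um = 1, frame_interval_s = 2,
               stimulus_onset_frame = 1, stimulus_duration_frames = 2,
               source_id = "u"))
  segs <- lapply(1:5, function(t)
    structure(list(frame = t - 1L,
                   components = tibble::tibble(label = 1L, area = 4L,
                                               centroid_row = 5,
                                               centroid_col = 5,
                                               mean_intensity = 50),
                   pixels = list(c(70L, 71L, 86L, 87L))),
              class = "frame_segmentation"))
  ts <- structure(list(tracks = list(list(
    track_id = 1, identity = "left", terminated = FALSE, gap_run_max = 1L,
    data = tibble::tibble(frame = 0:4, row = 5, col = 5, area = 4L,
                          label = c(1L, 1L, NA, 1L, 1L),
                          gap = c(FALSE, FALSE, TRUE, FALSE, FALSE)))),
    failed = FALSE, n_frames = 5), class = "track_set")
  tr <- extract_traces(pm, ts, segs)
  expect_equal(tr$raw[c(1, 2, 4, 5)], rep(50, 4))
  expect_equal(tr$raw[3], 50)    # interpolated between equal neighbours
  expect_true(tr$interpolated[3])

  # interpolation between unequal neighbours: 10 -> NA -> 14 gives 12
  filled <- zoo::na.approx(c(10, NA, 14), na.rm = FALSE, maxgap = 10)
  expect_equal(filled[2], 12)
})

test_that("failed tracking refuses trace extraction", {
  sim <- simulate_movie(tiny_scene(seed = 2, n_frames = 20))
  proj <- max_project(sim$movie)
  segs <- truth_segmentations(sim$truth, proj)
  ts <- truth_track_set(sim$truth)
  ts$failed <- TRUE
  expect_error(extract_traces(proj, ts, segs),
               class = "wormtrace_tracking_failure")
})

test_that("dF/F0 normalization honours its contract", {
  const <- normalize_trace(make_raw_trace(rep(80, 40)))
  expect_true(all(abs(const$dff) < 1e-12))

  raw <- rep(100, 40); raw[20] <- 200          # F = 2 F0 at 0-based frame 19
  tr <- normalize_trace(make_raw_trace(raw))
  expect_equal(tr$dff[tr$frame == 19], 1)
  expect_lt(abs(mean(tr$dff[tr$frame < 10])), 1e-9)
  expect_equal(attr(tr, "F0")[[1]], 100)

  expect_error(normalize_trace(make_raw_trace(rep(-5, 40))),
               class = "wormtrace_degenerate_baseline")
  expect_error(normalize_trace(make_raw_trace(c(rep(NA, 8), rep(100, 32)))),
               class = "wormtrace_degenerate_baseline")
})

test_that("dF/F0 is invariant to intensity rescaling", {
  sim <- simulate_movie(tiny_scene(seed = 3, n_frames = 40))
  proj <- max_project(sim$movie)
  segs <- truth_segmentations(sim$truth, proj)
  ts <- truth_track_set(sim$truth)
  n1 <- normalize_trace(extract_traces(proj, ts, segs),
                        subtract_background = FALSE)
  proj2 <- proj
  proj2$data <- proj$data * 3.7
  n2 <- normalize_trace(extract_traces(proj2, ts, segs),
                        subtract_background = FALSE)
  expect_equal(n1$dff, n2$dff, tolerance = 1e-12)
})

test_that("pooling aligns onsets and averages exactly", {
  t1 <- normalize_trace(make_raw_trace(c(rep(100, 10), 100 + 40 * exp(-(0:29) / 5)),
                                       onset = 10))
  t2raw <- c(rep(100, 15), 100 + 40 * exp(-(0:24) / 5))
  t2 <- normalize_trace(make_raw_trace(t2raw, onset = 15, movie = "m2"))
  pooled <- pool_traces(list(t1, t2))
  expect_true(all(pooled$n <= 2))
  # peaks align at offset 0 after synchronization
  expect_equal(pooled$offset[which.max(pooled$mean)], 0)

  same <- lapply(1:5, function(i)
    normalize_trace(make_raw_trace(c(rep(100, 10), 130, rep(100, 19)),
                                   onset = 10, movie = paste0("m", i))))
  p5 <- pool_traces(same)
  expect_true(all(p5$sd == 0))
  expect_equal(max(p5$mean), 0.3)
  expect_true(all(p5$n == 5))

  # pooled mean equals direct recomputation over contributing traces
  long <- do.call(rbind, lapply(list(t1, t2), function(tr)
    data.frame(offset = tr$frame - attr(tr, "stimulus_onset_frame"),
               dff = tr$dff)))
  want <- aggregate(dff ~ offset, long, mean)
  have <- merge(as.data.frame(pooled), want, by = "offset")
  expect_equal(have$mean, have$dff, tolerance = 1e-12)
  expect_error(pool_traces(list()), class = "wormtrace_invalid_parameter")
})

test_that("response classes follow the thresholds and amplitude ordering", {
  mk <- function(peak, noise_sd = 0.001, seed = 1) {
    set.seed(seed)
    raw <- 100 + rnorm(60, 0, noise_sd * 100)
    raw[26:35] <- raw[26:35] + peak * 100
    normalize_trace(make_raw_trace(raw, onset = 25, dur = 20))
  }
  expect_equal(classify_response(mk(0))$class, "absent")
  expect_equal(classify_response(mk(0.5))$class, "moderate")
  expect_equal(classify_response(mk(1.6))$class, "high")

  # monotone: increasing amplitude never demotes the class
  lv <- c(absent = 1, moderate = 2, high = 3)
  cls <- vapply(c(0, 0.1, 0.3, 0.5, 0.9, 1.6, 3),
                function(a) classify_response(mk(a))$class, "")
  expect_true(all(diff(lv[cls]) >= 0))

  # the absent floor also respects baseline noise (k_sigma * sigma)
  noisy <- classify_response(mk(0, noise_sd = 0.2, seed = 2))
  expect_equal(noisy$class, "absent")

  gap <- make_raw_trace(c(rep(100, 25), rep(NA, 35)), onset = 25, dur = 20)
  gap$dff <- c(rep(0, 25), rep(NA, 35))
  attr(gap, "baseline_sigma") <- c("m1\rleft" = 0)
  expect_true(classify_response(gap)$unclassifiable)
})

test_that("call summaries give complete per-condition fractions", {
  calls <- tibble::tibble(class = c("high", "high", "absent"),
                          condition = "wt")
  fr <- summarize_calls(calls)
  expect_equal(nrow(fr), 3)
  expect_equal(fr$fraction[fr$class == "high"], 2 / 3)
  expect_equal(fr$fraction[fr$class == "moderate"], 0)
  expect_equal(sum(fr$fraction), 1)
  expect_error(summarize_calls(calls[0, ]),
               class = "wormtrace_invalid_parameter")
})

test_that("compartment ROIs trace soma-only transients and ignore flat neurites", {
  H <- 48; W <- 48; Tn <- 60
  data <- array(100, dim = c(H, W, Tn))
  # soma blob at (24, 24) brightens from frame 21
  for (t in 21:40) data[20:28, 20:28, t] <- 100 + 80 * exp(-(t - 21) / 8)
  rois <- list(
    soma = rbind(c(18, 18), c(18, 30), c(30, 30), c(30, 18)),
    anterior_neurite = rbind(c(5, 5), c(5, 12), c(10, 12), c(10, 5)),
    posterior_neurite = rbind(c(38, 38), c(38, 45), c(43, 45), c(43, 38)))
  tr <- compartment_traces(data, rois, onset_frame = 20)
  soma <- tr$dff[tr$neuron_id == "soma"]
  expect_gt(max(soma), 0.3)
  for (nm in c("anterior_neurite", "posterior_neurite"))
    expect_lt(max(abs(tr$dff[tr$neuron_id == nm])), 1e-9)

  uni <- compartment_traces(array(77, dim = c(H, W, 30)), rois,
                            onset_frame = 10)
  expect_true(all(abs(uni$dff) < 1e-12))

  tr2 <- compartment_traces(data * 2.5, rois, onset_frame = 20)
  expect_equal(tr$dff, tr2$dff, tolerance = 1e-12)

  bad <- list(soma = rbind(c(1, 1), c(1, 1), c(1, 1)))
  expect_error(compartment_traces(data, bad, onset_frame = 20),
               class = "wormtrace_invalid_parameter")
})
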