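# Small, fast scenes for unit tests.

tiny_scene <- function(seed = 1, n_frames = 60, amplitude = c(1.6, 0.5),
                       drift_step_sd_px = 0.4, twitch_prob = 0.02,
                       shot_noise = TRUE, read_noise_sd = 4,
                       background_gradient = 0.3, bleach = 0, n_z = 2) {
  onset <- min(15L, n_frames %/% 3)
  scene_config(
    height_px = 64, width_px = 64, n_frames = n_frames, n_z = n_z,
    stimulus_onset_frame = onset,
    stimulus_duration_frames = min(30L, n_frames - onset),
    neurons = list(
      neuron_spec("N1", c(24, 20), radius_px = 2.5, baseline = 120,
                  amplitude = amplitude[1]),
      neuron_spec("N2", c(42, 46), radius_px = 2.5, baseline = 100,
                  amplitude = amplitude[2])),
    drift_step_sd_px = drift_step_sd_px, drift_max_px = 6,
    twitch_prob = twitch_prob, twitch_max_px = 2,
    background_level = 100, background_gradient = background_gradient,
    read_noise_sd = read_noise_sd, shot_noise = shot_noise,
    bleach_rate_per_frame = bleach, seed = seed)
}

static_scene <- function(seed = 1, amplitude = c(1.6, 0.5), ...) {
  tiny_scene(seed = seed, amplitude = amplitude, drift_step_sd_px = 0,
             twitch_prob = 0, ...)
}

# run the segmentation+tracking front end of a simulated scene
segment_and_track <- function(sim, params = benchmark_params(),
                              label_seed = 1) {
  proj <- max_project(sim$movie)
  reg <- register_movie(proj, params$max_shift)
  onset <- sim$truth$config$stimulus_onset_frame
  Tn <- sim$truth$config$n_frames
  tf <- sort(unique(c(round(seq(0, Tn - 1, length.out = 5)),
                      onset + round(seq(1, 8, length.out = 5)))))
  labels <- training_labels_from_truth(sim$truth, frames = tf,
                                       seed = label_seed)
  frames <- lapply(tf + 1, function(t) proj$data[, , t])
  clf <- train_pixel_classifier(
    frames, labels,
    feature_config = feature_bank_config(params$feature_transform,
                                         params$feature_scale),
    seed = label_seed)
  segs <- segment_movie(reg$movie, clf, params$min_area,
                        params$expected_count)
  ts <- track_movie(segs, params$expected_count, params$gate_px,
                    params$max_gap, params$init_window)
  list(proj = proj, reg = reg, clf = clf, segs = segs, track_set = ts)
}
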