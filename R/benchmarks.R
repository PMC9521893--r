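# Canonical synthetic study conditions. These generators freeze the scene
# parameters used throughout the package's validation: geometry and stimulus
# timing follow the acquisition being emulated (350 frames at 2 s, onset
# frame 40, 100-frame stimulus), response classes are built well inside the
# classifier bands, and noise is the default Poisson + 4-count read noise.

#' Two-neuron scene for end-to-end classification benchmarks
#'
#' 128 x 128 px, 350 frames, stimulus frames 40-139, two somata with the
#' stated response class: `absent` A = 0, `moderate` A = 0.5, `high`
#' A = 1.6 (twice the high threshold). Default drift/twitch motion and
#' noise; mild background gradient.
#'
#' @param class `"high"`, `"moderate"` or `"absent"`.
#' @param seed Scene seed.
#' @param n_z Z planes (2 keeps projection exercised at benchmark scale).
#' @return A [scene_config()].
#' @export
classification_scene <- function(class = c("high", "moderate", "absent"),
                                 seed = 1L, n_z = 2L) {
  class <- match.arg(class)
  A <- switch(class, high = 1.6, moderate = 0.5, absent = 0)
  kin_fast <- kinetics_preset("fast"); kin_slow <- kinetics_preset("slow")
  scene_config(
    height_px = 128, width_px = 128, n_frames = 350, n_z = n_z,
    stimulus_onset_frame = 40, stimulus_duration_frames = 100,
    neurons = list(
      neuron_spec("N1", c(54, 44), radius_px = 3, baseline = 130,
                  amplitude = A, tau_rise_s = kin_fast$tau_rise_s,
                  tau_decay_s = kin_fast$tau_decay_s, true_class = class),
      neuron_spec("N2", c(74, 84), radius_px = 3, baseline = 100,
                  amplitude = A, tau_rise_s = kin_slow$tau_rise_s,
                  tau_decay_s = kin_slow$tau_decay_s, true_class = class)),
    drift_step_sd_px = 0.4, twitch_prob = 0.02, twitch_max_px = 3,
    background_level = 100, background_gradient = 0.2,
    read_noise_sd = 4, shot_noise = TRUE, seed = seed)
}

#' Scene suite for the end-to-end classification benchmark
#'
#' @param n_per_class Movies per response class.
#' @param seed Base seed; scene seeds are derived from it.
#' @param n_z Z planes per movie.
#' @return List with `scenes` and the `classes` vector.
#' @export
classification_suite <- function(n_per_class = 20, seed = 1L, n_z = 2L) {
  classes <- rep(c("high", "moderate", "absent"), each = n_per_class)
  scenes <- lapply(seq_along(classes), function(i)
    classification_scene(classes[i], seed = as.integer(seed) * 100L + i,
                         n_z = n_z))
  list(scenes = scenes, classes = classes)
}

#' Strong-motion scene for registration benchmarks
#'
#' 50 frames with a vigorous reflected drift walk (step SD 2 px, bounded at
#' 10 px) plus frequent twitches, so ground-truth integer shifts span the
#' +-10 px range.
#'
#' @param n_frames Number of frames.
#' @param seed Scene seed.
#' @return A [scene_config()].
#' @export
registration_scene <- function(n_frames = 50, seed = 1L) {
  scene_config(
    height_px = 128, width_px = 128, n_frames = n_frames, n_z = 1,
    stimulus_onset_frame = 0, stimulus_duration_frames = 0,
    neurons = list(
      neuron_spec("N1", c(54, 44), radius_px = 3, baseline = 150,
                  amplitude = 0, true_class = "absent"),
      neuron_spec("N2", c(74, 84), radius_px = 3, baseline = 120,
                  amplitude = 0, true_class = "absent")),
    drift_step_sd_px = 2, drift_max_px = 10, twitch_prob = 0.1,
    twitch_max_px = 3, background_level = 100, background_gradient = 0.3,
    read_noise_sd = 4, shot_noise = TRUE, seed = seed)
}

#' Gradient-background scene for the segmentation benchmark
#'
#' Strong linear background gradient (0.6 counts/px) plus photobleaching
#' (brightness varies in time and space), the regime where a single global
#' threshold is inadequate but a trained pixel classifier is not.
#'
#' @param seed Scene seed.
#' @return A [scene_config()].
#' @export
gradient_scene <- function(seed = 1L) {
  scene_config(
    height_px = 128, width_px = 128, n_frames = 350, n_z = 1,
    stimulus_onset_frame = 40, stimulus_duration_frames = 100,
    neurons = list(
      neuron_spec("N1", c(54, 40), radius_px = 3, baseline = 130,
                  amplitude = 1.6, true_class = "high"),
      neuron_spec("N2", c(74, 88), radius_px = 3, baseline = 100,
                  amplitude = 1.6, true_class = "high")),
    drift_step_sd_px = 0, twitch_prob = 0, twitch_max_px = 0,
    background_level = 100, background_gradient = 0.6,
    read_noise_sd = 4, shot_noise = TRUE,
    bleach_rate_per_frame = 0.0015, seed = seed)
}

#' Amplitude-sweep scene for the trace-recovery benchmark
#'
#' Compact geometry (96 x 96 px, 150 frames, single plane, stimulus frames
#' 30-89) with default noise; used across A in {0.2, 0.5, 1, 2}.
#'
#' @param amplitude Response amplitude A (dF/F0 units) for both somata.
#' @param seed Scene seed.
#' @return A [scene_config()].
#' @export
amplitude_scene <- function(amplitude, seed = 1L) {
  scene_config(
    height_px = 96, width_px = 96, n_frames = 150, n_z = 1,
    stimulus_onset_frame = 30, stimulus_duration_frames = 60,
    neurons = list(
      neuron_spec("N1", c(40, 30), radius_px = 3.5, baseline = 150,
                  amplitude = amplitude),
      neuron_spec("N2", c(60, 66), radius_px = 3.5, baseline = 150,
                  amplitude = amplitude)),
    drift_step_sd_px = 0.4, twitch_prob = 0.02, twitch_max_px = 3,
    background_level = 100, background_gradient = 0.2,
    read_noise_sd = 4, shot_noise = TRUE, seed = seed)
}

#' Pipeline parameters used by the batch benchmarks
#'
#' The package defaults, including the full feature bank (identity;
#' gaussian 1, 2, 4; median 3, 5; range 3, 5). The full bank is load-bearing
#' for quantitative trace recovery: with fewer scales the tree draws its
#' soma boundary inconsistently across brightness levels, inflating the
#' baseline and diluting the peak.
#'
#' @param ... [pipeline_params()] overrides.
#' @return A [pipeline_params()] list.
#' @export
benchmark_params <- function(...) {
  pipeline_params(...)
}
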