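#' GCaMP-like transient kernel
#'
#' Normalized rise-times-decay double exponential used to shape simulated
#' calcium transients: `k(t) = c * (1 - exp(-t/tau_rise)) * exp(-t/tau_decay)`
#' with `c` chosen so that `max(k) = 1`. The analytic maximum is at
#' `t* = tau_rise * log(1 + tau_decay/tau_rise)`. For `t < 0` the kernel is 0.
#'
#' @param t Time since response onset, seconds. Vectorized.
#' @param tau_rise_s,tau_decay_s Rise and decay time constants in seconds;
#'   both positive and `tau_decay_s > tau_rise_s`.
#' @return Numeric vector of kernel values in `[0, 1]`.
#' @examples
#' transient_kernel(c(0, 5, 60), tau_rise_s = 2.5, tau_decay_s = 6)
#' @export
transient_kernel <- function(t, tau_rise_s, tau_decay_s) {
  if (!is.numeric(tau_rise_s) || !is.numeric(tau_decay_s) ||
      length(tau_rise_s) != 1L || length(tau_decay_s) != 1L ||
      !is.finite(tau_rise_s) || !is.finite(tau_decay_s) ||
      tau_rise_s <= 0 || tau_decay_s <= 0) {
    abort("`tau_rise_s` and `tau_decay_s` must be positive finite scalars.",
          class = "wormtrace_invalid_parameter")
  }
  if (tau_decay_s <= tau_rise_s) {
    abort("`tau_decay_s` must exceed `tau_rise_s`.",
          class = "wormtrace_invalid_parameter")
  }
  t_star <- tau_rise_s * log(1 + tau_decay_s / tau_rise_s)
  peak <- (1 - exp(-t_star / tau_rise_s)) * exp(-t_star / tau_decay_s)
  k <- ifelse(t < 0, 0,
              (1 - exp(-t / tau_rise_s)) * exp(-t / tau_decay_s) / peak)
  pmin(pmax(k, 0), 1)
}

#' Kinetic presets for simulated neurons
#'
#' `"fast"` reproduces an I2-like photoresponse that completes within
#' 10-15 s on a 2 s frame grid; `"slow"` a PHA-like response taking roughly
#' twice as long (~30 s) to return to baseline.
#'
#' @param preset `"fast"` or `"slow"`.
#' @return Named list with `tau_rise_s` and `tau_decay_s`.
#' @export
kinetics_preset <- function(preset = c("fast", "slow")) {
  preset <- match.arg(preset)
  switch(preset,
         fast = list(tau_rise_s = 2.5, tau_decay_s = 6),
         slow = list(tau_rise_s = 4, tau_decay_s = 15))
}

#' Specify a simulated neuron soma
#'
#' @param neuron_id Identifier string (e.g. `"N1"`).
#' @param centroid Length-2 numeric `(row, col)` in 0-based pixels.
#' @param radius_px Gaussian footprint scale (sigma) in pixels; the
#'   ground-truth mask is the footprint above 10% of its peak.
#' @param baseline Baseline fluorescence `B` in camera counts: the in-mask
#'   mean of the rendered blob at rest (before any background is added).
#' @param amplitude Response amplitude `A` in dF/F0 units; the in-mask mean
#'   rises to `B * (1 + A * k(t))` during the transient.
#' @param tau_rise_s,tau_decay_s Transient kinetics (seconds); defaults are
#'   the `"fast"` preset.
#' @param onset_lag_s Lag between stimulus onset and response onset, seconds.
#' @param true_class Ground-truth response class; if `NULL`, inferred from
#'   `amplitude` with the default classification thresholds (`< 0.2` absent,
#'   `>= 0.8` high, otherwise moderate). Amplitudes near a threshold should
#'   be labelled explicitly.
#' @return A `neuron_spec` list.
#' @export
neuron_spec <- function(neuron_id, centroid, radius_px = 3, baseline = 100,
                        amplitude = 1,
                        tau_rise_s = 2.5, tau_decay_s = 6,
                        onset_lag_s = 0, true_class = NULL) {
  if (radius_px <= 0 || baseline <= 0 || amplitude < 0 || onset_lag_s < 0) {
    abort("neuron_spec: radius_px and baseline must be positive; amplitude and onset_lag_s nonnegative.",
          class = "wormtrace_invalid_parameter")
  }
  if (tau_decay_s <= tau_rise_s) {
    abort("neuron_spec: tau_decay_s must exceed tau_rise_s.",
          class = "wormtrace_invalid_parameter")
  }
  if (is.null(true_class)) {
    true_class <- if (amplitude < 0.2) "absent"
                  else if (amplitude >= 0.8) "high" else "moderate"
  }
  true_class <- match.arg(true_class, c("high", "moderate", "absent"))
  if (amplitude == 0 && true_class != "absent") {
    abort("neuron_spec: amplitude 0 implies true_class 'absent'.",
          class = "wormtrace_invalid_parameter")
  }
  structure(list(neuron_id = as.character(neuron_id),
                 centroid = as.numeric(centroid), radius_px = radius_px,
                 baseline = baseline, amplitude = amplitude,
                 tau_rise_s = tau_rise_s, tau_decay_s = tau_decay_s,
                 onset_lag_s = onset_lag_s, true_class = true_class),
            class = "neuron_spec")
}

#' Configure a synthetic recording scene
#'
#' Defaults emulate the acquisition used for H2O2 responses of trapped
#' *C. elegans*: 350 time points at 2 s intervals, a 10-15 plane Z-stack,
#' stimulus perfused after 40 frames for 100 frames, two somata per field,
#' slow drift with occasional twitches, Poisson shot noise plus Gaussian
#' read noise.
#'
#' @param height_px,width_px Image size in pixels.
#' @param n_frames Number of time points.
#' @param n_z Number of Z planes.
#' @param frame_interval_s Seconds between frames.
#' @param stimulus_onset_frame 0-based frame at which the stimulus starts.
#' @param stimulus_duration_frames Stimulus window length in frames.
#' @param neurons List of [neuron_spec()] objects.
#' @param drift_step_sd_px SD of the per-frame Gaussian drift step (pixels).
#' @param drift_max_px Reflection bound on the drift walk (pixels).
#' @param twitch_prob Per-frame probability of a twitch jump.
#' @param twitch_max_px Maximum twitch jump per axis (integer pixels).
#' @param background_level Background fluorescence level (counts).
#' @param background_gradient Linear background slope, counts per pixel
#'   along columns (centered on the field).
#' @param read_noise_sd SD of additive Gaussian read noise (counts).
#' @param shot_noise Apply Poisson shot noise?
#' @param bleach_rate_per_frame Exponential photobleaching rate per frame.
#' @param pixel_size_um,z_step_um Geometry metadata carried on the output.
#' @param seed Integer seed; fully determines the scene.
#' @return A `scene_config` list.
#' @export
scene_config <- function(height_px = 128, width_px = 128, n_frames = 350,
                         n_z = 12, frame_interval_s = 2,
                         stimulus_onset_frame = 40,
                         stimulus_duration_frames = 100,
                         neurons = list(),
                         drift_step_sd_px = 0.4, drift_max_px = 10,
                         twitch_prob = 0.02, twitch_max_px = 3,
                         background_level = 100, background_gradient = 0,
                         read_noise_sd = 4, shot_noise = TRUE,
                         bleach_rate_per_frame = 0,
                         pixel_size_um = 0.33, z_step_um = 10,
                         seed = 1L) {
  cfg <- list(height_px = as.integer(height_px), width_px = as.integer(width_px),
              n_frames = as.integer(n_frames), n_z = as.integer(n_z),
              frame_interval_s = frame_interval_s,
              stimulus_onset_frame = as.integer(stimulus_onset_frame),
              stimulus_duration_frames = as.integer(stimulus_duration_frames),
              neurons = neurons,
              drift_step_sd_px = drift_step_sd_px, drift_max_px = drift_max_px,
              twitch_prob = twitch_prob, twitch_max_px = as.integer(twitch_max_px),
              background_level = background_level,
              background_gradient = background_gradient,
              read_noise_sd = read_noise_sd, shot_noise = isTRUE(shot_noise),
              bleach_rate_per_frame = bleach_rate_per_frame,
              pixel_size_um = pixel_size_um, z_step_um = z_step_um,
              seed = as.integer(seed))
  validate_scene_config(cfg)
  structure(cfg, class = "scene_config")
}

validate_scene_config <- function(cfg) {
  with(cfg, {
    if (height_px < 1 || width_px < 1 || n_frames < 1 || n_z < 1)
      abort("scene_config: dimensions must be positive.",
            class = "wormtrace_invalid_parameter")
    if (frame_interval_s <= 0)
      abort("scene_config: frame_interval_s must be positive.",
            class = "wormtrace_invalid_parameter")
    if (stimulus_onset_frame < 0 || stimulus_duration_frames < 0 ||
        stimulus_onset_frame + stimulus_duration_frames > n_frames)
      abort("scene_config: stimulus window must lie within the recording.",
            class = "wormtrace_invalid_parameter")
    if (drift_step_sd_px < 0 || twitch_prob < 0 || twitch_prob > 1 ||
        twitch_max_px < 0 || background_level < 0 || read_noise_sd < 0 ||
        bleach_rate_per_frame < 0)
      abort("scene_config: noise/motion parameters out of range.",
            class = "wormtrace_invalid_parameter")
    for (n in neurons) {
      if (!inherits(n, "neuron_spec"))
        abort("scene_config: neurons must be neuron_spec objects.",
              class = "wormtrace_invalid_parameter")
      if (n$centroid[1] < 0 || n$centroid[1] > height_px - 1 ||
          n$centroid[2] < 0 || n$centroid[2] > width_px - 1)
        abort(paste0("scene_config: centroid of ", n$neuron_id,
                     " outside image bounds."),
              class = "wormtrace_invalid_parameter")
    }
  })
  invisible(cfg)
}
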