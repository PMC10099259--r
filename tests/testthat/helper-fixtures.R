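# Shared fixtures, built in code at test time.

default_subject <- function(bw = 700, stance = 0.6, p0 = 0.5,
                            met5c = 0.60, met1c = 0.72,
                            gains = c(heel = 0.55, met1 = 0.45, met5 = 0.25),
                            group = "different") {
  subject_profile("S001", body_weight = bw, stance_duration = stance,
                  ap_crossing_phase = p0, met5_center = met5c,
                  met1_center = met1c, channel_gains = gains,
                  timing_group = group)
}

noiseless_config <- function(n_subjects = 1, seed = 5, ...) {
  synthetic_config(n_subjects, seed = seed, swing_noise_sd = 0,
                   sensor_noise_sd = 0, ...)
}

noiseless_trial <- function(seed = 5, subject = default_subject()) {
  cfg <- noiseless_config(seed = seed)
  generate_trial(subject, cfg, gait_rng(seed))
}

tiny_model_config <- function(epochs = 5L, seed = 3L, widths = c(8L, 4L))
  grf_model_config(lstm_widths = widths, epochs = epochs, seed = seed,
                   batch_size = 4L)

# A small synthetic segment set for model tests: a few subjects, short stance.
tiny_segments <- function(n_subjects = 4, seed = 9, noiseless = TRUE) {
  cfg <- if (noiseless) noiseless_config(n_subjects, seed = seed,
                                         trials_per_subject = 1L)
         else synthetic_config(n_subjects, seed = seed,
                               trials_per_subject = 1L)
  ds <- generate_dataset(cfg)
  lapply(ds$trials, function(tr)
    synchronize_pair(tr$lc, tr$fp, timing_group = tr$timing_group))
}
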