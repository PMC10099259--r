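#' Waveform shape parameters for the synthetic gait generator
#'
#' Parameters of the analytic stance-phase waveforms used by the generator.
#' Vertical GRF is an M-shaped curve built from two Gaussian bumps under a
#' half-sine taper; AP GRF is a braking (negative) then propulsive (positive)
#' lobe crossing zero at the subject's mid-stance phase; ML GRF is a small
#' single-lobe curve whose amplitude is coupled to the subject's metatarsal
#' gain ratio; the three load-cell channels are Gaussian bumps reproducing
#' the heel -> 5th metatarsal -> 1st metatarsal loading progression.
#'
#' @param a1,a2 Amplitudes (multiples of body weight) of the early- and
#'   late-stance vertical bumps.
#' @param sigma_v Width (stance fraction) of the vertical bumps.
#' @param gamma Exponent of the `sin(pi*p)` endpoint taper.
#' @param bump1,bump2 Phase centers of the vertical bumps.
#' @param ap_amp AP lobe amplitude as a fraction of body weight.
#' @param ml_c0,ml_c1 ML amplitude coupling: the amplitude is
#'   `(ml_c0 + ml_c1 * gain_met1/gain_met5) * body_weight`.
#' @param heel_gain,met1_gain,met5_gain Baseline load-cell channel gains
#'   (fractions of body weight; per-subject gains are jittered around these).
#' @param heel_center Phase center of the heel load-cell bump.
#' @param lc_sigma Width (stance fraction) of the load-cell bumps. The
#'   default 0.15 is calibrated so that, over default synthetic datasets, the
#'   pooled correlation between the load-cell sum and the vertical GRF falls
#'   near 0.84, the value observed with real instrumented shoes.
#' @param met5_center,met1_center Baseline phase centers of the 5th- and
#'   1st-metatarsal bumps (per-subject values are drawn around these).
#' @return A named list of shape parameters.
#' @export
grf_waveform_params <- function(a1 = 1.2, a2 = 1.15, sigma_v = 0.18,
                                gamma = 0.5, bump1 = 0.25, bump2 = 0.75,
                                ap_amp = 0.18, ml_c0 = 0.03, ml_c1 = 0.02,
                                heel_gain = 0.55, met1_gain = 0.45,
                                met5_gain = 0.25, heel_center = 0.22,
                                lc_sigma = 0.15, met5_center = 0.60,
                                met1_center = 0.72) {
  list(a1 = a1, a2 = a2, sigma_v = sigma_v, gamma = gamma,
       bump1 = bump1, bump2 = bump2, ap_amp = ap_amp,
       ml_c0 = ml_c0, ml_c1 = ml_c1,
       heel_gain = heel_gain, met1_gain = met1_gain, met5_gain = met5_gain,
       heel_center = heel_center, lc_sigma = lc_sigma,
       met5_center = met5_center, met1_center = met1_center)
}

gauss_bump <- function(p, mu, sigma) exp(-(p - mu)^2 / (2 * sigma^2))

check_phase <- function(phase) {
  if (!is.numeric(phase) || anyNA(phase) || any(phase < 0 | phase > 1))
    stop("'phase' must lie in [0, 1]", call. = FALSE)
}

#' Subject profile for the synthetic generator
#'
#' @param subject_id Identifier string.
#' @param body_weight Body weight in newtons (> 0).
#' @param stance_duration Stance-phase duration in seconds (0, 2).
#' @param ap_crossing_phase Stance fraction at which the AP GRF crosses from
#'   braking to propulsion, in (0.3, 0.7).
#' @param met5_center,met1_center Phase centers of the metatarsal load-cell
#'   bumps, in (0, 1).
#' @param channel_gains Named numeric vector `c(heel=, met1=, met5=)` of
#'   positive gains (fractions of body weight).
#' @param timing_group `"similar"` (1st and 5th metatarsal load essentially
#'   simultaneously) or `"different"` (5th metatarsal loads first, the
#'   common pattern).
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, body_weight, stance_duration,
                            ap_crossing_phase, met5_center, met1_center,
                            channel_gains, timing_group) {
  stopifnot(body_weight > 0, stance_duration > 0, stance_duration < 2,
            ap_crossing_phase > 0.3, ap_crossing_phase < 0.7,
            met5_center > 0, met5_center < 1,
            met1_center > 0, met1_center < 1,
            length(channel_gains) == 3, all(channel_gains > 0))
  timing_group <- match.arg(timing_group, c("similar", "different"))
  if (timing_group == "different" && met5_center > met1_center)
    stop("different-timing subjects must have met5_center <= met1_center",
         call. = FALSE)
  if (timing_group == "similar" && abs(met5_center - met1_center) >= 0.02)
    stop("similar-timing subjects must have |met5_center - met1_center| < 0.02",
         call. = FALSE)
  if (is.null(names(channel_gains)))
    names(channel_gains) <- c("heel", "met1", "met5")
  structure(list(subject_id = as.character(subject_id),
                 body_weight = body_weight,
                 stance_duration = stance_duration,
                 ap_crossing_phase = ap_crossing_phase,
                 met5_center = met5_center, met1_center = met1_center,
                 channel_gains = channel_gains,
                 timing_group = timing_group),
            class = "subject_profile")
}

#' Synthetic dataset configuration
#'
#' Study-scale defaults mirror the walking experiment the generator stands in
#' for: two trials per subject, 0.59 s mean stance, load cells sampled at
#' 100 Hz and the force plate at 120 Hz.
#'
#' @param n_subjects Number of subjects.
#' @param trials_per_subject Trials per subject (default 2).
#' @param seed Integer seed driving all sampling.
#' @param stance_duration_mean,stance_duration_sd Stance duration (s).
#' @param body_weight_mean,body_weight_sd Body weight (N).
#' @param swing_noise_sd Load-cell swing-phase noise sd (N).
#' @param sensor_noise_sd In-stance sensor noise sd (N), both instruments.
#' @param fraction_similar_timing Probability a subject is similar-timing.
#' @param lc_rate,fp_rate Native sampling rates (Hz).
#' @param waveform Shape parameters, see [grf_waveform_params()].
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects, trials_per_subject = 2L, seed = 1L,
                             stance_duration_mean = 0.59,
                             stance_duration_sd = 0.04,
                             body_weight_mean = 650, body_weight_sd = 90,
                             swing_noise_sd = 1.5, sensor_noise_sd = 2.0,
                             fraction_similar_timing = 0.25,
                             lc_rate = 100, fp_rate = 120,
                             waveform = grf_waveform_params()) {
  stopifnot(n_subjects >= 1, trials_per_subject >= 1,
            stance_duration_sd >= 0, body_weight_sd >= 0,
            swing_noise_sd >= 0, sensor_noise_sd >= 0,
            fraction_similar_timing >= 0, fraction_similar_timing <= 1,
            lc_rate > 30, fp_rate > 30)  # both must resolve the 15 Hz band
  structure(list(n_subjects = as.integer(n_subjects),
                 trials_per_subject = as.integer(trials_per_subject),
                 seed = as.integer(seed),
                 stance_duration_mean = stance_duration_mean,
                 stance_duration_sd = stance_duration_sd,
                 body_weight_mean = body_weight_mean,
                 body_weight_sd = body_weight_sd,
                 swing_noise_sd = swing_noise_sd,
                 sensor_noise_sd = sensor_noise_sd,
                 fraction_similar_timing = fraction_similar_timing,
                 lc_rate = lc_rate, fp_rate = fp_rate,
                 waveform = waveform),
            class = "synthetic_config")
}

#' Stance-phase GRF and load-cell waveforms
#'
#' Analytic noiseless waveforms as a function of stance phase
#' `p = (t - heel_strike) / stance_duration`. All return newtons and are
#' exactly zero at both stance endpoints (for the GRF channels).
#'
#' @param phase Stance phase, in \[0, 1\] (vectorized).
#' @param subject A [subject_profile()].
#' @param waveform Shape parameters, see [grf_waveform_params()].
#' @return `vertical_grf_waveform`, `ap_grf_waveform`, `ml_grf_waveform`: a
#'   numeric vector of forces (N). `loadcell_waveforms`: a matrix with
#'   columns `heel`, `met1`, `met5`.
#' @export
vertical_grf_waveform <- function(phase, subject,
                                  waveform = grf_waveform_params()) {
  check_phase(phase)
  w <- waveform
  taper <- pmax(sinpi(phase), 0)^w$gamma
  subject$body_weight *
    (w$a1 * gauss_bump(phase, w$bump1, w$sigma_v) +
     w$a2 * gauss_bump(phase, w$bump2, w$sigma_v)) * taper
}

#' @rdname vertical_grf_waveform
#' @export
ap_grf_waveform <- function(phase, subject,
                            waveform = grf_waveform_params()) {
  check_phase(phase)
  w <- waveform
  p0 <- subject$ap_crossing_phase
  B <- w$ap_amp * subject$body_weight
  taper <- pmax(sinpi(phase), 0)^w$gamma
  lobe <- ifelse(phase <= p0,
                 -sinpi(phase / p0),
                 sinpi((phase - p0) / (1 - p0)))
  B * lobe * taper
}

#' @rdname vertical_grf_waveform
#' @export
ml_grf_waveform <- function(phase, subject,
                            waveform = grf_waveform_params()) {
  check_phase(phase)
  w <- waveform
  g <- subject$channel_gains
  if (g[["met5"]] == 0)
    stop("gain_met5 must be positive (ML amplitude couples to met1/met5)",
         call. = FALSE)
  C <- (w$ml_c0 + w$ml_c1 * g[["met1"]] / g[["met5"]]) * subject$body_weight
  C * sinpi(phase) * (1 + 0.3 * sinpi(2 * phase))
}

#' @rdname vertical_grf_waveform
#' @export
loadcell_waveforms <- function(phase, subject,
                               waveform = grf_waveform_params()) {
  check_phase(phase)
  w <- waveform
  g <- subject$channel_gains
  bw <- subject$body_weight
  cbind(heel = g[["heel"]] * bw * gauss_bump(phase, w$heel_center, w$lc_sigma),
        met1 = g[["met1"]] * bw * gauss_bump(phase, subject$met1_center, w$lc_sigma),
        met5 = g[["met5"]] * bw * gauss_bump(phase, subject$met5_center, w$lc_sigma))
}

new_recording <- function(class, subject_id, trial_id, sample_rate,
                          time, channels) {
  structure(list(subject_id = subject_id, trial_id = trial_id,
                 sample_rate = sample_rate, time = time,
                 channels = channels),
            class = class)
}

# Truncated-normal draw by rejection; bounds are wide so this terminates fast.
rtruncnorm1 <- function(mean, sd, lo, hi) {
  if (sd == 0) return(min(max(mean, lo), hi))
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
}

sample_subject <- function(i, config) {
  w <- config$waveform
  stance <- rtruncnorm1(config$stance_duration_mean,
                        config$stance_duration_sd, 0.4, 0.9)
  bw <- rtruncnorm1(config$body_weight_mean, config$body_weight_sd, 400, 1000)
  gains <- c(heel = w$heel_gain, met1 = w$met1_gain, met5 = w$met5_gain) *
    stats::runif(3, 0.8, 1.2)
  similar <- stats::runif(1) < config$fraction_similar_timing
  if (similar) {
    center <- stats::runif(1, 0.62, 0.70)
    met5c <- center + stats::runif(1, -0.009, 0.009)
    met1c <- center + stats::runif(1, -0.009, 0.009)
    group <- "similar"
  } else {
    met5c <- stats::runif(1, w$met5_center - 0.04, w$met5_center + 0.04)
    met1c <- stats::runif(1, w$met1_center - 0.04, w$met1_center + 0.04)
    group <- "different"
  }
  p0 <- 0.45 + 0.25 * (met1c - met5c) + stats::rnorm(1, 0, 0.01)
  p0 <- min(max(p0, 0.35), 0.65)
  subject_profile(subject_id = sprintf("S%03d", i), body_weight = bw,
                  stance_duration = stance, ap_crossing_phase = p0,
                  met5_center = met5c, met1_center = met1c,
                  channel_gains = gains, timing_group = group)
}

# Swing padding on each side of stance, seconds. Kept well above the decay
# length of the 15 Hz zero-phase filter (about 0.3 s to the 1e-7 level) so
# synchronization is lag-invariant at the 1e-6 N level.
SWING_PAD_S <- 0.5

LOADCELL_CAPACITY_N <- 980.70

#' Generate one paired synthetic walking trial
#'
#' Produces a load-cell recording at its native rate (heel, met1, met5
#' channels; small zero-mean noise in swing, waveform plus sensor noise in
#' stance), a force-plate recording at its native rate (vertical, AP, ML;
#' exactly zero outside foot contact), and a ground-truth sidecar with the
#' event times and noiseless peak forces.
#'
#' @param subject A [subject_profile()].
#' @param config A [synthetic_config()].
#' @param rng A [gait_rng()] stream (required; no hidden global state).
#' @param trial_id Identifier for the trial.
#' @return A list with elements `lc` (`loadcell_recording`), `fp`
#'   (`forceplate_recording`) and `truth` (list: `heel_strike_time`,
#'   `toe_off_time`, `ap_crossing_time`, `peak_vertical`, `peak_ap`,
#'   `peak_ml`).
#' @export
generate_trial <- function(subject, config, rng, trial_id = "T1") {
  if (missing(rng) || !inherits(rng, "gait_rng"))
    stop("generate_trial() requires an explicit gait_rng stream", call. = FALSE)
  hs <- SWING_PAD_S
  toe <- hs + subject$stance_duration
  dur <- toe + SWING_PAD_S
  w <- config$waveform

  sample_channels <- function(rate, grf) {
    t <- seq(0, floor(dur * rate)) / rate
    stance <- t >= hs & t <= toe
    # guard against roundoff pushing the phase a few ulp outside [0, 1]
    p <- pmin(pmax((t[stance] - hs) / subject$stance_duration, 0), 1)
    n <- length(t)
    if (grf) {
      ch <- matrix(0, n, 3, dimnames = list(NULL, c("vertical", "ap", "ml")))
      ch[stance, "vertical"] <- vertical_grf_waveform(p, subject, w)
      ch[stance, "ap"] <- ap_grf_waveform(p, subject, w)
      ch[stance, "ml"] <- ml_grf_waveform(p, subject, w)
      if (config$sensor_noise_sd > 0)
        ch[stance, ] <- ch[stance, ] +
          rng_draw(rng, function()
            stats::rnorm(sum(stance) * 3, 0, config$sensor_noise_sd))
    } else {
      ch <- matrix(0, n, 3, dimnames = list(NULL, c("heel", "met1", "met5")))
      ch[stance, ] <- loadcell_waveforms(p, subject, w)
      noise_sd <- ifelse(stance, config$sensor_noise_sd, config$swing_noise_sd)
      if (any(noise_sd > 0))
        ch <- ch + rng_draw(rng, function()
          matrix(stats::rnorm(n * 3), n, 3) * noise_sd)
      ch <- pmin(ch, LOADCELL_CAPACITY_N)
    }
    list(time = t, channels = ch)
  }

  lc <- sample_channels(config$lc_rate, grf = FALSE)
  fp <- sample_channels(config$fp_rate, grf = TRUE)

  pg <- seq(0, 1, length.out = 2001)  # dense grid for noiseless truth peaks
  truth <- list(
    heel_strike_time = hs, toe_off_time = toe,
    ap_crossing_time = hs + subject$ap_crossing_phase * subject$stance_duration,
    peak_vertical = max(vertical_grf_waveform(pg, subject, w)),
    peak_ap = max(ap_grf_waveform(pg, subject, w)),
    peak_ml = max(ml_grf_waveform(pg, subject, w)))

  list(lc = new_recording("loadcell_recording", subject$subject_id, trial_id,
                          config$lc_rate, lc$time, lc$channels),
       fp = new_recording("forceplate_recording", subject$subject_id, trial_id,
                          config$fp_rate, fp$time, fp$channels),
       truth = truth)
}

#' Generate a full synthetic walking dataset
#'
#' Draws `n_subjects` subject profiles (body weight, stance duration,
#' channel gains, metatarsal timing group) and `trials_per_subject` paired
#' trials per subject. Fully determined by `config` including its seed.
#'
#' @param config A [synthetic_config()].
#' @return A list with `trials` (list of [generate_trial()] triples) and
#'   `subjects` (data.frame: subject_id, body_weight_n, stance_s,
#'   ap_crossing_phase, timing_group).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  rng <- gait_rng(config$seed)
  subjects <- lapply(seq_len(config$n_subjects), function(i)
    rng_draw(rng, function() sample_subject(i, config)))
  trials <- list()
  for (s in subjects) {
    for (k in seq_len(config$trials_per_subject)) {
      tr <- generate_trial(s, config, rng, trial_id = sprintf("T%d", k))
      tr$timing_group <- s$timing_group
      trials[[length(trials) + 1L]] <- tr
    }
  }
  subject_table <- data.frame(
    subject_id = vapply(subjects, `[[`, "", "subject_id"),
    body_weight_n = vapply(subjects, `[[`, 0, "body_weight"),
    stance_s = vapply(subjects, `[[`, 0, "stance_duration"),
    ap_crossing_phase = vapply(subjects, `[[`, 0, "ap_crossing_phase"),
    timing_group = vapply(subjects, `[[`, "", "timing_group"),
    stringsAsFactors = FALSE)
  list(trials = trials, subjects = subject_table, profiles = subjects)
}
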