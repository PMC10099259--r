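#' Lowpass filter specification
#'
#' @param order Filter order (default 4).
#' @param cutoff Cutoff frequency in Hz (default 15).
#' @param mode `"zero_phase"` (forward-backward, no group delay; effective
#'   magnitude response is the squared single-pass response) or `"causal"`.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(order = 4L, cutoff = 15, mode = c("zero_phase", "causal")) {
  mode <- match.arg(mode)
  stopifnot(order >= 1, cutoff > 0)
  structure(list(order = as.integer(order), cutoff = cutoff, mode = mode),
            class = "filter_spec")
}

#' Resample a uniformly sampled force series
#'
#' Cubic-spline interpolation onto the uniform destination grid
#' `k / dst_rate`, `k = 0, 1, ...`, covering the original duration. For
#' content well below the source Nyquist frequency (the signal band here is
#' subsequently limited to 15 Hz) the spline reproduces bandlimited signals
#' to a small fraction of a percent, and the operation is simple and
#' exactly reproducible.
#'
#' @param series Numeric vector sampled at `src_rate` starting at t = 0.
#' @param src_rate,dst_rate Sampling rates in Hz.
#' @return Numeric vector on the destination grid.
#' @export
resample_series <- function(series, src_rate, dst_rate) {
  stopifnot(src_rate > 0, dst_rate > 0)
  n <- length(series)
  if (n < 2) stop("resample_series() needs at least 2 samples", call. = FALSE)
  if (src_rate == dst_rate) return(series)
  dur <- (n - 1) / src_rate
  t_dst <- seq(0, floor(dur * dst_rate + 1e-9)) / dst_rate
  stats::spline(x = seq_len(n) - 1, y = series, xout = t_dst * src_rate,
                method = "fmm")$y
}

# Odd (point-symmetric) reflection padding, as used ahead of zero-phase
# filtering so edge transients decay inside the pad, not the data.
reflect_pad <- function(x, k) {
  n <- length(x)
  k <- min(k, n - 1)
  c(2 * x[1] - x[seq(k + 1, 2)], x, 2 * x[n] - x[seq(n - 1, n - k)])
}

#' Butterworth lowpass filter
#'
#' Applies an `order`-th order Butterworth lowpass. In `zero_phase` mode the
#' filter is run forward and backward over an odd-reflection-padded copy of
#' the series with steady-state initial conditions, so there is no group
#' delay and DC is preserved; the effective amplitude response is the square
#' of the single-pass response (0.5 at the cutoff).
#'
#' @param series Numeric vector.
#' @param sample_rate Sampling rate in Hz.
#' @param spec A [filter_spec()].
#' @return Filtered series, same length.
#' @export
lowpass <- function(series, sample_rate, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  if (spec$cutoff >= sample_rate / 2)
    stop("filter cutoff must be below the Nyquist frequency", call. = FALSE)
  bf <- signal::butter(spec$order, spec$cutoff / (sample_rate / 2),
                       type = "low")
  b <- bf$b; a <- bf$a
  run <- function(x) {
    # steady-state start assuming the pre-history equals the first sample
    k <- length(a) - 1
    as.numeric(signal::filter(b, a, x,
                              init.x = rep(x[1], k),
                              init.y = rep(x[1] * sum(b) / sum(a), k)))
  }
  if (spec$mode == "causal") return(run(series))
  pad <- min(length(series) - 1, 3L * ceiling(sample_rate / spec$cutoff))
  xp <- reflect_pad(series, pad)
  y <- run(xp)
  y <- rev(run(rev(y)))
  y[seq(pad + 1, pad + length(series))]
}

#' Detect force onset
#'
#' Returns the first (1-based) sample index at which the series exceeds
#' `threshold` and stays above it for at least `min_hold` seconds — the
#' debounced operationalization of "the point at which the force occurred",
#' used on the force-plate vertical channel and the load-cell heel channel.
#'
#' @param series Numeric vector of forces (N).
#' @param threshold Onset threshold in N.
#' @param min_hold Minimum time above threshold, seconds.
#' @param sample_rate Sampling rate in Hz.
#' @return Integer index (1-based). Throws a condition of class
#'   `grfnet_no_onset` if no qualifying sample exists.
#' @export
detect_onset <- function(series, threshold = 10, min_hold = 0.025,
                         sample_rate = 200) {
  if (anyNA(series) || any(!is.finite(series)))
    stop("series must be finite", call. = FALSE)
  hold_n <- max(1L, as.integer(ceiling(min_hold * sample_rate)))
  r <- rle(series > threshold)
  ends <- cumsum(r$lengths)
  ok <- which(r$values & r$lengths >= hold_n)
  if (!length(ok))
    stop(errorCondition(
      sprintf("no onset: no run of >= %d samples above %g N", hold_n, threshold),
      class = c("grfnet_no_onset", "error")))
  ends[ok[1]] - r$lengths[ok[1]] + 1L
}

#' Extract the stance interval from a force-plate recording
#'
#' Stance starts at the vertical-force onset and ends at the last sample of
#' the contiguous supra-threshold region.
#'
#' @param fp A `forceplate_recording` or a numeric vertical-force series.
#' @param threshold Threshold in N.
#' @param min_hold Debounce time in seconds (see [detect_onset()]).
#' @param sample_rate Sampling rate in Hz (taken from the recording if one
#'   is supplied).
#' @return Integer vector `c(start, end)`, 1-based inclusive indices.
#' @export
extract_stance <- function(fp, threshold = 10, min_hold = 0.025,
                           sample_rate = 200) {
  if (inherits(fp, "forceplate_recording")) {
    series <- fp$channels[, "vertical"]
    sample_rate <- fp$sample_rate
  } else series <- fp
  start <- detect_onset(series, threshold, min_hold, sample_rate)
  after <- which(series[seq(start, length(series))] <= threshold)
  end <- if (length(after)) start + after[1] - 2L else length(series)
  c(start = start, end = end)
}

#' Synchronize a load-cell / force-plate trial into a stance segment
#'
#' The preprocessing pipeline: resample both instruments to a common
#' `target_rate`, lowpass all channels, detect the heel strike independently
#' in each instrument (force-plate vertical onset; load-cell heel onset),
#' align both heel strikes to index 1, crop to the force-plate stance
#' interval, and append the load-cell sum as the fourth input channel.
#'
#' @param lc A `loadcell_recording`.
#' @param fp A `forceplate_recording` from the same trial.
#' @param spec A [filter_spec()], or `NULL` to skip filtering (for data that
#'   are already filtered).
#' @param fp_threshold,lc_threshold Onset thresholds (N).
#' @param min_hold Onset debounce time (s).
#' @param target_rate Common rate, Hz (default 200).
#' @param timing_group Optional subgroup label carried into the segment.
#' @return An object of class `stance_segment`: list with `inputs` (T x 4
#'   matrix: heel, met1, met5, sum), `targets` (T x 3 matrix: vertical, ap,
#'   ml), `sample_rate`, `subject_id`, `trial_id`, `timing_group`. Index 1
#'   is the synchronized heel strike.
#' @export
synchronize_pair <- function(lc, fp, spec = filter_spec(),
                             fp_threshold = 10, lc_threshold = 10,
                             min_hold = 0.025, target_rate = 200,
                             timing_group = NA_character_) {
  stopifnot(inherits(lc, "loadcell_recording"),
            inherits(fp, "forceplate_recording"))
  prep <- function(ch, rate) {
    m <- apply(ch, 2, resample_series, src_rate = rate,
               dst_rate = target_rate)
    if (!is.null(spec)) m <- apply(m, 2, lowpass, sample_rate = target_rate,
                                   spec = spec)
    m
  }
  lcm <- prep(lc$channels, lc$sample_rate)
  fpm <- prep(fp$channels, fp$sample_rate)
  hs_lc <- tryCatch(
    detect_onset(lcm[, "heel"], lc_threshold, min_hold, target_rate),
    grfnet_no_onset = function(e)
      stop("no heel-strike onset in the load-cell recording", call. = FALSE))
  hs_fp <- tryCatch(
    detect_onset(fpm[, "vertical"], fp_threshold, min_hold, target_rate),
    grfnet_no_onset = function(e)
      stop("no heel-strike onset in the force-plate recording", call. = FALSE))
  st <- extract_stance(fpm[, "vertical"], fp_threshold, min_hold, target_rate)
  len <- st[["end"]] - st[["start"]]
  lc_rows <- hs_lc + 0:len
  if (max(lc_rows) > nrow(lcm))
    stop("load-cell recording too short after heel strike to cover stance",
         call. = FALSE)
  inputs <- lcm[lc_rows, , drop = FALSE]
  inputs <- cbind(inputs, sum = rowSums(inputs))
  targets <- fpm[seq(st[["start"]], st[["end"]]), , drop = FALSE]
  structure(list(subject_id = lc$subject_id, trial_id = lc$trial_id,
                 sample_rate = target_rate, inputs = inputs,
                 targets = targets, timing_group = timing_group),
            class = "stance_segment")
}
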