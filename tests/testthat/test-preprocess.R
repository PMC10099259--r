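test_that("resampling preserves constants, identity, and bandlimited content", {
  x <- rep(5, 101)  # 1 s at 100 Hz inclusive
  y <- resample_series(x, 100, 200)
  expect_length(y, 201)
  expect_equal(y, rep(5, 201))

  z <- rnorm(50)
  expect_identical(resample_series(z, 120, 120), z)
  expect_error(resample_series(1, 100, 200), "2 samples")

  # oracle: the analytic sine evaluated on the destination grid
  t120 <- seq(0, 1, by = 1 / 120)
  s <- sin(2 * pi * 10 * t120)
  s200 <- resample_series(s, 120, 200)
  t200 <- seq(0, (length(s200) - 1)) / 200
  expect_lt(max(abs(s200 - sin(2 * pi * 10 * t200))), 0.02)
})

test_that("resampling down and back reproduces bandlimited signals within 1%", {
  t <- seq(0, 1.5, by = 1 / 100)
  x <- 300 * sin(2 * pi * 3 * t) + 100 * sin(2 * pi * 12 * t + 1)
  back <- resample_series(resample_series(x, 100, 200), 200, 100)
  n <- min(length(back), length(x))
  expect_lt(max(abs(back[1:n] - x[1:n])), 0.01 * max(abs(x)))
})

test_that("zero-phase Butterworth has unit DC gain, half-power cutoff, sharp rolloff", {
  const <- rep(100, 400)
  out <- lowpass(const, 200)
  expect_lt(max(abs(out - 100)), 1e-9)

  amp_ratio <- function(freq, n = 1000, rate = 200) {
    t <- seq(0, n - 1) / rate
    y <- lowpass(sin(2 * pi * freq * t), rate)
    # amplitude fit on the central portion, away from edge transients
    mid <- seq(round(n * 0.25), round(n * 0.75))
    basis <- cbind(sin(2 * pi * freq * t[mid]), cos(2 * pi * freq * t[mid]))
    co <- coef(lm(y[mid] ~ basis - 1))
    sqrt(sum(co^2))
  }
  expect_equal(amp_ratio(15), 0.5, tolerance = 0.01 / 0.5)
  expect_lt(amp_ratio(50), 1e-4)

  expect_error(lowpass(const, 200, filter_spec(cutoff = 120)), "Nyquist")
})

test_that("lowpass is linear and causal mode lags zero-phase mode", {
  t <- seq(0, 2, by = 1 / 200)
  x <- sin(2 * pi * 5 * t) + 0.3 * sin(2 * pi * 20 * t)
  y1 <- lowpass(x, 200)
  y3 <- lowpass(3.5 * x, 200)
  expect_lt(max(abs(y3 - 3.5 * y1)) / max(abs(y3)), 1e-9)

  yc <- lowpass(x, 200, filter_spec(mode = "causal"))
  mid <- 100:300
  lag_err <- function(k) sum((yc[mid + k] - y1[mid])^2)
  errs <- vapply(0:10, lag_err, 0)
  expect_gt(which.min(errs) - 1, 1)  # causal filtering delays the signal
})

test_that("onset detection is debounced, shift-equivariant, and matches truth", {
  x <- c(rep(0, 40), rep(100, 30))
  expect_identical(detect_onset(x, 10, 0, 200), 41L)
  expect_error(detect_onset(rep(3, 50), 10, 0, 200),
               class = "grfnet_no_onset")

  # a blip shorter than min_hold is rejected
  x2 <- c(rep(0, 10), 50, rep(0, 10), rep(100, 30))
  expect_identical(detect_onset(x2, 10, 0.025, 200), 22L)

  for (k in c(1L, 7L, 50L)) {
    expect_identical(detect_onset(c(rep(0, k), x), 10, 0, 200), 41L + k)
  }

  nl <- noiseless_trial()
  for (rec in list(nl$fp, nl$lc)) {
    series <- if (inherits(rec, "forceplate_recording"))
      rec$channels[, "vertical"] else rec$channels[, "heel"]
    idx <- detect_onset(series, 10, 0, rec$sample_rate)
    truth_idx <- nl$truth$heel_strike_time * rec$sample_rate + 1
    expect_lt(abs(idx - truth_idx), 2 + 1e-9)
  }
})

test_that("stance extraction finds the supported interval", {
  pulse <- rep(0, 200)
  pulse[51:151] <- 100
  expect_identical(extract_stance(pulse, 10, 0, 200),
                   c(start = 51L, end = 151L))
  expect_error(extract_stance(rep(0, 100), 10, 0, 200),
               class = "grfnet_no_onset")

  nl <- noiseless_trial()
  st <- extract_stance(nl$fp, 10, 0)
  dur <- (st[["end"]] - st[["start"]]) / nl$fp$sample_rate
  truth_dur <- nl$truth$toe_off_time - nl$truth$heel_strike_time
  expect_lt(abs(dur - truth_dur), 0.02)
})

test_that("synchronization aligns instruments, crops stance, appends the sum", {
  cfg <- synthetic_config(1, seed = 31)
  tr <- generate_trial(default_subject(), cfg, gait_rng(31))
  seg <- synchronize_pair(tr$lc, tr$fp)
  expect_s3_class(seg, "stance_segment")
  expect_identical(seg$sample_rate, 200)
  expect_identical(ncol(seg$inputs), 4L)
  expect_identical(ncol(seg$targets), 3L)
  expect_identical(nrow(seg$inputs), nrow(seg$targets))
  expect_identical(seg$inputs[, 4], rowSums(seg$inputs[, 1:3]))

  # lag invariance: extra swing noise ahead of the load-cell recording must
  # not change the synchronized segment
  rng <- gait_rng(99)
  k <- round(0.25 * tr$lc$sample_rate)
  lc2 <- tr$lc
  lc2$channels <- rbind(
    rng_draw(rng, function()
      matrix(rnorm(k * 3, 0, cfg$swing_noise_sd), k, 3,
             dimnames = list(NULL, colnames(tr$lc$channels)))),
    tr$lc$channels)
  lc2$time <- seq(0, length.out = nrow(lc2$channels)) / lc2$sample_rate
  seg2 <- synchronize_pair(lc2, tr$fp)
  expect_identical(dim(seg2$inputs), dim(seg$inputs))
  expect_lt(max(abs(seg2$inputs - seg$inputs)), 1e-6)
  expect_lt(max(abs(seg2$targets - seg$targets)), 1e-6)
})

test_that("synchronized AP target crosses zero at the generator's crossing time", {
  nl <- noiseless_trial()
  seg <- synchronize_pair(nl$lc, nl$fp)
  tc <- midstance_crossing_time(seg$targets[, "ap"], seg$sample_rate)
  truth_rel <- nl$truth$ap_crossing_time - nl$truth$heel_strike_time
  expect_lt(abs(tc - truth_rel), 0.01)
})

test_that("alignment is idempotent on an already-synchronized pair", {
  nl <- noiseless_trial()
  seg <- synchronize_pair(nl$lc, nl$fp)
  lc2 <- structure(list(subject_id = "S001", trial_id = "T1",
                        sample_rate = 200,
                        time = seq(0, nrow(seg$inputs) - 1) / 200,
                        channels = seg$inputs[, 1:3]),
                   class = "loadcell_recording")
  fp2 <- structure(list(subject_id = "S001", trial_id = "T1",
                        sample_rate = 200,
                        time = seq(0, nrow(seg$targets) - 1) / 200,
                        channels = seg$targets),
                   class = "forceplate_recording")
  seg2 <- synchronize_pair(lc2, fp2, spec = NULL)
  expect_identical(dim(seg2$inputs), dim(seg$inputs))
  expect_lt(max(abs(seg2$inputs - seg$inputs)), 1e-6)
  expect_lt(max(abs(seg2$targets - seg$targets)), 1e-6)
})

test_that("a flat recording raises an instrument-named synchronization error", {
  nl <- noiseless_trial()
  flat <- nl$lc
  flat$channels[] <- 0
  expect_error(synchronize_pair(flat, nl$fp), "load-cell")
  flat_fp <- nl$fp
  flat_fp$channels[] <- 0
  expect_error(synchronize_pair(nl$lc, flat_fp), "force-plate")
})
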