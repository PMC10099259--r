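test_that("vertical GRF waveform is an M-shaped curve scaled by body weight", {
  s <- default_subject(bw = 700)
  expect_identical(vertical_grf_waveform(0, s), 0)
  expect_equal(vertical_grf_waveform(1, s), 0)
  expect_error(vertical_grf_waveform(-0.1, s), "phase")
  expect_error(vertical_grf_waveform(1.5, s), "phase")

  # grid-scan oracle at 1e-3 phase resolution
  p <- seq(0, 1, by = 1e-3)
  v <- vertical_grf_waveform(p, s)
  interior <- 2:(length(p) - 1)
  is_max <- interior[v[interior] > v[interior - 1] & v[interior] > v[interior + 1]]
  is_min <- interior[v[interior] < v[interior - 1] & v[interior] < v[interior + 1]]
  expect_length(is_max, 2)
  expect_length(is_min, 1)
  expect_true(all(v[is_max] >= 1.0 * 700 & v[is_max] <= 1.3 * 700))
  # peak locations per the same grid-scan oracle: the endpoint taper pulls
  # both bump maxima toward mid-stance
  expect_true(p[is_max[1]] > 0.27 && p[is_max[1]] < 0.35)
  expect_true(p[is_max[2]] > 0.65 && p[is_max[2]] < 0.73)
  expect_true(p[is_min] > 0.45 && p[is_min] < 0.55)
  expect_true(v[is_min] > 0.6 * 700 && v[is_min] < 0.9 * 700)
})

test_that("AP GRF waveform brakes then propels, crossing at the subject phase", {
  s <- default_subject(bw = 700, p0 = 0.5)
  expect_equal(ap_grf_waveform(0.5, s), 0)
  zero_amp <- grf_waveform_params(ap_amp = 0)
  expect_equal(ap_grf_waveform(seq(0, 1, 0.05), s, zero_amp), rep(0, 21))

  p <- seq(0, 1, by = 1e-3)
  a <- ap_grf_waveform(p, s)
  expect_true(all(a[p > 0 & p < 0.5] < 0))
  expect_true(all(a[p > 0.5 & p < 1] > 0))
  interior <- 2:(length(p) - 1)
  ext <- interior[sign(a[interior] - a[interior - 1]) !=
                  sign(a[interior + 1] - a[interior])]
  expect_length(ext[p[ext] < 0.5], 1)
  expect_length(ext[p[ext] > 0.5], 1)
  expect_true(all(abs(a[ext]) >= 0.10 * 700 & abs(a[ext]) <= 0.20 * 700))
})

test_that("ML GRF amplitude couples to the metatarsal gain ratio", {
  s <- default_subject(bw = 700)
  expect_equal(ml_grf_waveform(0, s), 0)
  flat <- grf_waveform_params(ml_c0 = 0, ml_c1 = 0)
  expect_equal(ml_grf_waveform(seq(0, 1, 0.1), s, flat), rep(0, 11))
  p <- seq(0, 1, by = 1e-3)
  peak <- max(ml_grf_waveform(p, s))
  expect_true(peak >= 0.03 * 700 && peak <= 0.08 * 700)
  s$channel_gains[["met5"]] <- 0
  expect_error(ml_grf_waveform(0.5, s), "met5")
})

test_that("load-cell channels load heel -> 5th met -> 1st met in order", {
  s <- default_subject()
  p <- seq(0, 1, by = 1e-3)
  lc <- loadcell_waveforms(p, s)
  expect_true(all(lc >= 0))
  zero <- s
  zero$channel_gains[] <- 1e-12
  expect_lt(max(loadcell_waveforms(p, zero)), 1e-6)
  onset <- function(ch) p[which(ch > 0.05 * max(ch))[1]]
  expect_lt(onset(lc[, "heel"]), onset(lc[, "met5"]))
  expect_lt(onset(lc[, "met5"]), onset(lc[, "met1"]))
})

test_that("generate_trial is seeded, padded, and respects noise settings", {
  s <- default_subject()
  cfg <- synthetic_config(1, seed = 2)
  t1 <- generate_trial(s, cfg, gait_rng(42))
  t2 <- generate_trial(s, cfg, gait_rng(42))
  expect_identical(t1, t2)
  expect_error(generate_trial(s, cfg), "gait_rng")

  nl <- noiseless_trial()
  swing_lc <- nl$lc$time < nl$truth$heel_strike_time |
    nl$lc$time > nl$truth$toe_off_time
  expect_true(all(nl$lc$channels[swing_lc, ] == 0))
  swing_fp <- nl$fp$time < nl$truth$heel_strike_time |
    nl$fp$time > nl$truth$toe_off_time
  expect_true(all(nl$fp$channels[swing_fp, ] == 0))
  expect_true(all(nl$fp$channels[, "vertical"] >= 0))

  # swing padding on both sides
  expect_gte(nl$truth$heel_strike_time, 0.3)
  expect_gte(max(nl$lc$time) - nl$truth$toe_off_time, 0.3)

  peak <- max(t1$fp$channels[, "vertical"])
  expect_true(peak >= 1.0 * s$body_weight && peak <= 1.3 * s$body_weight)
})

test_that("noiseless AP series has exactly one sign change, at the known crossing", {
  nl <- noiseless_trial()
  ap <- nl$fp$channels[, "ap"]
  sgn <- sign(ap[ap != 0])
  flips <- which(diff(sgn) != 0)
  expect_length(flips, 1)
  nz <- which(ap != 0)
  t_flip <- nl$fp$time[nz[flips]]
  expect_lt(abs(t_flip - nl$truth$ap_crossing_time), 1 / nl$fp$sample_rate + 1e-9)
})

test_that("generate_dataset is reproducible and draws plausible subjects", {
  cfg <- synthetic_config(12, seed = 7)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1, d2)
  expect_length(d1$trials, 24)
  expect_identical(nrow(d1$subjects), 12L)
  expect_true(all(d1$subjects$timing_group %in% c("similar", "different")))

  big <- generate_dataset(synthetic_config(1000, trials_per_subject = 1L,
                                           seed = 13))
  m <- mean(big$subjects$stance_s)
  expect_true(m >= 0.57 && m <= 0.61)
  expect_true(all(big$subjects$stance_s >= 0.4 & big$subjects$stance_s <= 0.9))
  expect_true(all(big$subjects$body_weight_n >= 400 &
                  big$subjects$body_weight_n <= 1000))
})

test_that("load-cell sum correlates with vertical GRF near the instrumented-shoe value", {
  ds <- generate_dataset(synthetic_config(25, seed = 21))  # 50 trials
  sums <- verts <- NULL
  for (tr in ds$trials) {
    fp_on_lc <- apply(tr$fp$channels, 2, resample_series,
                      src_rate = tr$fp$sample_rate,
                      dst_rate = tr$lc$sample_rate)
    idx <- which(tr$lc$time >= tr$truth$heel_strike_time &
                 tr$lc$time <= tr$truth$toe_off_time)
    idx <- idx[idx <= nrow(fp_on_lc)]
    sums <- c(sums, rowSums(tr$lc$channels[idx, ]))
    verts <- c(verts, fp_on_lc[idx, "vertical"])
  }
  r <- cor(sums, verts)
  expect_true(r >= 0.80 && r <= 0.90)
})
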