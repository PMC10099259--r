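# Independent direct-formula oracles, sharing no code with the package.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - sum(x) / n) * (y - sum(y) / n)) / (n - 1)
  sx <- sqrt(sum((x - sum(x) / n)^2) / (n - 1))
  sy <- sqrt(sum((y - sum(y) / n)^2) / (n - 1))
  sxy / (sx * sy)
}
oracle_rmse <- function(x, y) sqrt(sum((x - y)^2) / length(x))

test_that("pooled correlation and RMSE match direct-formula oracles", {
  set.seed(101)
  for (case in 1:50) {
    n <- sample(10:1000, 1)
    pred <- matrix(rnorm(n * 3, sd = 50), n, 3)
    meas <- pred + matrix(rnorm(n * 3, sd = 20), n, 3)
    r <- pearson_per_axis(pred, meas)
    e <- rmse_per_axis(pred, meas)
    for (j in 1:3) {
      expect_equal(r[[j]], oracle_pearson(pred[, j], meas[, j]),
                   tolerance = 1e-12)
      expect_equal(e[[j]], oracle_rmse(pred[, j], meas[, j]),
                   tolerance = 1e-12)
    }
  }
})

test_that("correlation and RMSE behave under shifts and perfect agreement", {
  m <- matrix(abs(rnorm(60, 100, 30)), 20, 3)
  expect_equal(unname(pearson_per_axis(m, m)), rep(1, 3))
  expect_equal(unname(rmse_per_axis(m, m)), rep(0, 3))
  expect_equal(unname(pearson_per_axis(m + 10, m)), rep(1, 3))
  expect_equal(unname(rmse_per_axis(m + 10, m)), rep(10, 3))
  expect_error(pearson_per_axis(matrix(1, 5, 3), m[1:5, ]), "zero variance")
  expect_error(rmse_per_axis(m[1:5, ], m), "mismatch|pair")
})

test_that("pooling concatenates segments rather than averaging per trial", {
  set.seed(5)
  a <- matrix(rnorm(30), 10, 3); b <- matrix(rnorm(60), 20, 3)
  am <- a + rnorm(30, sd = 0.2); bm <- b + rnorm(60, sd = 0.2)
  pooled <- pearson_per_axis(list(a, b), list(am, bm))
  direct <- sapply(1:3, function(j)
    oracle_pearson(c(a[, j], b[, j]), c(am[, j], bm[, j])))
  expect_equal(unname(pooled), direct, tolerance = 1e-12)
})

test_that("mid-stance crossing interpolates between bracketing samples", {
  expect_equal(midstance_crossing_time(c(-1, -1, 1, 1), 200), 0.0075)
  expect_error(midstance_crossing_time(c(1, 2, 3), 200),
               class = "grfnet_no_crossing")
  expect_error(midstance_crossing_time(c(-3, -2, -1), 200),
               class = "grfnet_no_crossing")
  # spurious early flip is skipped: search starts at the global minimum
  ap <- c(-0.1, 0.2, -0.5, -2, -1, 0.5, 1)
  expect_equal(midstance_crossing_time(ap, 200), (4 + 2 / 3) / 200)
  # exact zero at the transition
  expect_equal(midstance_crossing_time(c(-2, -1, 0, 1), 100), 0.02)

  s <- default_subject(stance = 0.6, p0 = 0.5)
  nl <- noiseless_trial(subject = s)
  seg <- synchronize_pair(nl$lc, nl$fp)
  expect_equal(midstance_crossing_time(seg$targets[, "ap"], 200), 0.300,
               tolerance = 0.005 / 0.3)
})

test_that("timing error is signed, classified, and antisymmetric", {
  ap <- c(rep(-5, 50), seq(-5, 5, length.out = 21), rep(5, 50))
  same <- midstance_timing_error(ap, ap, 200)
  expect_equal(same$signed, 0)
  expect_identical(same$class, "equal")

  shifted <- c(rep(-5, 3), ap)  # measured crossing 3 samples later
  err <- midstance_timing_error(ap, shifted, 200)
  expect_equal(err$signed, -0.015)
  expect_identical(err$class, "earlier")

  rev_err <- midstance_timing_error(shifted, ap, 200)
  expect_equal(rev_err$signed, -err$signed)
  expect_identical(rev_err$class, "later")
})

test_that("timing percentages follow the stance-fraction identity", {
  expect_equal(timing_error_percent(0.059, 0.59, 0.6),
               c(pct_of_cycle = 6, pct_of_stance = 10))
  expect_equal(timing_error_percent(0, 0.59, 0.6),
               c(pct_of_cycle = 0, pct_of_stance = 0))
  expect_equal(timing_error_percent(0.0550, 0.59, 0.6)[["pct_of_stance"]],
               9.322034, tolerance = 1e-6)
  expect_error(timing_error_percent(0.05, 0, 0.6), "positive")
  for (e in c(0.01, 0.06)) for (f in c(0.4, 0.6)) {
    p <- timing_error_percent(e, 0.59, f)
    expect_equal(p[["pct_of_cycle"]], p[["pct_of_stance"]] * f)
  }
})

test_that("peak extraction takes the propulsive AP maximum", {
  m <- cbind(c(0, 700, 650, 0), c(-50, -10, 40, 20), c(1, 30, 25, 2))
  expect_equal(peak_values(m), c(vertical = 700, ap = 40, ml = 30))
  m_neg <- m; m_neg[, 2] <- -abs(m_neg[, 2])
  expect_error(peak_values(m_neg), "propulsive")

  nl <- noiseless_trial()
  seg <- synchronize_pair(nl$lc, nl$fp)
  pk <- peak_values(seg)
  expect_lt(abs(pk[["vertical"]] - nl$truth$peak_vertical), 1)
  expect_lt(abs(pk[["ap"]] - nl$truth$peak_ap), 1)
  expect_lt(abs(pk[["ml"]] - nl$truth$peak_ml), 1)
})

test_that("Bland-Altman matches the direct formulas, including the 5-pair example", {
  ba <- bland_altman(c(12, 19, 33, 38, 55), c(10, 20, 30, 40, 50))
  expect_equal(ba$bias, 1.4)
  expect_equal(ba$sd_diff, 2.880972, tolerance = 1e-6)
  expect_equal(ba$lloa, 1.4 - 1.96 * ba$sd_diff)
  expect_equal(ba$uloa, 1.4 + 1.96 * ba$sd_diff)
  expect_equal(ba$lloa, -4.246706, tolerance = 1e-6)
  expect_equal(ba$uloa, 7.046706, tolerance = 1e-6)

  set.seed(77)
  for (case in 1:150) {
    n <- sample(2:1000, 1)
    est <- rnorm(n, 100, 25)
    mea <- est + rnorm(n, 2, 10)
    ba <- bland_altman(est, mea)
    d <- est - mea
    bias <- sum(d) / n
    sdd <- sqrt(sum((d - bias)^2) / (n - 1))
    tq <- qt(0.975, n - 1)
    expect_equal(ba$bias, bias, tolerance = 1e-12)
    expect_equal(ba$sd_diff, sdd, tolerance = 1e-12)
    expect_equal(ba$lloa, bias - 1.96 * sdd, tolerance = 1e-12)
    expect_equal(ba$uloa, bias + 1.96 * sdd, tolerance = 1e-12)
    expect_equal(ba$bias_ci, bias + c(-1, 1) * tq * sdd / sqrt(n),
                 tolerance = 1e-12)
    expect_equal(ba$lloa_ci,
                 bias - 1.96 * sdd + c(-1, 1) * tq * sdd * sqrt(3 / n),
                 tolerance = 1e-12)
    expect_equal(ba$uloa_ci,
                 bias + 1.96 * sdd + c(-1, 1) * tq * sdd * sqrt(3 / n),
                 tolerance = 1e-12)
    if (n >= 3 && sdd > 0) {
      expect_gt(ba$bias_ci[1], ba$lloa)
      expect_lt(ba$bias_ci[2], ba$uloa)
    }
  }
})

test_that("Bland-Altman is scale-equivariant and degenerates cleanly", {
  ba0 <- bland_altman(c(5, 5, 5, 5, 5), c(5, 5, 5, 5, 5))
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$sd_diff, 0)
  expect_equal(c(ba0$lloa, ba0$uloa), c(0, 0))
  expect_error(bland_altman(1, 1), "at least 2")

  est <- c(12, 19, 33, 38, 55); mea <- c(10, 20, 30, 40, 50)
  b1 <- bland_altman(est, mea)
  b2 <- bland_altman(2 * est, 2 * mea)
  for (f in c("bias", "sd_diff", "lloa", "uloa", "bias_ci", "lloa_ci",
              "uloa_ci"))
    expect_equal(b2[[f]], 2 * b1[[f]])
})

test_that("test-set evaluation scores a perfect predictor perfectly", {
  segs <- tiny_segments(5, seed = 17, noiseless = FALSE)
  oracle_model <- function(seg) seg$targets
  rp <- evaluate_testset(oracle_model, segs)
  expect_equal(unname(rp$pearson_r), rep(1, 3))
  expect_equal(unname(rp$rmse), rep(0, 3))
  expect_equal(rp$timing$mean_abs_error, 0)
  expect_identical(rp$timing$n_equal, length(segs))
  expect_identical(rp$n_trials, length(segs))
  expect_error(evaluate_testset(oracle_model, list()), "empty")

  groups <- vapply(segs, `[[`, "", "timing_group")
  counts <- vapply(rp$subgroups, `[[`, 0L, "n_trials")
  expect_identical(sum(counts), length(segs))
  for (g in names(rp$subgroups))
    expect_identical(rp$subgroups[[g]]$n_trials, sum(groups == g))
})
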