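AXES <- c("vertical", "ap", "ml")

pool_axes <- function(pred, meas) {
  as_list <- function(x) if (is.matrix(x)) list(x) else x
  pred <- as_list(pred); meas <- as_list(meas)
  if (length(pred) != length(meas))
    stop("pred and meas must pair up", call. = FALSE)
  for (i in seq_along(pred))
    if (!identical(dim(pred[[i]]), dim(meas[[i]])))
      stop("length mismatch between paired segments", call. = FALSE)
  list(pred = do.call(rbind, pred), meas = do.call(rbind, meas))
}

#' Per-axis Pearson correlation between predicted and measured GRF
#'
#' Samples are concatenated (pooled) across all supplied segments per axis
#' and one coefficient is computed per axis.
#'
#' @param pred,meas T x 3 matrices (vertical, ap, ml) or lists of them,
#'   paired and of equal lengths.
#' @return Named numeric vector of 3 correlations.
#' @export
pearson_per_axis <- function(pred, meas) {
  p <- pool_axes(pred, meas)
  r <- vapply(1:3, function(j) {
    if (stats::sd(p$pred[, j]) == 0 || stats::sd(p$meas[, j]) == 0)
      stop("undefined correlation: zero variance on axis ", AXES[j],
           call. = FALSE)
    stats::cor(p$pred[, j], p$meas[, j])
  }, 0)
  stats::setNames(r, AXES)
}

#' Per-axis root mean square error (N)
#'
#' Pooled over all concatenated samples per axis.
#'
#' @inheritParams pearson_per_axis
#' @return Named numeric vector of 3 RMSEs in newtons.
#' @export
rmse_per_axis <- function(pred, meas) {
  p <- pool_axes(pred, meas)
  stats::setNames(sqrt(colMeans((p$pred - p$meas)^2)), AXES)
}

#' Mid-stance crossing time of the AP GRF
#'
#' The instant the AP force changes sign from negative (braking) to positive
#' (propulsion): the first negative-to-positive transition at or after the
#' series' global minimum, located with linear sub-sample interpolation.
#' Sample i sits at time (i - 1) / sample_rate.
#'
#' @param ap Numeric AP force series (N).
#' @param sample_rate Sampling rate (Hz).
#' @return Crossing time in seconds. Throws a `grfnet_no_crossing` condition
#'   if no braking-to-propulsion transition exists.
#' @export
midstance_crossing_time <- function(ap, sample_rate) {
  no_cross <- function(msg)
    stop(errorCondition(msg, class = c("grfnet_no_crossing", "error")))
  imin <- which.min(ap)
  if (ap[imin] >= 0) no_cross("no crossing: AP series never negative")
  rest <- seq(imin, length(ap))
  jpos <- rest[which(ap[rest] > 0)[1]]
  if (is.na(jpos)) no_cross("no crossing: AP series never positive after minimum")
  before <- seq(imin, jpos - 1)
  ineg <- before[max(which(ap[before] < 0))]
  if (jpos == ineg + 1) {
    frac <- -ap[ineg] / (ap[jpos] - ap[ineg])
    (ineg - 1 + frac) / sample_rate
  } else {
    # exact zeros between the last negative and first positive sample:
    # the crossing is at the first zero
    (ineg) / sample_rate
  }
}

#' Mid-stance timing error between predicted and measured AP GRF
#'
#' @param pred_ap,meas_ap AP force series (N), same rate.
#' @param sample_rate Sampling rate (Hz).
#' @return List with `signed` (predicted crossing minus measured crossing,
#'   s), `abs`, and `class` in `"earlier"` / `"later"` / `"equal"` (equal =
#'   within half a sample period).
#' @export
midstance_timing_error <- function(pred_ap, meas_ap, sample_rate) {
  tp <- midstance_crossing_time(pred_ap, sample_rate)
  tm <- midstance_crossing_time(meas_ap, sample_rate)
  signed <- tp - tm
  cls <- if (abs(signed) < 0.5 / sample_rate) "equal"
         else if (signed < 0) "earlier" else "later"
  list(signed = signed, abs = abs(signed), class = cls)
}

#' Express a timing error as a percentage of the gait cycle and of stance
#'
#' With stance occupying `stance_fraction` of the gait cycle, a mean
#' absolute timing error `e` is `100 * e / mean_stance` percent of stance
#' and `100 * e / (mean_stance / stance_fraction)` percent of the cycle.
#'
#' @param mean_abs_error Mean absolute timing error (s).
#' @param mean_stance Mean stance duration (s), > 0.
#' @param stance_fraction Stance share of the gait cycle, in (0, 1\].
#' @return Named vector `c(pct_of_cycle, pct_of_stance)`.
#' @export
timing_error_percent <- function(mean_abs_error, mean_stance,
                                 stance_fraction = 0.6) {
  if (mean_stance <= 0) stop("mean_stance must be positive", call. = FALSE)
  stopifnot(stance_fraction > 0, stance_fraction <= 1)
  c(pct_of_cycle = 100 * mean_abs_error / (mean_stance / stance_fraction),
    pct_of_stance = 100 * mean_abs_error / mean_stance)
}

#' Peak (maximum) force per axis
#'
#' Per-axis maxima of a stance-phase GRF trace; for the AP axis the peak is
#' the propulsive (positive-phase) maximum.
#'
#' @param x A `stance_segment` (its targets are used) or a T x 3 matrix
#'   (vertical, ap, ml).
#' @return Named vector `c(vertical, ap, ml)` of peak forces (N).
#' @export
peak_values <- function(x) {
  m <- if (inherits(x, "stance_segment")) x$targets else x
  if (!is.matrix(m) || ncol(m) != 3 || nrow(m) == 0)
    stop("expected a non-empty T x 3 GRF matrix", call. = FALSE)
  ap <- m[, 2]
  if (all(ap <= 0))
    stop("no propulsive peak: AP series has no positive phase", call. = FALSE)
  c(vertical = max(m[, 1]), ap = max(ap[ap > 0]), ml = max(m[, 3]))
}

#' Bland-Altman agreement analysis
#'
#' Differences are taken as `estimated - measured`. The limits of agreement
#' are `bias +/- 1.96 * sd`; the bias confidence interval uses the exact t
#' standard error `sd / sqrt(n)`, and each limit's confidence interval uses
#' the classical approximation `sd * sqrt(3 / n)`, both with a
#' `t(n - 1, 0.975)` multiplier.
#'
#' @param estimated,measured Paired numeric vectors, n >= 2.
#' @return An object of class `bland_altman`: `n`, `bias`, `sd_diff`,
#'   `lloa`, `uloa`, `bias_ci`, `lloa_ci`, `uloa_ci`, and `points` (a
#'   data.frame of per-pair means and differences for plotting).
#' @export
bland_altman <- function(estimated, measured) {
  if (length(estimated) != length(measured))
    stop("estimated and measured must pair up", call. = FALSE)
  n <- length(estimated)
  if (n < 2) stop("Bland-Altman needs at least 2 pairs", call. = FALSE)
  d <- estimated - measured
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  tq <- stats::qt(0.975, n - 1)
  lloa <- bias - 1.96 * sd_diff
  uloa <- bias + 1.96 * sd_diff
  half_bias <- tq * sd_diff / sqrt(n)
  half_loa <- tq * sd_diff * sqrt(3 / n)
  structure(list(n = n, bias = bias, sd_diff = sd_diff,
                 lloa = lloa, uloa = uloa,
                 bias_ci = c(bias - half_bias, bias + half_bias),
                 lloa_ci = c(lloa - half_loa, lloa + half_loa),
                 uloa_ci = c(uloa - half_loa, uloa + half_loa),
                 points = data.frame(mean = (estimated + measured) / 2,
                                     diff = d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.2f N [%.2f, %.2f]\n",
              x$n, x$bias, x$bias_ci[1], x$bias_ci[2]))
  cat(sprintf("  LoA [%.2f, %.2f] N; LoA CIs [%.2f, %.2f] / [%.2f, %.2f]\n",
              x$lloa, x$uloa, x$lloa_ci[1], x$lloa_ci[2],
              x$uloa_ci[1], x$uloa_ci[2]))
  invisible(x)
}

eval_metrics <- function(preds, segs, stance_fraction, sample_rate) {
  meas <- lapply(segs, `[[`, "targets")
  r <- pearson_per_axis(preds, meas)
  rmse <- rmse_per_axis(preds, meas)
  timing <- list(signed = numeric(0), classes = character(0), excluded = 0L)
  for (i in seq_along(segs)) {
    te <- tryCatch(
      midstance_timing_error(preds[[i]][, 2], meas[[i]][, 2], sample_rate),
      grfnet_no_crossing = function(e) NULL)
    if (is.null(te)) timing$excluded <- timing$excluded + 1L
    else {
      timing$signed <- c(timing$signed, te$signed)
      timing$classes <- c(timing$classes, te$class)
    }
  }
  mean_stance <- mean(vapply(segs, function(s) nrow(s$targets), 0)) /
    sample_rate
  mae <- if (length(timing$signed)) mean(abs(timing$signed)) else NA_real_
  pct <- if (is.na(mae)) c(pct_of_cycle = NA_real_, pct_of_stance = NA_real_)
         else timing_error_percent(mae, mean_stance, stance_fraction)
  timing_report <- list(
    signed_errors = timing$signed, mean_abs_error = mae,
    pct_of_cycle = unname(pct["pct_of_cycle"]),
    pct_of_stance = unname(pct["pct_of_stance"]),
    mean_stance = mean_stance, stance_fraction = stance_fraction,
    n_earlier = sum(timing$classes == "earlier"),
    n_later = sum(timing$classes == "later"),
    n_equal = sum(timing$classes == "equal"),
    n_excluded = timing$excluded)
  peaks_pred <- t(vapply(preds, peak_values, numeric(3)))
  peaks_meas <- t(vapply(meas, peak_values, numeric(3)))
  ba <- lapply(1:3, function(j) bland_altman(peaks_pred[, j], peaks_meas[, j]))
  names(ba) <- AXES
  list(n_trials = length(segs), pearson_r = r, rmse = rmse,
       timing = timing_report, bland_altman = ba)
}

#' Evaluate a fitted estimator on a held-out test set
#'
#' Runs the estimator on every test segment and assembles the validation
#' suite: pooled per-axis Pearson r and RMSE, the mid-stance timing report
#' (braking-to-propulsion AP sign change), Bland-Altman agreement on the
#' three peak forces, and, when `timing_group` labels are present, the same
#' metrics per metatarsal-timing subgroup.
#'
#' @param model A fitted [grfnet()] model, or a function mapping a
#'   `stance_segment` to a T x 3 prediction matrix.
#' @param test Non-empty list of `stance_segment` objects.
#' @param stance_fraction Stance share of the gait cycle used for the
#'   cycle-percentage timing error (default 0.6).
#' @return An object of class `eval_report`.
#' @export
evaluate_testset <- function(model, test, stance_fraction = 0.6) {
  test <- segment_list(test)
  if (!length(test)) stop("test set is empty", call. = FALSE)
  predictor <- if (is.function(model)) model else
    function(seg) predict(model, seg)
  preds <- lapply(test, predictor)
  rate <- test[[1]]$sample_rate
  report <- eval_metrics(preds, test, stance_fraction, rate)
  groups <- vapply(test, function(s)
    if (is.null(s$timing_group)) NA_character_ else s$timing_group, "")
  if (any(!is.na(groups))) {
    report$subgroups <- lapply(
      stats::setNames(nm = sort(unique(groups[!is.na(groups)]))),
      function(g) {
        idx <- which(groups == g)
        eval_metrics(preds[idx], test[idx], stance_fraction, rate)
      })
  }
  structure(report, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("GRF estimation on %d test stance segments\n", x$n_trials))
  tab <- data.frame(axis = AXES, r = round(x$pearson_r, 2),
                    rmse_n = round(x$rmse, 2), row.names = NULL)
  print(tab, row.names = FALSE)
  tm <- x$timing
  if (!is.na(tm$mean_abs_error))
    cat(sprintf(
      "mid-stance timing error: %.3f s (%.2f%% of cycle, %.2f%% of stance); %d earlier / %d later / %d equal\n",
      tm$mean_abs_error, tm$pct_of_cycle, tm$pct_of_stance,
      tm$n_earlier, tm$n_later, tm$n_equal))
  for (ax in AXES) {
    b <- x$bland_altman[[ax]]
    cat(sprintf("peak %-8s bias %7.2f N, LoA [%.2f, %.2f]\n",
                paste0(ax, ":"), b$bias, b$lloa, b$uloa))
  }
  if (!is.null(x$subgroups)) {
    for (g in names(x$subgroups)) {
      s <- x$subgroups[[g]]
      cat(sprintf("subgroup %s (n = %d): r = %s; RMSE = %s N\n", g,
                  s$n_trials, paste(round(s$pearson_r, 2), collapse = "/"),
                  paste(round(s$rmse, 2), collapse = "/")))
    }
  }
  invisible(x)
}
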