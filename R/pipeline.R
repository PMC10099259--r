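fmt_num <- function(x) sprintf("%.9f", x)

write_channels_csv <- function(time, channels, cols, path) {
  df <- data.frame(fmt_num(time),
                   fmt_num(channels[, 1]), fmt_num(channels[, 2]),
                   fmt_num(channels[, 3]))
  names(df) <- cols
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_channels_csv <- function(path, cols, channel_names) {
  df <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("CSV ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  t <- df[[cols[1]]]
  if (length(t) < 2) stop("recording too short: ", path, call. = FALSE)
  dt <- diff(t)
  if (any(dt <= 0))
    stop("non-monotone time column in ", path, call. = FALSE)
  if (max(abs(dt - stats::median(dt))) > 0.01 * stats::median(dt))
    stop("non-uniform sampling (> 1% jitter) in ", path, call. = FALSE)
  ch <- as.matrix(df[cols[-1]])
  colnames(ch) <- channel_names
  rate <- 1 / stats::median(dt)
  # snap to the nominal integer rate when within the jitter tolerance
  if (abs(rate - round(rate)) < 0.01 * rate) rate <- round(rate)
  list(time = t, channels = ch, sample_rate = rate)
}

LC_COLS <- c("time_s", "heel_n", "met1_n", "met5_n")
FP_COLS <- c("time_s", "fz_n", "fap_n", "fml_n")

#' Read and write recording CSV files
#'
#' Load-cell CSVs have columns `time_s,heel_n,met1_n,met5_n`; force-plate
#' CSVs `time_s,fz_n,fap_n,fml_n`. Values are newtons, written at nanonewton
#' precision so a write/read round trip is lossless for practical purposes.
#' The sampling rate is recovered from the time column, which must be
#' uniform to within 1% jitter.
#'
#' @param rec A `loadcell_recording` / `forceplate_recording`.
#' @param path CSV file path.
#' @param subject_id,trial_id Identifiers attached on read.
#' @return The readers return the corresponding recording object; the
#'   writers return `path` invisibly.
#' @export
write_loadcell_csv <- function(rec, path) {
  stopifnot(inherits(rec, "loadcell_recording"))
  write_channels_csv(rec$time, rec$channels, LC_COLS, path)
}

#' @rdname write_loadcell_csv
#' @export
read_loadcell_csv <- function(path, subject_id = NA_character_,
                              trial_id = NA_character_) {
  p <- read_channels_csv(path, LC_COLS, c("heel", "met1", "met5"))
  new_recording("loadcell_recording", subject_id, trial_id,
                p$sample_rate, p$time, p$channels)
}

#' @rdname write_loadcell_csv
#' @export
write_forceplate_csv <- function(rec, path) {
  stopifnot(inherits(rec, "forceplate_recording"))
  write_channels_csv(rec$time, rec$channels, FP_COLS, path)
}

#' @rdname write_loadcell_csv
#' @export
read_forceplate_csv <- function(path, subject_id = NA_character_,
                                trial_id = NA_character_) {
  p <- read_channels_csv(path, FP_COLS, c("vertical", "ap", "ml"))
  new_recording("forceplate_recording", subject_id, trial_id,
                p$sample_rate, p$time, p$channels)
}

#' Write a generated dataset to a directory of CSV files
#'
#' One load-cell CSV, one force-plate CSV and one ground-truth CSV per
#' trial, plus a subject table.
#'
#' @param dataset A [generate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset_csv <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tr in dataset$trials) {
    stem <- file.path(dir, paste0(tr$lc$subject_id, "_", tr$lc$trial_id))
    write_loadcell_csv(tr$lc, paste0(stem, "_loadcell.csv"))
    write_forceplate_csv(tr$fp, paste0(stem, "_forceplate.csv"))
    tdf <- data.frame(lapply(tr$truth, fmt_num))
    utils::write.table(tdf, paste0(stem, "_truth.csv"), sep = ",",
                       quote = FALSE, row.names = FALSE)
  }
  utils::write.table(dataset$subjects, file.path(dir, "subjects.csv"),
                     sep = ",", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Subject-wise train/validation/test split
#'
#' Seeded shuffle of the subject identifiers followed by assignment of the
#' requested counts. Splits are subject-disjoint by construction, matching
#' the validation principle that data from one subject never straddles
#' splits.
#'
#' @param subject_ids Character vector of unique subject identifiers.
#' @param counts Named or positional integer vector
#'   `c(train, validation, test)`; default 37/12/11.
#' @param seed Integer seed.
#' @return List with `train`, `validation`, `test` id vectors.
#' @export
split_subjects <- function(subject_ids, counts = c(37L, 12L, 11L), seed = 1L) {
  subject_ids <- unique(as.character(subject_ids))
  counts <- as.integer(counts)
  stopifnot(length(counts) == 3, all(counts >= 0))
  if (sum(counts) > length(subject_ids))
    stop("split counts (", sum(counts), ") exceed available subjects (",
         length(subject_ids), ")", call. = FALSE)
  rng <- gait_rng(seed)
  shuffled <- rng_draw(rng, function() sample(subject_ids))
  list(train = shuffled[seq_len(counts[1])],
       validation = shuffled[counts[1] + seq_len(counts[2])],
       test = shuffled[counts[1] + counts[2] + seq_len(counts[3])])
}

#' Experiment configuration
#'
#' Bundles every stage's configuration so a run is fully reproducible from
#' its archived configuration.
#'
#' @param synthetic A [synthetic_config()] (or `NULL` with `data_dir` to
#'   load existing CSV recordings).
#' @param data_dir Directory of CSV recordings, used when `synthetic` is
#'   `NULL`; must contain the files written by [write_dataset_csv()].
#' @param filter A [filter_spec()].
#' @param model A [grf_model_config()].
#' @param split_counts Train/validation/test subject counts.
#' @param split_seed Seed for the subject shuffle.
#' @param fp_threshold,lc_threshold,min_hold Onset-detection settings.
#' @param stance_fraction Stance share of the gait cycle (timing report).
#' @return An object of class `run_config`.
#' @export
run_config <- function(synthetic = synthetic_config(60L),
                       data_dir = NULL,
                       filter = filter_spec(),
                       model = grf_model_config(),
                       split_counts = c(37L, 12L, 11L),
                       split_seed = 1L,
                       fp_threshold = 10, lc_threshold = 10,
                       min_hold = 0.025, stance_fraction = 0.6) {
  if (is.null(synthetic) && is.null(data_dir))
    stop("either a synthetic config or a data directory is required",
         call. = FALSE)
  structure(list(synthetic = synthetic, data_dir = data_dir, filter = filter,
                 model = model, split_counts = as.integer(split_counts),
                 split_seed = as.integer(split_seed),
                 fp_threshold = fp_threshold, lc_threshold = lc_threshold,
                 min_hold = min_hold, stance_fraction = stance_fraction),
            class = "run_config")
}

config_to_list <- function(x) {
  strip <- function(v) if (is.list(v)) lapply(unclass(v), strip) else v
  strip(x)
}

#' Restore a run configuration from its archived JSON form
#'
#' @param path Path to a `config.json` written by [run_experiment()], or a
#'   YAML file with the same structure.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  syn <- if (!is.null(raw$synthetic))
    do.call(synthetic_config,
            c(raw$synthetic[setdiff(names(raw$synthetic), "waveform")],
              list(waveform = do.call(grf_waveform_params,
                                      as.list(raw$synthetic$waveform)))))
  run_config(synthetic = syn, data_dir = raw$data_dir,
             filter = do.call(filter_spec, as.list(raw$filter)),
             model = do.call(grf_model_config, as.list(raw$model)),
             split_counts = raw$split_counts, split_seed = raw$split_seed,
             fp_threshold = raw$fp_threshold,
             lc_threshold = raw$lc_threshold,
             min_hold = raw$min_hold, stance_fraction = raw$stance_fraction)
}

ba_to_list <- function(b)
  list(n = b$n, bias = b$bias, sd_diff = b$sd_diff, lloa = b$lloa,
       uloa = b$uloa, bias_ci = b$bias_ci, lloa_ci = b$lloa_ci,
       uloa_ci = b$uloa_ci)

report_to_list <- function(report) {
  core <- function(x)
    list(n_trials = x$n_trials, pearson_r = as.list(x$pearson_r),
         rmse = as.list(x$rmse), timing = x$timing,
         bland_altman = lapply(x$bland_altman, ba_to_list))
  out <- core(report)
  if (!is.null(report$subgroups))
    out$subgroups <- lapply(report$subgroups, core)
  out
}

#' Write an evaluation report to disk
#'
#' Emits `report.json` (full precision), `report_summary.csv` (one row per
#' axis and statistic, rounded to 2 decimals for presentation) and the
#' Bland-Altman point sets as `bland_altman_<axis>.csv`.
#'
#' @param report An `eval_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report_to_list(report),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  summary_df <- data.frame(
    axis = rep(AXES, 2),
    statistic = rep(c("pearson_r", "rmse_n"), each = 3),
    value = round(c(report$pearson_r, report$rmse), 2))
  summary_df <- rbind(summary_df, data.frame(
    axis = "ap", statistic = c("timing_mae_s", "timing_pct_cycle",
                               "timing_pct_stance"),
    value = round(c(report$timing$mean_abs_error, report$timing$pct_of_cycle,
                    report$timing$pct_of_stance), 2)))
  utils::write.table(summary_df, file.path(dir, "report_summary.csv"),
                     sep = ",", quote = FALSE, row.names = FALSE)
  for (ax in AXES) {
    pts <- report$bland_altman[[ax]]$points
    names(pts) <- c("mean_n", "diff_n")
    utils::write.table(pts, file.path(dir, sprintf("bland_altman_%s.csv", ax)),
                       sep = ",", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

load_dataset_csv <- function(dir) {
  subj <- utils::read.csv(file.path(dir, "subjects.csv"))
  lcs <- list.files(dir, pattern = "_loadcell\\.csv$", full.names = TRUE)
  trials <- lapply(lcs, function(f) {
    stem <- sub("_loadcell\\.csv$", "", f)
    ids <- strsplit(basename(stem), "_")[[1]]
    tr <- list(lc = read_loadcell_csv(f, ids[1], ids[2]),
               fp = read_forceplate_csv(paste0(stem, "_forceplate.csv"),
                                        ids[1], ids[2]))
    tr$timing_group <-
      subj$timing_group[match(ids[1], subj$subject_id)]
    tr
  })
  list(trials = trials, subjects = subj)
}

#' Run the full estimation experiment
#'
#' Generate (or load) paired recordings, preprocess every trial into
#' synchronized stance segments, split by subject, train the estimator, and
#' evaluate it on the held-out test subjects. All artifacts — the report
#' (JSON + CSV), the model checkpoint, the archived configuration, and a
#' run log with seeds and counts — are written to `out_dir`.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with `report` (an `eval_report`), `model`, the
#'   `segments` by split, and `dataset`.
#' @export
run_experiment <- function(config, out_dir = tempfile("grfnet_run_")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "run.log")
  logmsg <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(...))
    cat(line, "\n", file = logf, append = TRUE, sep = "")
    message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  if (config$split_counts[3] == 0)
    stop("stage 'split' failed: configuration has 0 test subjects",
         call. = FALSE)

  dataset <- stage("data", {
    if (!is.null(config$synthetic)) {
      logmsg("generating synthetic dataset: %d subjects x %d trials (seed %d)",
             config$synthetic$n_subjects, config$synthetic$trials_per_subject,
             config$synthetic$seed)
      generate_dataset(config$synthetic)
    } else {
      logmsg("loading recordings from %s", config$data_dir)
      load_dataset_csv(config$data_dir)
    }
  })

  segments <- stage("preprocess", {
    segs <- list()
    dropped <- 0L
    for (tr in dataset$trials) {
      seg <- tryCatch(
        synchronize_pair(tr$lc, tr$fp, spec = config$filter,
                         fp_threshold = config$fp_threshold,
                         lc_threshold = config$lc_threshold,
                         min_hold = config$min_hold,
                         timing_group = tr$timing_group),
        error = function(e) {
          logmsg("dropped trial %s/%s: %s", tr$lc$subject_id,
                 tr$lc$trial_id, conditionMessage(e))
          NULL
        })
      if (is.null(seg)) dropped <- dropped + 1L
      else segs[[length(segs) + 1L]] <- seg
    }
    logmsg("preprocessed %d stance segments (%d dropped)",
           length(segs), dropped)
    segs
  })

  split <- stage("split", {
    if (config$split_counts[3] == 0)
      stop("configuration has 0 test subjects")
    ids <- unique(vapply(segments, `[[`, "", "subject_id"))
    sp <- split_subjects(ids, config$split_counts, config$split_seed)
    logmsg("subject split (seed %d): %d train / %d validation / %d test",
           config$split_seed, length(sp$train), length(sp$validation),
           length(sp$test))
    sp
  })
  by_split <- lapply(split, function(ids)
    Filter(function(s) s$subject_id %in% ids, segments))

  model <- stage("train", {
    logmsg("training: widths %s, %d epochs, lr %g, batch %d, seed %d",
           paste(config$model$lstm_widths, collapse = "/"),
           config$model$epochs, config$model$learning_rate,
           config$model$batch_size, config$model$seed)
    grfnet(by_split$train, by_split$validation, config$model)
  })

  report <- stage("evaluate", {
    if (!length(by_split$test)) stop("no test segments after preprocessing")
    evaluate_testset(model, by_split$test, config$stance_fraction)
  })

  stage("write", {
    write_report(report, out_dir)
    write_grfnet(model, file.path(out_dir, "model.rds"))
    jsonlite::write_json(config_to_list(config),
                         file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(
      list(package_version = as.character(utils::packageVersion("grfnet")),
           r_version = R.version.string,
           seeds = list(synthetic = if (!is.null(config$synthetic))
             config$synthetic$seed, split = config$split_seed,
             model = config$model$seed)),
      file.path(out_dir, "versions.json"), auto_unbox = TRUE)
    logmsg("artifacts written to %s", out_dir)
  })

  invisible(list(report = report, model = model, segments = by_split,
                 dataset = dataset, out_dir = out_dir))
}
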