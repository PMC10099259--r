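#' Configuration of the sequence-to-sequence GRF estimator
#'
#' Defaults follow the training recipe the estimator was designed around:
#' three LSTM layers of 200, 50 and 200 units, each followed by a fully
#' connected layer of the same width, a 3-unit linear regression head, Adam
#' with learning rate 0.01, minibatch size 32 and 1000 epochs.
#'
#' @param lstm_widths Integer vector of LSTM layer widths.
#' @param epochs Training epochs.
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size (sequences are padded to the batch
#'   maximum length and the loss masked over padding).
#' @param optimizer Only `"adam"` is supported.
#' @param seed Integer seed for initialization and batch shuffling.
#' @param selection `"best_validation"` returns the checkpoint with the
#'   lowest validation loss; `"last_epoch"` the final parameters.
#' @param clip_norm Global gradient-norm clip (0 disables). Training at the
#'   recipe's learning rate of 0.01 is only stable with clipping; 1 is the
#'   default.
#' @return An object of class `grf_model_config`.
#' @export
grf_model_config <- function(lstm_widths = c(200L, 50L, 200L),
                             epochs = 1000L, learning_rate = 0.01,
                             batch_size = 32L, optimizer = "adam",
                             seed = 1L,
                             selection = c("best_validation", "last_epoch"),
                             clip_norm = 1) {
  selection <- match.arg(selection)
  stopifnot(all(lstm_widths >= 1), learning_rate > 0, epochs >= 0,
            batch_size >= 1, identical(optimizer, "adam"))
  structure(list(lstm_widths = as.integer(lstm_widths),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 optimizer = optimizer, seed = as.integer(seed),
                 selection = selection, clip_norm = clip_norm),
            class = "grf_model_config")
}

GRFNET_SCHEMA_VERSION <- 1L

segment_list <- function(x) {
  if (inherits(x, "stance_segment")) list(x)
  else if (is.list(x) && all(vapply(x, inherits, TRUE, "stance_segment"))) x
  else stop("expected a stance_segment or a list of stance_segments",
            call. = FALSE)
}

# Per-channel z-score statistics from the training split only.
fit_scaler <- function(segments) {
  X <- do.call(rbind, lapply(segments, `[[`, "inputs"))
  Y <- do.call(rbind, lapply(segments, `[[`, "targets"))
  sc <- list(x_mean = colMeans(X), x_sd = apply(X, 2, stats::sd),
             y_mean = colMeans(Y), y_sd = apply(Y, 2, stats::sd))
  if (any(sc$x_sd <= 0) || any(sc$y_sd <= 0))
    stop("cannot normalize: a channel has zero variance in the training split",
         call. = FALSE)
  sc
}

identity_scaler <- function(n_in = 4L, n_out = 3L) {
  list(x_mean = rep(0, n_in), x_sd = rep(1, n_in),
       y_mean = rep(0, n_out), y_sd = rep(1, n_out))
}

scale_mat <- function(m, mean, sd) sweep(sweep(m, 2, mean), 2, sd, "/")
unscale_mat <- function(m, mean, sd) sweep(sweep(m, 2, sd, "*"), 2, mean, "+")

check_subject_disjoint <- function(train, validation) {
  tr <- unique(vapply(train, `[[`, "", "subject_id"))
  va <- unique(vapply(validation, `[[`, "", "subject_id"))
  both <- intersect(tr, va)
  if (length(both))
    stop("training and validation sets share subjects (",
         paste(both, collapse = ", "),
         "); subject-wise splitting is required", call. = FALSE)
}

#' Fit the sequence-to-sequence LSTM GRF estimator
#'
#' Maps the four load-cell input channels (heel, 1st metatarsal, 5th
#' metatarsal, sum) of synchronized stance segments to the three GRF axes
#' (vertical, AP, ML). Inputs and targets are z-scored per channel with
#' training-split statistics; the loss is mean squared error over the
#' normalized channels, masked over batch padding.
#'
#' @param train List of `stance_segment` objects (training split).
#' @param validation Optional list of `stance_segment` objects from
#'   different subjects (enforced); required for
#'   `selection = "best_validation"`.
#' @param config A [grf_model_config()].
#' @return An object of class `grfnet`: learned parameters, channel scaler,
#'   per-epoch training history, configuration and seed.
#' @seealso [predict.grfnet()], [write_grfnet()], [evaluate_testset()]
#' @export
grfnet <- function(train, validation = NULL, config = grf_model_config()) {
  stopifnot(inherits(config, "grf_model_config"))
  train <- segment_list(train)
  if (!length(train)) stop("training set is empty", call. = FALSE)
  has_val <- !is.null(validation) && length(validation) > 0
  if (has_val) {
    validation <- segment_list(validation)
    check_subject_disjoint(train, validation)
  } else if (config$selection == "best_validation" && config$epochs > 0) {
    config$selection <- "last_epoch"
  }
  scaler <- fit_scaler(train)
  norm_x <- function(s) scale_mat(s$inputs, scaler$x_mean, scaler$x_sd)
  norm_y <- function(s) scale_mat(s$targets, scaler$y_mean, scaler$y_sd)
  X <- lapply(train, norm_x)
  Y <- lapply(train, norm_y)
  Xv <- if (has_val) lapply(validation, norm_x) else list()
  Yv <- if (has_val) lapply(validation, norm_y) else list()

  params <- lstm_init(config$lstm_widths, 4L, 3L, config$seed)
  if (config$epochs == 0) {
    fit <- list(params = params, best_params = params, best_epoch = 0L,
                train_loss = numeric(0), val_loss = numeric(0))
  } else {
    fit <- lstm_train(params, config$lstm_widths, X, Y, Xv, Yv,
                      config$epochs, config$learning_rate, config$batch_size,
                      config$seed, config$clip_norm,
                      config$selection == "best_validation")
  }
  sel <- if (config$selection == "best_validation" && fit$best_epoch > 0)
    fit$best_params else fit$params
  history <- data.frame(
    epoch = seq_along(fit$train_loss),
    train_loss = as.numeric(fit$train_loss),
    val_loss = if (length(fit$val_loss)) as.numeric(fit$val_loss) else
      rep(NA_real_, length(fit$train_loss)))
  structure(list(params = sel, final_params = fit$params,
                 widths = config$lstm_widths, scaler = scaler,
                 history = history,
                 best_epoch = if (fit$best_epoch > 0) fit$best_epoch else
                   config$epochs,
                 config = config, seed = config$seed,
                 n_train = length(train), n_validation = length(Xv),
                 schema_version = GRFNET_SCHEMA_VERSION),
            class = "grfnet")
}

#' Build an untrained estimator
#'
#' Seeded parameter initialization with an identity channel scaler; mainly
#' useful for architecture/shape checks. Equivalent to fitting with
#' `epochs = 0` but without training data.
#'
#' @param config A [grf_model_config()].
#' @return An untrained `grfnet` object.
#' @export
grfnet_init <- function(config = grf_model_config()) {
  structure(list(params = lstm_init(config$lstm_widths, 4L, 3L, config$seed),
                 final_params = NULL, widths = config$lstm_widths,
                 scaler = identity_scaler(), history = data.frame(
                   epoch = integer(0), train_loss = numeric(0),
                   val_loss = numeric(0)),
                 best_epoch = 0L, config = config, seed = config$seed,
                 n_train = 0L, n_validation = 0L,
                 schema_version = GRFNET_SCHEMA_VERSION),
            class = "grfnet")
}

#' Estimate three-axis GRF from load-cell inputs
#'
#' @param object A fitted [grfnet()] model.
#' @param newdata A `stance_segment`, a list of them, or a numeric T x 4
#'   matrix of input channels (heel, met1, met5, sum) in newtons.
#' @param ... Unused.
#' @return A T x 3 matrix (columns vertical, ap, ml) of forces in newtons,
#'   or a list of such matrices when `newdata` is a list.
#' @export
predict.grfnet <- function(object, newdata, ...) {
  one <- function(m) {
    if (!is.matrix(m) || ncol(m) != 4)
      stop("inputs must have 4 channels (heel, met1, met5, sum)",
           call. = FALSE)
    if (anyNA(m) || any(!is.finite(m)))
      stop("inputs must be finite", call. = FALSE)
    xn <- scale_mat(m, object$scaler$x_mean, object$scaler$x_sd)
    yn <- lstm_forward_one(object$params, object$widths, xn)
    out <- unscale_mat(yn, object$scaler$y_mean, object$scaler$y_sd)
    colnames(out) <- c("vertical", "ap", "ml")
    out
  }
  if (inherits(newdata, "stance_segment")) return(one(newdata$inputs))
  if (is.matrix(newdata)) return(one(newdata))
  if (is.list(newdata))
    return(lapply(newdata, function(s)
      one(if (inherits(s, "stance_segment")) s$inputs else s)))
  stop("unsupported 'newdata'", call. = FALSE)
}

#' @export
coef.grfnet <- function(object, ...) object$params

#' @export
print.grfnet <- function(x, ...) {
  cat("Sequence-to-sequence LSTM GRF estimator\n")
  cat("  architecture: ",
      paste(sprintf("LSTM(%d)+FC(%d)", x$widths, x$widths), collapse = " -> "),
      " -> FC(3)\n", sep = "")
  cat(sprintf("  trained: %d epochs on %d segments (%d validation)\n",
              nrow(x$history), x$n_train, x$n_validation))
  if (nrow(x$history) > 0) {
    cat(sprintf("  selected checkpoint: epoch %d", x$best_epoch))
    if (!all(is.na(x$history$val_loss)))
      cat(sprintf(" (validation loss %.4f)",
                  x$history$val_loss[x$best_epoch]))
    cat("\n")
  }
  invisible(x)
}

#' @export
summary.grfnet <- function(object, ...) {
  n_par <- sum(vapply(object$params, length, 0L))
  h <- object$history
  out <- list(widths = object$widths, n_parameters = n_par,
              epochs_run = nrow(h), best_epoch = object$best_epoch,
              final_train_loss = if (nrow(h)) h$train_loss[nrow(h)] else NA,
              best_val_loss = if (nrow(h) && !all(is.na(h$val_loss)))
                min(h$val_loss) else NA,
              config = object$config)
  class(out) <- "summary.grfnet"
  out
}

#' @export
print.summary.grfnet <- function(x, ...) {
  cat("seq2seq LSTM GRF estimator —", x$n_parameters, "parameters\n")
  cat("LSTM widths:", paste(x$widths, collapse = "/"),
      "| epochs run:", x$epochs_run,
      "| selected epoch:", x$best_epoch, "\n")
  if (!is.na(x$final_train_loss))
    cat(sprintf("final training loss (normalized MSE): %.5f\n",
                x$final_train_loss))
  if (!is.na(x$best_val_loss))
    cat(sprintf("best validation loss (normalized MSE): %.5f\n",
                x$best_val_loss))
  invisible(x)
}

#' Plot training history
#'
#' @param x A fitted `grfnet`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.grfnet <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) stop("model has no training history", call. = FALSE)
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("black", "red3"),
                    xlab = "epoch", ylab = "normalized MSE", log = "y", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("black", "red3"), bty = "n")
  invisible(x)
}

#' Save / load a fitted estimator
#'
#' The checkpoint is a single file holding the parameters, channel scaler,
#' configuration and training history, tagged with a schema version.
#'
#' @param object A `grfnet` model.
#' @param path File path.
#' @return `read_grfnet` returns the restored `grfnet` object;
#'   `write_grfnet` returns `path` invisibly.
#' @export
write_grfnet <- function(object, path) {
  stopifnot(inherits(object, "grfnet"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname write_grfnet
#' @export
read_grfnet <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "grfnet") ||
      !identical(obj$schema_version, GRFNET_SCHEMA_VERSION))
    stop("not a grfnet checkpoint with a supported schema version",
         call. = FALSE)
  obj
}
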