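# Covariate-driven stem-moisture filling: a recurrent model maps a window
# of micro-environment channels (air humidity, PAR, soil temperature) to
# the stem-moisture value at the window's final timestamp.  Each gap index
# is predicted from covariates alone — no recursion, no feedback of
# predictions — so fill length is not limited by error accumulation.

.subset_channels <- c(AH = "air_humidity", PAR = "par",
                      ST = "soil_temperature")

resolve_subset <- function(input_subset) {
  if (!length(input_subset)) {
    stop("input_subset must name at least one covariate channel",
         call. = FALSE)
  }
  out <- ifelse(input_subset %in% names(.subset_channels),
                .subset_channels[input_subset],
                input_subset)
  unknown <- setdiff(out, unname(.subset_channels))
  if (length(unknown)) {
    stop(sprintf("unknown covariate channel(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  unname(out)
}

#' Aligned multi-channel frame for covariate filling
#'
#' @param target Stem-moisture [stem_series()] (may contain gaps).
#' @param covariates Named list of aligned covariate [stem_series()]
#'   (`air_humidity`, `par`, `soil_temperature`); equal length and
#'   cadence to the target.
#' @param input_subset Channels used as model input, by short code
#'   (`"AH"`, `"PAR"`, `"ST"`) or full name.
#' @return An object of class `covariate_frame`.
#' @export
covariate_frame <- function(target, covariates,
                            input_subset = c("AH", "PAR", "ST")) {
  stopifnot(inherits(target, "stem_series"), length(covariates) >= 1L,
            !is.null(names(covariates)))
  subset <- resolve_subset(input_subset)
  for (nm in names(covariates)) {
    cov <- covariates[[nm]]
    stopifnot(inherits(cov, "stem_series"))
    if (length(cov) != length(target) ||
        abs(cov$cadence_minutes - target$cadence_minutes) > 1e-9) {
      stop(sprintf("covariate '%s' is not aligned with the target", nm),
           call. = FALSE)
    }
  }
  missing_ch <- setdiff(subset, names(covariates))
  if (length(missing_ch)) {
    stop(sprintf("frame lacks requested channel(s): %s",
                 paste(missing_ch, collapse = ", ")), call. = FALSE)
  }
  structure(list(target = target, covariates = covariates,
                 input_subset = subset),
            class = "covariate_frame")
}

#' @export
print.covariate_frame <- function(x, ...) {
  cat(sprintf("<covariate_frame> %d samples, channels: %s -> %s\n",
              length(x$target), paste(x$input_subset, collapse = " + "),
              x$target$channel))
  invisible(x)
}

# covariate windows ending at each index in `ends`; per-channel
# normalization transforms must already be fitted
covariate_window_array <- function(frame, ends, window_length, transforms) {
  subset <- frame$input_subset
  Fd <- length(subset)
  X <- array(NA_real_, dim = c(length(ends), window_length, Fd))
  for (j in seq_len(Fd)) {
    vals <- normalize_values(frame$covariates[[subset[j]]]$values,
                             transforms[[subset[j]]])
    for (k in seq_along(ends)) {
      idx <- (ends[k] - window_length + 1L):ends[k]
      X[k, , j] <- vals[idx]
    }
  }
  X
}

#' Train a covariate-to-stem-moisture model
#'
#' The model consumes a `window_length`-long window of the selected
#' covariate channels (default one day) and predicts the stem-moisture
#' value at the window's final timestamp.  Min-max normalization is
#' fitted per channel on the training range.
#'
#' @param frame A [covariate_frame()]; the target must be observed over
#'   the training range and the covariates over all window positions.
#' @param arch An [architecture_spec()] with
#'   `input_features = length(input_subset)`; `NULL` builds the default
#'   3-layer, 50-unit stack with keep-probability 0.8 dropout via
#'   [covariate_architecture()].
#' @param train_range Integer index range used for training (default: the
#'   whole frame).
#' @param epochs,seed,learning_rate Passed to [train_recurrent()].
#' @param window_length Covariate window length in samples (default 144,
#'   one day at 10-min cadence); used when `arch` is `NULL`.
#' @return A `trained_model` whose `transform` field carries the
#'   per-channel transforms, the target transform, the input subset and
#'   the window length.
#' @export
train_covariate_model <- function(frame, arch = NULL, train_range = NULL,
                                  epochs = 100L, seed = 1L,
                                  learning_rate = 1e-3,
                                  window_length = 144L) {
  stopifnot(inherits(frame, "covariate_frame"))
  subset <- frame$input_subset
  if (is.null(arch)) {
    arch <- covariate_architecture(n_layers = 3L, units = 50L,
                                   keep_prob = 0.8,
                                   input_features = length(subset),
                                   window_length = window_length)
  }
  if (arch$input_features != length(subset)) {
    stop(sprintf(
      "architecture expects %d input features but the frame subset has %d channels",
      arch$input_features, length(subset)), call. = FALSE)
  }
  w <- arch$window_length
  n <- length(frame$target)
  if (is.null(train_range)) train_range <- seq_len(n)
  ends <- train_range[train_range >= w]
  tv <- frame$target$values[ends]
  keep <- !is.na(tv)
  ends <- ends[keep]; tv <- tv[keep]
  if (!length(ends)) {
    stop("training range has no observed target beyond the first window",
         call. = FALSE)
  }
  transforms <- lapply(subset, function(nm) {
    fit_minmax(frame$covariates[[nm]], train_range)
  })
  names(transforms) <- subset
  target_tf <- fit_minmax(frame$target, train_range)
  X <- covariate_window_array(frame, ends, w, transforms)
  y <- normalize_values(tv, target_tf)
  tf <- list(channels = transforms, target = target_tf,
             input_subset = subset, window_length = w)
  train_recurrent(arch, X, y, epochs = epochs, seed = seed,
                  learning_rate = learning_rate, transform = tf)
}

#' Reference covariate-model architectures
#'
#' Builds the three covariate-filling stacks compared in the study:
#' 2 recurrent layers of 50 units, 3 layers of 50 units, and 3 layers of
#' 50 units with dropout at keep-probability 0.8 (drop fraction 0.2)
#' after the first layer.
#'
#' @param n_layers Number of LSTM layers (2 or 3).
#' @param units Units per layer (default 50).
#' @param keep_prob Dropout keep-probability (`NULL` for no dropout;
#'   0.8 reproduces the published "dropout weight 0.8" setting read as a
#'   keep-probability).
#' @param input_features Number of covariate channels.
#' @param window_length,batch_size See [architecture_spec()].
#' @return An [architecture_spec()].
#' @export
covariate_architecture <- function(n_layers = 3L, units = 50L,
                                   keep_prob = 0.8, input_features = 3L,
                                   window_length = 144L,
                                   batch_size = 100L) {
  stopifnot(n_layers >= 1L)
  layers <- list(lstm_layer(units))
  if (!is.null(keep_prob)) {
    stopifnot(keep_prob > 0, keep_prob <= 1)
    if (keep_prob < 1) layers <- c(layers, list(dropout_layer(1 - keep_prob)))
  }
  for (j in seq_len(n_layers - 1L)) {
    layers <- c(layers, list(lstm_layer(units)))
  }
  layers <- c(layers, list(dense_layer(1L)))
  architecture_spec(layers, window_length = window_length,
                    batch_size = batch_size,
                    input_features = input_features)
}

#' Fill a gap from covariates alone
#'
#' One prediction per gap index, each computed from the covariate window
#' ending at that index; no recursion or feedback, so the fill length is
#' unlimited by the window length and the result is independent of fill
#' order.
#'
#' @param model A model from [train_covariate_model()].
#' @param frame A [covariate_frame()] whose covariates are observed over
#'   the gap (and the `window_length - 1` samples before it).
#' @param gap The [gap_spec()] to fill.
#' @return A [fill_result()] with scheme `"covariate"`.
#' @export
fill_from_covariates <- function(model, frame, gap) {
  stopifnot(inherits(model, "trained_model"),
            inherits(frame, "covariate_frame"))
  check_gap_bounds(frame$target, gap)
  tf <- model$transform
  subset <- tf$input_subset
  if (!setequal(subset, frame$input_subset)) {
    stop("frame input subset differs from the one the model was trained on",
         call. = FALSE)
  }
  w <- tf$window_length
  idx <- gap_indices(gap)
  if (idx[1L] - w + 1L < 1L) {
    stop(sprintf(
      "gap start %d leaves no room for a %d-sample covariate window",
      gap$start, w), call. = FALSE)
  }
  for (nm in subset) {
    vals <- frame$covariates[[nm]]$values
    span <- (idx[1L] - w + 1L):idx[length(idx)]
    bad <- span[is.na(vals[span])]
    if (length(bad)) {
      stop(sprintf("covariate '%s' is missing at index %d inside the fill window",
                   nm, bad[1L]), call. = FALSE)
    }
  }
  X <- covariate_window_array(frame, idx, w, tf$channels)
  pred <- predict_windows(model, X)
  fill_result("covariate", gap, denormalize_values(pred, tf$target),
              provenance = list(input_subset = subset, window_length = w,
                                seed = model$seed))
}

#' Compare covariate input subsets
#'
#' Trains one model per input subset under an identical configuration and
#' seed, fills the same evaluation gap with each, and reports the errors
#' against the observed truth.  Defaults to the seven canonical subsets
#' AH, PAR, ST, AH+PAR, AH+ST, PAR+ST, AH+PAR+ST.
#'
#' @param frame A [covariate_frame()] with a fully observed target (the
#'   truth on the evaluation gap).
#' @param gap Evaluation [gap_spec()] (treated as unseen target data).
#' @param subsets List of character vectors of channel codes.
#' @param train_range Training index range (default: everything before
#'   the gap).
#' @param units,n_layers,keep_prob,window_length Architecture settings
#'   applied to every subset (input width varies with the subset).
#' @param epochs,seed,learning_rate Training settings shared by all runs.
#' @return A `data.frame` with one error row per subset, in input order.
#' @export
compare_input_subsets <- function(frame, gap,
                                  subsets = list("AH", "PAR", "ST",
                                                 c("AH", "PAR"),
                                                 c("AH", "ST"),
                                                 c("PAR", "ST"),
                                                 c("AH", "PAR", "ST")),
                                  train_range = NULL,
                                  units = 50L, n_layers = 3L,
                                  keep_prob = 0.8, window_length = 144L,
                                  epochs = 100L, seed = 1L,
                                  learning_rate = 1e-3) {
  stopifnot(inherits(frame, "covariate_frame"), length(subsets) >= 1L)
  check_gap_bounds(frame$target, gap)
  if (is.null(train_range)) train_range <- seq_len(gap$start - 1L)
  truth <- frame$target$values[gap_indices(gap)]
  if (anyNA(truth)) stop("frame target must be observed on the gap",
                         call. = FALSE)
  rows <- lapply(subsets, function(sub) {
    f <- covariate_frame(frame$target, frame$covariates,
                         input_subset = sub)
    arch <- covariate_architecture(n_layers = n_layers, units = units,
                                   keep_prob = keep_prob,
                                   input_features = length(f$input_subset),
                                   window_length = window_length)
    model <- train_covariate_model(f, arch, train_range = train_range,
                                   epochs = epochs, seed = seed,
                                   learning_rate = learning_rate)
    res <- fill_from_covariates(model, f, gap)
    cbind(data.frame(subset = paste(sub, collapse = " + ")),
          as.data.frame(error_report(res$filled, truth)))
  })
  do.call(rbind, rows)
}

#' Compare covariate-model architectures
#'
#' Reproduces the three-row architecture comparison (2x50, 3x50,
#' 3x50 with keep-probability 0.8 dropout) on any frame.
#'
#' @inheritParams compare_input_subsets
#' @param archs Named list of [architecture_spec()]s; default the three
#'   canonical stacks.
#' @return A `data.frame` with one error row per architecture.
#' @export
compare_architectures <- function(frame, gap, archs = NULL,
                                  train_range = NULL, window_length = 144L,
                                  epochs = 100L, seed = 1L,
                                  learning_rate = 1e-3) {
  stopifnot(inherits(frame, "covariate_frame"))
  Fd <- length(frame$input_subset)
  if (is.null(archs)) {
    archs <- list(
      "2*50" = covariate_architecture(2L, 50L, keep_prob = NULL,
                                      input_features = Fd,
                                      window_length = window_length),
      "3*50" = covariate_architecture(3L, 50L, keep_prob = NULL,
                                      input_features = Fd,
                                      window_length = window_length),
      "3*50*0.8" = covariate_architecture(3L, 50L, keep_prob = 0.8,
                                          input_features = Fd,
                                          window_length = window_length))
  }
  if (is.null(train_range)) train_range <- seq_len(gap$start - 1L)
  truth <- frame$target$values[gap_indices(gap)]
  rows <- lapply(names(archs), function(nm) {
    model <- train_covariate_model(frame, archs[[nm]],
                                   train_range = train_range,
                                   epochs = epochs, seed = seed,
                                   learning_rate = learning_rate)
    res <- fill_from_covariates(model, frame, gap)
    cbind(data.frame(architecture = nm),
          as.data.frame(error_report(res$filled, truth)))
  })
  do.call(rbind, rows)
}
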