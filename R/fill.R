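# Recursive window-push gap filling and bidirectional fusion.
#
# A gap is filled one step at a time: the model predicts the value just
# past its input window, the prediction is appended to the window and the
# oldest value dropped, and the window is pushed forward until the gap is
# covered.  Predictions feed back verbatim in normalized space (no
# clipping) — error accumulation along the gap is a studied behaviour of
# this recursion, not something to mask.  A reverse fill runs the same
# procedure on the time-reversed series, and the two directional fills
# are fused per index by weights summing to one.

model_window_length <- function(model) model$architecture$window_length
model_transform <- function(model) model$transform

.fill_schemes <- c("forward", "reverse", "bidir_equal", "bidir_decreasing",
                   "bidir_segmented")

#' Construct a fill result
#'
#' @param scheme Scheme label (`"forward"`, `"reverse"`,
#'   `"bidir_equal"`, `"bidir_decreasing"`, `"bidir_segmented"`,
#'   `"covariate"` or `"baseline:<name>"`).
#' @param gap The [gap_spec()] that was filled.
#' @param filled Numeric vector of denormalized filled values,
#'   forward-aligned to the gap indices (length = gap length).
#' @param weights Optional two-column matrix of per-index fusion weights
#'   `(a_i, b_i)`; present iff the scheme is bidirectional, each row
#'   summing to 1.
#' @param provenance List of free-form identifiers (models, seeds,
#'   configuration).
#' @return An object of class `fill_result`.
#' @export
fill_result <- function(scheme, gap, filled, weights = NULL,
                        provenance = list()) {
  stopifnot(inherits(gap, "gap_spec"))
  filled <- as.numeric(filled)
  if (length(filled) != gap$length) {
    stop(sprintf("filled length %d does not match gap length %d",
                 length(filled), gap$length), call. = FALSE)
  }
  bidir <- grepl("^bidir_", scheme)
  if (bidir) {
    stopifnot(is.matrix(weights), nrow(weights) == gap$length,
              ncol(weights) == 2L)
    if (any(abs(rowSums(weights) - 1) > 1e-12)) {
      stop("fusion weights must satisfy a_i + b_i = 1 at every index",
           call. = FALSE)
    }
  } else if (!is.null(weights)) {
    stop("weights are only recorded for bidirectional schemes",
         call. = FALSE)
  }
  structure(list(scheme = scheme, gap = gap, filled = filled,
                 weights = weights, provenance = provenance),
            class = "fill_result")
}

#' @export
print.fill_result <- function(x, ...) {
  cat(sprintf("<fill_result> scheme '%s', gap %d..%d (%d values)\n",
              x$scheme, x$gap$start, x$gap$start + x$gap$length - 1L,
              x$gap$length))
  invisible(x)
}

check_same_gap <- function(a, b) {
  stopifnot(inherits(a, "fill_result"), inherits(b, "fill_result"))
  if (a$gap$start != b$gap$start || a$gap$length != b$gap$length) {
    stop("fill results cover different gaps and cannot be combined",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Fill a gap by recursive one-step prediction in one direction
#'
#' Forward: the `window_length` observed values immediately before the
#' gap seed the window and the gap is filled from its start.  Reverse:
#' the same recursion runs on the time-reversed series (seeded by the
#' values immediately *after* the gap), and the result is re-aligned to
#' forward index order.
#'
#' @param model A `trained_model` or [oracle_model()] carrying the
#'   normalization transform of its training data.
#' @param series [stem_series()] observed on the run-up side of the gap.
#' @param gap The [gap_spec()] to fill.
#' @param direction `"forward"` or `"reverse"`.
#' @return A [fill_result()] with denormalized values.
#' @export
fill_directional <- function(model, series, gap,
                             direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  check_gap_bounds(series, gap)
  if (direction == "reverse") {
    n <- length(series$values)
    res <- fill_directional(model, reverse_series(series),
                            mirror_gap(gap, n), direction = "forward")
    return(fill_result("reverse", gap, rev(res$filled),
                       provenance = res$provenance))
  }
  w <- model_window_length(model)
  tf <- model_transform(model)
  pre <- (gap$start - w):(gap$start - 1L)
  if (pre[1L] < 1L || anyNA(series$values[pre])) {
    stop(sprintf(
      "the %d values immediately preceding the gap must be observed", w),
      call. = FALSE)
  }
  buffer <- series$values[pre]
  if (!is.null(tf)) buffer <- normalize_values(buffer, tf)
  filled <- numeric(gap$length)
  for (k in seq_len(gap$length)) {
    p <- predict_next(model, buffer, step = k)
    filled[k] <- p
    buffer <- c(buffer[-1L], p)
  }
  if (!is.null(tf)) filled <- denormalize_values(filled, tf)
  fill_result("forward", gap, filled,
              provenance = list(window_length = w,
                                model_class = class(model)[1L]))
}

#' Equal-weight bidirectional fusion
#'
#' `z_i = 0.5 x_i + 0.5 y_i` at every gap index.
#'
#' @param forward,reverse [fill_result()]s of schemes `"forward"` and
#'   `"reverse"` over the same gap.
#' @return A `fill_result` of scheme `"bidir_equal"` with recorded
#'   weights `(0.5, 0.5)`.
#' @export
combine_equal <- function(forward, reverse) {
  check_same_gap(forward, reverse)
  stopifnot(forward$scheme == "forward", reverse$scheme == "reverse")
  L <- forward$gap$length
  w <- matrix(0.5, L, 2L)
  fill_result("bidir_equal", forward$gap,
              0.5 * forward$filled + 0.5 * reverse$filled, weights = w,
              provenance = list(forward = forward$provenance,
                                reverse = reverse$provenance))
}

decreasing_weight_schedule <- function(L, gradient = 0.05) {
  n_levels <- 1 / gradient
  if (abs(n_levels - round(n_levels)) > 1e-9) {
    stop("gradient must divide the weight range evenly (e.g. 0.05)",
         call. = FALSE)
  }
  n_levels <- as.integer(round(n_levels))  # 20 levels for gradient 0.05
  a_levels <- 1 - gradient * (seq_len(n_levels) - 1L)   # 1.00 .. 0.05
  # partition the L gap indices into n_levels consecutive blocks; any
  # remainder goes to the earliest blocks
  base <- L %/% n_levels
  sizes <- rep(base, n_levels)
  rem <- L - base * n_levels
  if (rem > 0L) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  a <- rep(a_levels, times = sizes)
  cbind(a = a, b = 1 - a)
}

#' Decreasing-weight bidirectional fusion
#'
#' The forward weight descends from 1.00 to `gradient` (default 0.05) in
#' `gradient` steps across the gap while the reverse weight ascends
#' complementarily from 0.00 to `1 - gradient`, so `a_i + b_i = 1`
#' everywhere.  The 20 weight levels are mapped onto the gap as equal
#' consecutive blocks (remainders to the earliest blocks), preserving the
#' endpoint pairs (1.00, 0.00) and (0.05, 0.95).
#'
#' @inheritParams combine_equal
#' @param gradient Weight decrement per level (must divide the range
#'   evenly; default 0.05, i.e. 20 levels).
#' @return A `fill_result` of scheme `"bidir_decreasing"`.
#' @export
combine_decreasing <- function(forward, reverse, gradient = 0.05) {
  check_same_gap(forward, reverse)
  stopifnot(forward$scheme == "forward", reverse$scheme == "reverse")
  w <- decreasing_weight_schedule(forward$gap$length, gradient)
  fill_result("bidir_decreasing", forward$gap,
              w[, 1L] * forward$filled + w[, 2L] * reverse$filled,
              weights = w,
              provenance = list(gradient = gradient,
                                forward = forward$provenance,
                                reverse = reverse$provenance))
}

#' Segmented bidirectional fusion
#'
#' The first half of the gap (ceiling split) takes the forward fill, the
#' remainder the reverse fill.  A junction discontinuity is expected and
#' deliberately not smoothed.
#'
#' @inheritParams combine_equal
#' @return A `fill_result` of scheme `"bidir_segmented"`.
#' @export
combine_segmented <- function(forward, reverse) {
  check_same_gap(forward, reverse)
  stopifnot(forward$scheme == "forward", reverse$scheme == "reverse")
  L <- forward$gap$length
  n_fwd <- as.integer(ceiling(L / 2))
  z <- c(forward$filled[seq_len(n_fwd)],
         reverse$filled[seq.int(n_fwd + 1L, length.out = L - n_fwd)])
  w <- matrix(0, L, 2L)
  w[seq_len(n_fwd), 1L] <- 1
  w[seq.int(n_fwd + 1L, length.out = L - n_fwd), 2L] <- 1
  fill_result("bidir_segmented", forward$gap, z, weights = w,
              provenance = list(split_at = n_fwd,
                                forward = forward$provenance,
                                reverse = reverse$provenance))
}

#' Train directional models and fill a gap bidirectionally
#'
#' Trains a forward model on the observed pre-gap segment and a reverse
#' model on the time-reversed post-gap segment (independent seeds
#' `seed` and `seed + 1`), runs both recursive fills, and fuses them with
#' the requested scheme.  One min-max normalization, fitted on the union
#' of both training segments, is shared by the two models.
#'
#' @param arch An [architecture_spec()].
#' @param series [stem_series()] with at least `window_length + 1`
#'   observed points on each side of the gap.
#' @param gap The [gap_spec()] to fill.
#' @param scheme One of `"forward"`, `"reverse"`, `"bidir_equal"`,
#'   `"bidir_decreasing"`, `"bidir_segmented"`.
#' @param train_config List of training options: `epochs` (default 100),
#'   `learning_rate` (default 1e-3), `train_length` (points used per
#'   side; default all observed flank), `gradient` (default 0.05).
#' @param seed Master seed; the forward model uses `seed`, the reverse
#'   model `seed + 1`.
#' @return A [fill_result()]; for bidirectional schemes (and any scheme
#'   where both directions were trained) the component directional fills
#'   are attached as `$components$forward` / `$components$reverse`.
#' @export
fill_bidirectional <- function(arch, series, gap,
                               scheme = "bidir_decreasing",
                               train_config = list(), seed = 1L) {
  stopifnot(inherits(arch, "architecture_spec"))
  check_gap_bounds(series, gap)
  if (!scheme %in% .fill_schemes) {
    stop(sprintf("unknown scheme '%s' (expected one of %s)", scheme,
                 paste(.fill_schemes, collapse = ", ")), call. = FALSE)
  }
  tc <- utils::modifyList(
    list(epochs = 100L, learning_rate = 1e-3, train_length = NULL,
         gradient = 0.05),
    train_config)
  n <- length(series$values)
  w <- arch$window_length
  gap_end <- gap$start + gap$length - 1L

  seg_side <- function(side) {
    if (side == "pre") {
      hi <- gap$start - 1L
      lo <- if (is.null(tc$train_length)) 1L
            else max(1L, hi - tc$train_length + 1L)
    } else {
      lo <- gap_end + 1L
      hi <- if (is.null(tc$train_length)) n
            else min(n, lo + tc$train_length - 1L)
    }
    if (hi - lo + 1L < w + 1L || lo < 1L || hi > n ||
        anyNA(series$values[lo:hi])) {
      stop(sprintf(
        "insufficient observed data on the %s-gap side: need at least %d contiguous points",
        side, w + 1L), call. = FALSE)
    }
    lo:hi
  }

  need_fwd <- scheme != "reverse"
  need_rev <- scheme != "forward"
  pre_seg <- if (need_fwd) seg_side("pre")
  post_seg <- if (need_rev) seg_side("post")
  tf <- fit_minmax(series, c(pre_seg, post_seg))
  norm <- normalize_series(series, tf)

  train_side <- function(segment, reversed, model_seed) {
    s <- norm
    if (reversed) {
      s <- reverse_series(norm)
      segment <- sort(n - segment + 1L)
    }
    tw <- make_training_windows(s, w, segment)
    train_recurrent(arch, tw$x, tw$y, epochs = tc$epochs,
                    seed = model_seed,
                    learning_rate = tc$learning_rate, transform = tf)
  }

  fwd_fill <- rev_fill <- NULL
  if (need_fwd) {
    m_f <- train_side(pre_seg, reversed = FALSE, model_seed = seed)
    fwd_fill <- fill_directional(m_f, series, gap, "forward")
  }
  if (need_rev) {
    m_r <- train_side(post_seg, reversed = TRUE, model_seed = seed + 1L)
    rev_fill <- fill_directional(m_r, series, gap, "reverse")
  }

  out <- switch(scheme,
    forward = fwd_fill,
    reverse = rev_fill,
    bidir_equal = combine_equal(fwd_fill, rev_fill),
    bidir_decreasing = combine_decreasing(fwd_fill, rev_fill,
                                          gradient = tc$gradient),
    bidir_segmented = combine_segmented(fwd_fill, rev_fill))
  out$provenance$seed <- seed
  out$provenance$epochs <- tc$epochs
  out$components <- list(forward = fwd_fill, reverse = rev_fill)
  out
}
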