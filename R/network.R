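# Minimal stacked recurrent network (LSTM / simple RNN / dropout / dense)
# with backpropagation through time and Adam, in vectorised base R.
#
# No deep-learning framework is assumed.  Weights follow the fused-bias
# convention: an LSTM layer holds one matrix W of shape (n + m) x 4m over
# the concatenated [h_{t-1}, x_t] vector (gate column blocks ordered
# forget | input | candidate | output) and one bias vector of length 4m,
# so its instantiated size is exactly 4 * ((n + m) * m + m) — the same
# quantity count_layer_params() computes analytically.  A simple-RNN
# layer holds (n + m) x m plus m.  Inference never applies dropout, so
# prediction is deterministic.

sigmoid <- function(x) 1 / (1 + exp(-x))

add_bias <- function(Z, b) Z + matrix(b, nrow(Z), length(b), byrow = TRUE)

glorot_matrix <- function(n_in, n_out, fan_out = n_out) {
  lim <- sqrt(6 / (n_in + fan_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

# ---- weight initialisation -------------------------------------------------

init_weights <- function(arch) {
  width <- arch$input_features
  weights <- vector("list", length(arch$layers))
  for (j in seq_along(arch$layers)) {
    ly <- arch$layers[[j]]
    if (ly$kind == "dropout") {
      weights[[j]] <- list(kind = "dropout", rate = ly$rate)
    } else if (ly$kind == "lstm") {
      m <- ly$units
      b <- rep(0, 4L * m)
      b[seq_len(m)] <- 1  # unit forget-gate bias, the conventional default
      weights[[j]] <- list(kind = "lstm", units = m,
                           W = glorot_matrix(width + m, 4L * m, fan_out = m),
                           b = b,
                           return_sequences = ly$return_sequences)
      width <- m
    } else if (ly$kind == "rnn") {
      m <- ly$units
      weights[[j]] <- list(kind = "rnn", units = m,
                           W = glorot_matrix(width + m, m), b = rep(0, m),
                           return_sequences = ly$return_sequences)
      width <- m
    } else {
      m <- ly$units
      weights[[j]] <- list(kind = "dense", units = m,
                           W = glorot_matrix(width, m), b = rep(0, m))
      width <- m
    }
  }
  weights
}

# ---- layer forward/backward ------------------------------------------------

lstm_forward <- function(lw, xs, training) {
  Tn <- length(xs); batch <- nrow(xs[[1L]]); m <- lw$units
  h <- matrix(0, batch, m); cs <- matrix(0, batch, m)
  H <- vector("list", Tn)
  cache <- if (training) {
    list(comb = vector("list", Tn), f = vector("list", Tn),
         i = vector("list", Tn), g = vector("list", Tn),
         o = vector("list", Tn), c_prev = vector("list", Tn),
         c = vector("list", Tn))
  }
  for (t in seq_len(Tn)) {
    comb <- cbind(h, xs[[t]])
    Z <- add_bias(comb %*% lw$W, lw$b)
    f <- sigmoid(Z[, seq_len(m), drop = FALSE])
    i <- sigmoid(Z[, m + seq_len(m), drop = FALSE])
    g <- tanh(Z[, 2L * m + seq_len(m), drop = FALSE])
    o <- sigmoid(Z[, 3L * m + seq_len(m), drop = FALSE])
    c_new <- f * cs + i * g
    h <- o * tanh(c_new)
    if (training) {
      cache$comb[[t]] <- comb; cache$f[[t]] <- f; cache$i[[t]] <- i
      cache$g[[t]] <- g; cache$o[[t]] <- o; cache$c_prev[[t]] <- cs
      cache$c[[t]] <- c_new
    }
    cs <- c_new
    H[[t]] <- h
  }
  list(out = if (lw$return_sequences) H else h, cache = cache)
}

lstm_backward <- function(lw, cache, d_out) {
  # d_out: list over time of gradients w.r.t. the hidden outputs (zeros
  # allowed); returns weight gradients and gradients w.r.t. the inputs.
  Tn <- length(cache$comb); m <- lw$units
  batch <- nrow(cache$comb[[1L]])
  n <- ncol(cache$comb[[1L]]) - m
  dW <- matrix(0, n + m, 4L * m); db <- rep(0, 4L * m)
  dh_next <- matrix(0, batch, m); dc_next <- matrix(0, batch, m)
  dX <- vector("list", Tn)
  for (t in rev(seq_len(Tn))) {
    dh <- d_out[[t]] + dh_next
    f <- cache$f[[t]]; i <- cache$i[[t]]; g <- cache$g[[t]]
    o <- cache$o[[t]]; cs <- cache$c[[t]]; cp <- cache$c_prev[[t]]
    tc <- tanh(cs)
    do_ <- dh * tc
    dc <- dh * o * (1 - tc^2) + dc_next
    df <- dc * cp
    di <- dc * g
    dg <- dc * i
    dZ <- cbind(df * f * (1 - f), di * i * (1 - i),
                dg * (1 - g^2), do_ * o * (1 - o))
    dW <- dW + crossprod(cache$comb[[t]], dZ)
    db <- db + colSums(dZ)
    dcomb <- tcrossprod(dZ, lw$W)
    dh_next <- dcomb[, seq_len(m), drop = FALSE]
    dX[[t]] <- dcomb[, m + seq_len(n), drop = FALSE]
    dc_next <- dc * f
  }
  list(dW = dW, db = db, dX = dX)
}

rnn_forward <- function(lw, xs, training) {
  Tn <- length(xs); batch <- nrow(xs[[1L]]); m <- lw$units
  h <- matrix(0, batch, m)
  H <- vector("list", Tn)
  cache <- if (training) list(comb = vector("list", Tn),
                              h = vector("list", Tn))
  for (t in seq_len(Tn)) {
    comb <- cbind(h, xs[[t]])
    h <- tanh(add_bias(comb %*% lw$W, lw$b))
    if (training) { cache$comb[[t]] <- comb; cache$h[[t]] <- h }
    H[[t]] <- h
  }
  list(out = if (lw$return_sequences) H else h, cache = cache)
}

rnn_backward <- function(lw, cache, d_out) {
  Tn <- length(cache$comb); m <- lw$units
  batch <- nrow(cache$comb[[1L]])
  n <- ncol(cache$comb[[1L]]) - m
  dW <- matrix(0, n + m, m); db <- rep(0, m)
  dh_next <- matrix(0, batch, m)
  dX <- vector("list", Tn)
  for (t in rev(seq_len(Tn))) {
    dh <- d_out[[t]] + dh_next
    dz <- dh * (1 - cache$h[[t]]^2)
    dW <- dW + crossprod(cache$comb[[t]], dz)
    db <- db + colSums(dz)
    dcomb <- tcrossprod(dz, lw$W)
    dh_next <- dcomb[, seq_len(m), drop = FALSE]
    dX[[t]] <- dcomb[, m + seq_len(n), drop = FALSE]
  }
  list(dW = dW, db = db, dX = dX)
}

# inverted dropout; masks drawn fresh per step and per batch
dropout_forward <- function(rate, x, training) {
  if (!training || rate == 0) return(list(out = x, masks = NULL))
  keep <- 1 - rate
  mask_one <- function(h) {
    msk <- (matrix(stats::runif(length(h)), nrow(h), ncol(h)) < keep) / keep
    msk
  }
  if (is.list(x)) {
    masks <- lapply(x, mask_one)
    out <- Map(`*`, x, masks)
  } else {
    masks <- mask_one(x)
    out <- x * masks
  }
  list(out = out, masks = masks)
}

# ---- full forward / backward ----------------------------------------------

array_to_steps <- function(X) {
  # (batch, T, F) array -> list over time of (batch x F) matrices
  d <- dim(X)
  lapply(seq_len(d[2L]), function(t) {
    matrix(X[, t, , drop = FALSE], d[1L], d[3L])
  })
}

net_forward <- function(weights, X, training = FALSE) {
  rep_ <- array_to_steps(X)
  caches <- vector("list", length(weights))
  for (j in seq_along(weights)) {
    lw <- weights[[j]]
    if (lw$kind == "lstm") {
      fw <- lstm_forward(lw, rep_, training)
      rep_ <- fw$out; caches[[j]] <- fw$cache
    } else if (lw$kind == "rnn") {
      fw <- rnn_forward(lw, rep_, training)
      rep_ <- fw$out; caches[[j]] <- fw$cache
    } else if (lw$kind == "dropout") {
      fw <- dropout_forward(lw$rate, rep_, training)
      rep_ <- fw$out; caches[[j]] <- fw$masks
    } else {
      caches[[j]] <- rep_  # dense input
      rep_ <- add_bias(rep_ %*% lw$W, lw$b)
    }
  }
  list(out = rep_, caches = caches)
}

net_backward <- function(weights, caches, dY) {
  grads <- vector("list", length(weights))
  d_rep <- dY  # matrix at the top
  for (j in rev(seq_along(weights))) {
    lw <- weights[[j]]
    if (lw$kind == "dense") {
      Xin <- caches[[j]]
      grads[[j]] <- list(dW = crossprod(Xin, d_rep), db = colSums(d_rep))
      d_rep <- tcrossprod(d_rep, lw$W)
    } else if (lw$kind == "dropout") {
      msk <- caches[[j]]
      if (!is.null(msk)) {
        d_rep <- if (is.list(d_rep)) Map(`*`, d_rep, msk) else d_rep * msk
      }
    } else {
      Tn <- length(caches[[j]]$comb)
      batch <- nrow(caches[[j]]$comb[[1L]])
      m <- lw$units
      if (is.list(d_rep)) {
        d_out <- d_rep
      } else {
        # gradient only at the final hidden state
        zero <- matrix(0, batch, m)
        d_out <- rep(list(zero), Tn)
        d_out[[Tn]] <- d_rep
      }
      bk <- if (lw$kind == "lstm") lstm_backward(lw, caches[[j]], d_out)
            else rnn_backward(lw, caches[[j]], d_out)
      grads[[j]] <- list(dW = bk$dW, db = bk$db)
      d_rep <- bk$dX
    }
  }
  grads
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(weights) {
  lapply(weights, function(lw) {
    if (is.null(lw$W)) return(NULL)
    list(mW = lw$W * 0, vW = lw$W * 0,
         mb = lw$b * 0, vb = lw$b * 0)
  })
}

adam_step <- function(weights, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (j in seq_along(weights)) {
    if (is.null(weights[[j]]$W)) next
    g <- grads[[j]]
    s <- state[[j]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$dW
    s$vW <- beta2 * s$vW + (1 - beta2) * g$dW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$db
    s$vb <- beta2 * s$vb + (1 - beta2) * g$db^2
    corr1 <- 1 - beta1^t; corr2 <- 1 - beta2^t
    weights[[j]]$W <- weights[[j]]$W -
      lr * (s$mW / corr1) / (sqrt(s$vW / corr2) + eps)
    weights[[j]]$b <- weights[[j]]$b -
      lr * (s$mb / corr1) / (sqrt(s$vb / corr2) + eps)
    state[[j]] <- s
  }
  list(weights = weights, state = state)
}

# ---- training windows ------------------------------------------------------

#' Build sliding training windows and one-step targets
#'
#' Window `k` covers values `segment[k] .. segment[k] + window_length - 1`
#' and its target is the value one step further, so a fully observed
#' segment of `L` points yields `L - window_length` (window, target)
#' pairs.
#'
#' @param series A [stem_series()] (typically already normalized).
#' @param window_length Window length in samples.
#' @param segment Integer index range (contiguous) to draw windows from;
#'   default the whole series.  Must be fully observed and longer than
#'   `window_length`.
#' @return List with `x` (matrix, one window per row) and `y` (targets).
#' @export
make_training_windows <- function(series, window_length, segment = NULL) {
  stopifnot(inherits(series, "stem_series"), window_length >= 1)
  if (is.null(segment)) segment <- seq_along(series$values)
  if (any(diff(segment) != 1L)) {
    stop("segment must be a contiguous index range", call. = FALSE)
  }
  vals <- series$values[segment]
  if (anyNA(vals)) {
    stop("training segment contains missing values", call. = FALSE)
  }
  L <- length(vals)
  if (L <= window_length) {
    stop(sprintf(
      "segment length %d must exceed window_length %d to yield a target",
      L, window_length), call. = FALSE)
  }
  n <- L - window_length
  x <- matrix(NA_real_, n, window_length)
  for (k in seq_len(n)) x[k, ] <- vals[k:(k + window_length - 1L)]
  list(x = x, y = vals[window_length + seq_len(n)])
}

# ---- training --------------------------------------------------------------

coerce_windows <- function(x, arch) {
  if (is.matrix(x)) x <- array(x, dim = c(nrow(x), ncol(x), 1L))
  stopifnot(length(dim(x)) == 3L)
  if (dim(x)[2L] != arch$window_length) {
    stop(sprintf("windows have length %d but the architecture expects %d",
                 dim(x)[2L], arch$window_length), call. = FALSE)
  }
  if (dim(x)[3L] != arch$input_features) {
    stop(sprintf("windows carry %d feature(s) but the architecture expects %d",
                 dim(x)[3L], arch$input_features), call. = FALSE)
  }
  x
}

#' Train a recurrent one-step predictor
#'
#' Minimises the mean squared one-step error with Adam over seeded
#' mini-batches; dropout is active during training only.  With a fixed
#' seed the loss trace and fitted weights are fully reproducible.
#'
#' @param arch An [architecture_spec()].
#' @param x Training windows: matrix (windows x window_length) for
#'   univariate input or array (windows x window_length x features);
#'   values are expected in normalized units.
#' @param y One-step targets, normalized units.
#' @param epochs Training epochs (default 100); 0 returns the seeded
#'   initialisation with an empty loss trace.
#' @param seed Integer seed for initialisation, shuffling and dropout.
#' @param learning_rate Adam step size (default 1e-3).
#' @param transform Optional [fit_minmax()] transform (or per-channel list)
#'   stored with the model for denormalisation.
#' @param shuffle Reshuffle mini-batches each epoch (default TRUE).
#' @return An object of class `trained_model` with fields `architecture`,
#'   `weights`, `transform`, `loss_trace`, `seed`, `epochs`.
#' @export
train_recurrent <- function(arch, x, y, epochs = 100L, seed = 1L,
                            learning_rate = 1e-3, transform = NULL,
                            shuffle = TRUE) {
  stopifnot(inherits(arch, "architecture_spec"))
  x <- coerce_windows(x, arch)
  n <- dim(x)[1L]
  stopifnot(n >= 1L, length(y) == n)
  loss_trace <- numeric(0L)
  weights <- NULL
  withr::with_seed(seed, {
    weights <- init_weights(arch)
    if (epochs > 0L) {
      state <- adam_init(weights)
      step <- 0L
      loss_trace <- numeric(epochs)
      for (ep in seq_len(epochs)) {
        ord <- if (shuffle) sample.int(n) else seq_len(n)
        starts <- seq(1L, n, by = arch$batch_size)
        ep_loss <- 0
        for (s in starts) {
          idx <- ord[s:min(s + arch$batch_size - 1L, n)]
          xb <- x[idx, , , drop = FALSE]
          yb <- y[idx]
          fw <- net_forward(weights, xb, training = TRUE)
          resid <- drop(fw$out) - yb
          ep_loss <- ep_loss + sum(resid^2)
          dY <- matrix(2 * resid / length(idx), ncol = 1L)
          grads <- net_backward(weights, fw$caches, dY)
          step <- step + 1L
          upd <- adam_step(weights, grads, state, learning_rate, step)
          weights <- upd$weights; state <- upd$state
        }
        loss_trace[ep] <- ep_loss / n
      }
    }
  })
  structure(list(architecture = arch, weights = weights,
                 transform = transform, loss_trace = loss_trace,
                 seed = as.integer(seed), epochs = as.integer(epochs)),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> %d epochs, seed %d, %d parameters\n",
              x$epochs, x$seed, model_param_count(x)$total))
  if (length(x$loss_trace)) {
    cat(sprintf("  MSE loss: first %.3g, last %.3g\n",
                x$loss_trace[1L], x$loss_trace[length(x$loss_trace)]))
  }
  invisible(x)
}

#' Instantiated parameter count of a trained model
#'
#' Counts the elements of the actually allocated weight arrays, layer by
#' layer — the implementation-side counterpart of the analytic
#' [count_model_params()] (the two must agree exactly).
#'
#' @param model A [train_recurrent()] model.
#' @return List with `per_layer` and `total` (integer).
#' @export
model_param_count <- function(model) {
  stopifnot(inherits(model, "trained_model"))
  per <- vapply(model$weights, function(lw) {
    if (is.null(lw$W)) 0L else length(lw$W) + length(lw$b)
  }, integer(1L))
  list(per_layer = per, total = sum(per))
}

# ---- prediction ------------------------------------------------------------

#' Predict the value one step past a window
#'
#' Generic over trained networks and oracle predictors.  Inference is
#' deterministic (dropout disabled); repeated calls on the same window
#' return identical values.
#'
#' @param model A `trained_model` or [oracle_model()].
#' @param window Numeric vector of length `window_length` (univariate) or
#'   matrix `window_length x features`, in normalized units.
#' @param step Optional fill-step index forwarded to oracle predictors.
#' @return A single numeric prediction in normalized units.
#' @export
predict_next <- function(model, window, step = NULL) {
  UseMethod("predict_next")
}

#' @export
predict_next.trained_model <- function(model, window, step = NULL) {
  arch <- model$architecture
  if (is.matrix(window)) {
    stopifnot(nrow(window) == arch$window_length,
              ncol(window) == arch$input_features)
    X <- array(window, dim = c(1L, nrow(window), ncol(window)))
  } else {
    if (length(window) != arch$window_length) {
      stop(sprintf("window length %d does not match architecture window %d",
                   length(window), arch$window_length), call. = FALSE)
    }
    X <- array(window, dim = c(1L, length(window), 1L))
  }
  drop(net_forward(model$weights, X, training = FALSE)$out)
}

#' Batched window prediction
#'
#' @param model A `trained_model`.
#' @param x Matrix (windows x window_length) or array
#'   (windows x window_length x features) of normalized windows.
#' @return Numeric vector of normalized one-step predictions.
#' @export
predict_windows <- function(model, x) {
  stopifnot(inherits(model, "trained_model"))
  x <- coerce_windows(x, model$architecture)
  drop(net_forward(model$weights, x, training = FALSE)$out)
}

#' Wrap a deterministic predictor function as a model
#'
#' Oracle predictors stand in for trained networks when the recursion
#' itself is under test: `fn(window, step)` (or `fn(window)`) must return
#' the normalized one-step prediction.  `step` is the 1-based index of
#' the value being filled, counted in the fill direction.
#'
#' @param fn Prediction function.
#' @param window_length Window length the oracle expects.
#' @param transform Optional [fit_minmax()] transform for
#'   denormalisation.
#' @return An object of class `oracle_model`.
#' @export
oracle_model <- function(fn, window_length, transform = NULL) {
  stopifnot(is.function(fn), window_length >= 1)
  structure(list(fn = fn, window_length = as.integer(window_length),
                 transform = transform,
                 architecture = list(window_length =
                                       as.integer(window_length))),
            class = "oracle_model")
}

#' @export
predict_next.oracle_model <- function(model, window, step = NULL) {
  if (length(window) != model$window_length) {
    stop(sprintf("window length %d does not match oracle window %d",
                 length(window), model$window_length), call. = FALSE)
  }
  if (length(formals(model$fn)) >= 2L) model$fn(window, step)
  else model$fn(window)
}

# ---- serialization ---------------------------------------------------------

#' Save / load a trained model
#'
#' The model is written as a native R checkpoint (`.rds`) together with
#' a human-readable sidecar JSON (`<path>.json`) recording the
#' architecture, the normalization parameters, the training seed and the
#' per-layer parameter-count table.  The sidecar is documentation; the
#' checkpoint is what [load_trained_model()] restores.
#'
#' @param model A [train_recurrent()] model.
#' @param path Checkpoint path (conventionally ending in `.rds`).
#' @return `path`, invisibly / the restored `trained_model`.
#' @export
save_trained_model <- function(model, path) {
  stopifnot(inherits(model, "trained_model"))
  saveRDS(model, path)
  arch <- model$architecture
  sidecar <- list(
    layers = lapply(arch$layers, function(ly) {
      list(kind = ly$kind,
           units = if (!is.na(ly$units)) ly$units,
           rate = if (!is.na(ly$rate)) ly$rate,
           return_sequences = if (!is.na(ly$return_sequences))
             ly$return_sequences)
    }),
    window_length = arch$window_length,
    batch_size = arch$batch_size,
    input_features = arch$input_features,
    normalization = model$transform,
    seed = model$seed,
    epochs = model$epochs,
    parameter_counts = list(
      per_layer = count_model_params(arch)$per_layer,
      total = count_model_params(arch)$total))
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", force = TRUE)
  invisible(path)
}

#' @rdname save_trained_model
#' @export
load_trained_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "trained_model"))
  model
}
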