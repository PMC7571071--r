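# Architecture descriptors and analytic trainable-parameter accounting for
# the stacked recurrent networks.
#
# Counts use the fused-bias convention (one bias vector per gate):
#   LSTM layer   Param = 4 * ((n + m) * m + m)
#   simple RNN   Param = (n + m) * m + m
#   dense layer  Param = n * m + m
# with n the input feature width and m the number of units.  Each of the
# four LSTM gate blocks (forget, input, candidate, output) contributes
# (n + m) * m + m, so an LSTM layer holds exactly four times the
# parameters of the simple-RNN layer of the same size.

#' Describe one network layer
#'
#' @param kind One of `"lstm"`, `"rnn"`, `"dense"`, `"dropout"`.
#' @param units Number of units (positive integer; absent for dropout).
#' @param rate Drop fraction in \[0, 1) (dropout layers only).
#' @param return_sequences For recurrent layers: emit the whole hidden
#'   sequence (`TRUE`) or only the final state (`FALSE`).  Leave `NA` to
#'   let [architecture_spec()] infer it from the layer position.
#' @return An object of class `layer_spec`.
#' @export
layer_spec <- function(kind = c("lstm", "rnn", "dense", "dropout"),
                       units = NULL, rate = NULL,
                       return_sequences = NA) {
  kind <- match.arg(kind)
  if (kind == "dropout") {
    if (is.null(rate) || rate < 0 || rate >= 1) {
      stop("dropout rate must lie in [0, 1)", call. = FALSE)
    }
    units <- NA_integer_
  } else {
    if (is.null(units) || units < 1 || units != round(units)) {
      stop(sprintf("%s layers need units >= 1", kind), call. = FALSE)
    }
    units <- as.integer(units)
    rate <- NA_real_
  }
  structure(list(kind = kind, units = units, rate = rate,
                 return_sequences = return_sequences),
            class = "layer_spec")
}

#' @rdname layer_spec
#' @export
lstm_layer <- function(units, return_sequences = NA) {
  layer_spec("lstm", units = units, return_sequences = return_sequences)
}

#' @rdname layer_spec
#' @export
rnn_layer <- function(units, return_sequences = NA) {
  layer_spec("rnn", units = units, return_sequences = return_sequences)
}

#' @rdname layer_spec
#' @export
dense_layer <- function(units = 1L) layer_spec("dense", units = units)

#' @rdname layer_spec
#' @export
dropout_layer <- function(rate = 0.2) layer_spec("dropout", rate = rate)

#' Describe a full network architecture
#'
#' Validates that the last layer is a 1-unit dense output and resolves
#' `return_sequences` for the recurrent layers: every recurrent layer
#' before the last one returns the full sequence, the last returns only
#' its final hidden state.
#'
#' @param layers Ordered list of [layer_spec()]s.
#' @param window_length Input window length in samples (default 200).
#' @param batch_size Training batch size (default 100).
#' @param input_features Feature width of each time step (1 for the
#'   univariate filler).
#' @return An object of class `architecture_spec`.
#' @export
architecture_spec <- function(layers, window_length = 200L,
                              batch_size = 100L, input_features = 1L) {
  stopifnot(length(layers) >= 1L,
            all(vapply(layers, inherits, logical(1L), "layer_spec")),
            window_length >= 1, batch_size >= 1, input_features >= 1)
  kinds <- vapply(layers, `[[`, character(1L), "kind")
  last <- layers[[length(layers)]]
  if (last$kind != "dense" || last$units != 1L) {
    stop("the final layer must be a dense layer with 1 unit", call. = FALSE)
  }
  rec <- which(kinds %in% c("lstm", "rnn"))
  if (!length(rec)) stop("at least one recurrent layer is required",
                         call. = FALSE)
  for (j in rec) {
    if (is.na(layers[[j]]$return_sequences)) {
      layers[[j]]$return_sequences <- j != max(rec)
    }
  }
  structure(list(layers = layers,
                 window_length = as.integer(window_length),
                 batch_size = as.integer(batch_size),
                 input_features = as.integer(input_features)),
            class = "architecture_spec")
}

#' Reference univariate LSTM architecture
#'
#' Three stacked LSTM layers of 256, 128 and 64 units with one dropout
#' layer after the first, closed by a 1-unit dense output; input window
#' 200, batch size 100.  [default_rnn_architecture()] is the same stack
#' with simple-RNN layers.
#'
#' @param units Units per recurrent layer.
#' @param dropout Drop fraction after the first recurrent layer.
#' @param window_length,batch_size,input_features See
#'   [architecture_spec()].
#' @return An `architecture_spec`.
#' @export
default_lstm_architecture <- function(units = c(256L, 128L, 64L),
                                      dropout = 0.2,
                                      window_length = 200L,
                                      batch_size = 100L,
                                      input_features = 1L) {
  .default_recurrent_arch("lstm", units, dropout, window_length,
                          batch_size, input_features)
}

#' @rdname default_lstm_architecture
#' @export
default_rnn_architecture <- function(units = c(256L, 128L, 64L),
                                     dropout = 0.2,
                                     window_length = 200L,
                                     batch_size = 100L,
                                     input_features = 1L) {
  .default_recurrent_arch("rnn", units, dropout, window_length,
                          batch_size, input_features)
}

.default_recurrent_arch <- function(kind, units, dropout, window_length,
                                    batch_size, input_features) {
  layers <- list(layer_spec(kind, units = units[1L]))
  if (!is.null(dropout) && dropout > 0) {
    layers <- c(layers, list(dropout_layer(dropout)))
  }
  for (u in units[-1L]) layers <- c(layers, list(layer_spec(kind, units = u)))
  layers <- c(layers, list(dense_layer(1L)))
  architecture_spec(layers, window_length = window_length,
                    batch_size = batch_size,
                    input_features = input_features)
}

#' Parameters of one recurrent gate block
#'
#' One LSTM gate (forget, input, candidate or output) holds a weight
#' matrix over the concatenated `[h, x]` vector plus a fused bias:
#' `(n + m) * m + m` parameters.  For the first layer of the reference
#' network (`n = 1`, `m = 256`) this is 66,048; the state-update block
#' (input gate + candidate) holds twice that, 132,096.
#'
#' @param input_width Feature width `n` of the current input.
#' @param units Hidden width `m`.
#' @return Integer parameter count.
#' @export
count_gate_params <- function(input_width, units) {
  if (input_width < 0 || units < 0) {
    stop("input_width and units must be nonnegative", call. = FALSE)
  }
  as.integer((input_width + units) * units + units)
}

#' Analytic per-layer parameter count
#'
#' @param kind `"lstm"`, `"rnn"`, `"dense"` or `"dropout"`.
#' @param input_width Feature width `n` consumed by the layer.
#' @param units Units `m` of the layer (ignored for dropout).
#' @return Integer count: `4 * ((n + m) * m + m)` for LSTM,
#'   `(n + m) * m + m` for simple RNN, `n * m + m` for dense, 0 for
#'   dropout.
#' @export
count_layer_params <- function(kind = c("lstm", "rnn", "dense", "dropout"),
                               input_width, units = 0L) {
  kind <- match.arg(kind)
  if (kind == "dropout") return(0L)
  if (input_width < 0 || units < 0) {
    stop("input_width and units must be nonnegative", call. = FALSE)
  }
  n <- input_width; m <- units
  as.integer(switch(kind,
    lstm = 4 * ((n + m) * m + m),
    rnn = (n + m) * m + m,
    dense = n * m + m))
}

#' Analytic per-layer and total parameter counts of an architecture
#'
#' Walks the layer list tracking the feature width (dropout layers pass
#' the width through and contribute zero parameters).
#'
#' @param arch An [architecture_spec()].
#' @return List with `per_layer` (integer vector in layer order) and
#'   `total`.
#' @export
count_model_params <- function(arch) {
  stopifnot(inherits(arch, "architecture_spec"))
  width <- arch$input_features
  per <- integer(length(arch$layers))
  for (j in seq_along(arch$layers)) {
    ly <- arch$layers[[j]]
    if (ly$kind == "dropout") {
      per[j] <- 0L
    } else {
      per[j] <- count_layer_params(ly$kind, width, ly$units)
      width <- ly$units
    }
  }
  list(per_layer = per, total = sum(per))
}

#' Model-overview table
#'
#' A keras-style summary of an architecture: layer kind, output width and
#' analytic parameter count per layer, plus the total.
#'
#' @param arch An [architecture_spec()].
#' @return A `data.frame` with columns `layer`, `kind`, `units`, `params`.
#' @export
param_table <- function(arch) {
  stopifnot(inherits(arch, "architecture_spec"))
  counts <- count_model_params(arch)
  kinds <- vapply(arch$layers, `[[`, character(1L), "kind")
  units <- vapply(arch$layers, `[[`, integer(1L), "units")
  data.frame(layer = seq_along(arch$layers), kind = kinds,
             units = units, params = counts$per_layer)
}

#' @export
print.architecture_spec <- function(x, ...) {
  cat(sprintf(
    "<architecture_spec> window %d, batch %d, input features %d\n",
    x$window_length, x$batch_size, x$input_features))
  tb <- param_table(x)
  rates <- vapply(x$layers, `[[`, numeric(1L), "rate")
  tb$rate <- ifelse(is.na(rates), "", sprintf("%.2f", rates))
  print(tb, row.names = FALSE)
  cat(sprintf("total trainable parameters: %d\n",
              count_model_params(x)$total))
  invisible(x)
}
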