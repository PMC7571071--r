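test_that("analytic layer parameter counts match the published formulas", {
  # reference LSTM stack: 1 -> 256 -> 128 -> 64 -> 1
  expect_identical(count_layer_params("lstm", 1, 256), 264192L)
  expect_identical(count_layer_params("lstm", 256, 128), 197120L)
  expect_identical(count_layer_params("lstm", 128, 64), 49408L)
  expect_identical(count_layer_params("dense", 64, 1), 65L)
  # one gate block, and the two-gate state-update block
  expect_identical(count_gate_params(1, 256), 66048L)
  expect_identical(2L * count_gate_params(1, 256), 132096L)
  # simple-RNN stack
  expect_identical(count_layer_params("rnn", 1, 256), 66048L)
  expect_identical(count_layer_params("rnn", 256, 128), 49280L)
  expect_identical(count_layer_params("rnn", 128, 64), 12352L)
  # degenerate and invalid inputs
  expect_identical(count_layer_params("lstm", 0, 0), 0L)
  expect_error(count_layer_params("lstm", -1, 8), "nonnegative")
})

test_that("whole-model counts follow layer order with zero-cost dropout", {
  lstm <- default_lstm_architecture()
  expect_identical(count_model_params(lstm)$per_layer,
                   c(264192L, 0L, 197120L, 49408L, 65L))
  expect_identical(count_model_params(lstm)$total, 510785L)
  rnn <- default_rnn_architecture()
  expect_identical(count_model_params(rnn)$per_layer,
                   c(66048L, 0L, 49280L, 12352L, 65L))
  dense_only <- architecture_spec(list(rnn_layer(4L), dense_layer(1L)),
                                  window_length = 4L)
  expect_identical(count_model_params(dense_only)$per_layer[2L], 5L)
})

test_that("LSTM layers hold exactly four times the simple-RNN parameters", {
  set.seed(99)
  for (k in 1:20) {
    n <- sample(1:300, 1)
    m <- sample(1:300, 1)
    expect_identical(count_layer_params("lstm", n, m),
                     4L * count_layer_params("rnn", n, m))
  }
})

test_that("instantiated weight arrays agree with the analytic counts", {
  for (arch in list(default_lstm_architecture(units = c(16L, 8L),
                                              window_length = 10L),
                    default_rnn_architecture(units = c(16L, 8L),
                                             window_length = 10L),
                    tiny_arch("lstm"),
                    covariate_architecture(3L, 10L, keep_prob = 0.8,
                                           input_features = 3L,
                                           window_length = 6L))) {
    m <- train_recurrent(arch,
                         matrix(0.5,
                                nrow = 2L,
                                ncol = arch$window_length *
                                  arch$input_features) |>
                           array(dim = c(2L, arch$window_length,
                                         arch$input_features)),
                         c(0.5, 0.5), epochs = 0L, seed = 1L)
    expect_identical(model_param_count(m)$per_layer,
                     count_model_params(arch)$per_layer)
    expect_identical(model_param_count(m)$total,
                     count_model_params(arch)$total)
  }
})

test_that("training windows slide one step with the documented count", {
  s <- sinusoid_series(1000L)
  tw <- make_training_windows(s, 200L)
  expect_identical(dim(tw$x), c(800L, 200L))
  expect_length(tw$y, 800L)
  expect_identical(tw$x[1L, ], s$values[1:200])
  expect_identical(tw$y[1L], s$values[201L])
  expect_identical(tw$y[800L], s$values[1000L])

  tw1 <- make_training_windows(sinusoid_series(201L), 200L)
  expect_identical(nrow(tw1$x), 1L)
  expect_error(make_training_windows(sinusoid_series(200L), 200L),
               "exceed")
  expect_error(make_training_windows(stem_series(c(50, NA, 51, 52)), 2L),
               "missing")
})

test_that("training reduces the loss on a noiseless sinusoid, reproducibly", {
  s <- sinusoid_series(200L, period = 24L)
  tf <- fit_minmax(s)
  tw <- make_training_windows(normalize_series(s, tf), 12L)
  arch <- tiny_arch("lstm")
  for (seed in 1:3) {
    m <- train_recurrent(arch, tw$x, tw$y, epochs = 100L, seed = seed,
                         learning_rate = 0.005, transform = tf)
    expect_length(m$loss_trace, 100L)
    expect_lt(m$loss_trace[100L], m$loss_trace[1L])
    # >= 10x reduction against the first epoch
    expect_lt(m$loss_trace[100L], m$loss_trace[1L] / 10)
  }
  m1 <- train_recurrent(arch, tw$x, tw$y, epochs = 5L, seed = 42L)
  m2 <- train_recurrent(arch, tw$x, tw$y, epochs = 5L, seed = 42L)
  expect_identical(m1$loss_trace, m2$loss_trace)
  expect_identical(m1$weights, m2$weights)

  m0 <- train_recurrent(arch, tw$x, tw$y, epochs = 0L, seed = 1L)
  expect_length(m0$loss_trace, 0L)
  expect_true(is.finite(predict_next(m0, tw$x[1L, ])))
})

test_that("prediction is deterministic and shape-checked", {
  s <- sinusoid_series(100L, period = 24L)
  tw <- make_training_windows(s, 12L)
  m <- train_recurrent(tiny_arch("rnn"), tw$x / 100, tw$y / 100,
                       epochs = 3L, seed = 1L)
  w <- tw$x[5L, ] / 100
  expect_identical(predict_next(m, w), predict_next(m, w))
  expect_error(predict_next(m, w[1:5]), "window length")
  expect_error(train_recurrent(tiny_arch("lstm", input_features = 2L),
                               tw$x, tw$y, epochs = 1L, seed = 1L),
               "feature")
})

test_that("a model trained on a constant-plus-jitter signal predicts near it", {
  # constant target c = 0.5 in normalized space; tiny jitter keeps the
  # min-max fit defined
  set.seed(3)
  vals <- 0.5 + rnorm(150, 0, 1e-3)
  s <- stem_series(pmin(pmax(vals * 100, 0), 100))
  tw <- make_training_windows(s, 12L)
  m <- train_recurrent(tiny_arch("lstm"), tw$x / 100, tw$y / 100,
                       epochs = 150L, seed = 2L, learning_rate = 0.01)
  p <- predict_next(m, rep(0.5, 12L))
  expect_lt(abs(p - 0.5), 0.02)
})

test_that("models round-trip through the checkpoint with a sidecar summary", {
  s <- sinusoid_series(80L, period = 24L)
  tf <- fit_minmax(s)
  tw <- make_training_windows(normalize_series(s, tf), 12L)
  m <- train_recurrent(tiny_arch("lstm"), tw$x, tw$y, epochs = 2L,
                       seed = 9L, transform = tf)
  path <- withr::local_tempfile(fileext = ".rds")
  save_trained_model(m, path)
  m2 <- load_trained_model(path)
  expect_identical(m2$weights, m$weights)
  expect_identical(predict_next(m2, tw$x[1L, ]),
                   predict_next(m, tw$x[1L, ]))
  side <- jsonlite::read_json(paste0(path, ".json"),
                              simplifyVector = TRUE)
  expect_identical(side$parameter_counts$total,
                   count_model_params(m$architecture)$total)
  expect_identical(side$seed, 9L)
  expect_equal(side$normalization$min, tf$min)
})
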