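# Shared fixtures for the test suite.
#
# The "scaled world" mirrors the benchmark layout (train:gap ratio 5:1,
# a window spanning one diurnal period, dropout after the first recurrent
# layer) at a size a plain-R training loop handles quickly: 48 samples
# per day instead of 144, a 96-sample central gap flanked by 480 observed
# samples per side, 32/16-unit two-layer stacks, 40 epochs.

scaled_spd <- 48L
scaled_window <- 48L
scaled_gap_length <- 96L
scaled_train <- list(epochs = 40L, learning_rate = 0.005)

scaled_lstm_arch <- function(input_features = 1L) {
  default_lstm_architecture(units = c(32L, 16L), dropout = 0.2,
                            window_length = scaled_window,
                            batch_size = 100L,
                            input_features = input_features)
}

scaled_rnn_arch <- function() {
  default_rnn_architecture(units = c(32L, 16L), dropout = 0.2,
                           window_length = scaled_window,
                           batch_size = 100L)
}

# scaled analogue of the paper-small layout: 480 + 96 + 480 samples
scaled_scenario <- function(seed = 1L, total_length = 1056L,
                            gap_length = scaled_gap_length, ...) {
  suppressWarnings(make_benchmark_scenario(
    "custom", seed = seed, total_length = total_length,
    gap_length = gap_length, samples_per_day = scaled_spd, ...))
}

# tiny architecture for fast unit tests of the training machinery
tiny_arch <- function(kind = "lstm", window_length = 12L,
                      input_features = 1L) {
  layers <- list(layer_spec(kind, units = 8L), dense_layer(1L))
  architecture_spec(layers, window_length = window_length,
                    batch_size = 32L, input_features = input_features)
}

# noiseless diurnal series: pure sinusoid around 50 with amplitude 5
sinusoid_series <- function(n, period = 144L, phase = 0) {
  t <- seq_len(n) - 1L
  stem_series(50 + 5 * sin(2 * pi * t / period + phase),
              cadence_minutes = 24 * 60 / period)
}

gap_truth <- function(scenario) {
  scenario$truth$values[gap_indices_of(scenario$gap)]
}

gap_indices_of <- function(gap) seq.int(gap$start, gap$start + gap$length - 1L)
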