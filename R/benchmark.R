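# End-to-end benchmark orchestration: simulate -> train -> fill ->
# evaluate, with a JSON run manifest, per-method reports and a stage log.
# Every stochastic stage receives a seed derived deterministically from
# the master seed, so a repeated run with the same config reproduces its
# reports byte for byte.

.benchmark_methods <- c("lstm_forward", "lstm_reverse", "bidir_equal",
                        "bidir_decreasing", "bidir_segmented",
                        "rnn_forward", "rnn_reverse",
                        "spline", "pchip", "arma", "arima")

#' Benchmark run configuration
#'
#' @param scenario Scenario name for [make_benchmark_scenario()]
#'   (`"paper-small"`, `"paper-large"`, `"custom"`).
#' @param methods Character vector of methods to run, among
#'   `lstm_forward`, `lstm_reverse`, `bidir_equal`, `bidir_decreasing`,
#'   `bidir_segmented`, `rnn_forward`, `rnn_reverse`, `spline`, `pchip`,
#'   `arma`, `arima`.
#' @param units Units per recurrent layer.
#' @param dropout Drop fraction after the first recurrent layer.
#' @param window_length,batch_size,epochs,learning_rate Training
#'   settings.
#' @param seed Master seed; stage seeds are derived from it.
#' @param out_dir Output directory for artifacts.
#' @param total_length,gap_length,samples_per_day Scenario overrides
#'   (custom/scaled runs).
#' @param max_order ARMA/ARIMA auto-selection bounds.
#' @return An object of class `run_config`.
#' @export
run_config <- function(scenario = "paper-small",
                       methods = .benchmark_methods,
                       units = c(256L, 128L, 64L), dropout = 0.2,
                       window_length = 200L, batch_size = 100L,
                       epochs = 100L, learning_rate = 1e-3,
                       seed = 1L, out_dir = "stemfill-run",
                       total_length = NULL, gap_length = NULL,
                       samples_per_day = 144L,
                       max_order = c(3L, 1L, 3L)) {
  unknown <- setdiff(methods, .benchmark_methods)
  if (length(unknown)) {
    stop(sprintf("unknown method(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  structure(list(scenario = scenario, methods = methods,
                 units = as.integer(units), dropout = dropout,
                 window_length = as.integer(window_length),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 seed = as.integer(seed), out_dir = out_dir,
                 total_length = total_length, gap_length = gap_length,
                 samples_per_day = as.integer(samples_per_day),
                 max_order = as.integer(max_order)),
            class = "run_config")
}

#' Serialize / restore a run configuration
#'
#' JSON round trip is lossless: `read_run_config(write_run_config(cfg))`
#' reproduces `cfg`.
#'
#' @param config A [run_config()].
#' @param path JSON file path.
#' @return `path` / the restored `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, obj[!vapply(obj, is.null, logical(1L))])
}

#' Run the end-to-end filling benchmark
#'
#' Simulates the scenario, masks the gap, runs every configured method,
#' evaluates each against the truth and writes to `out_dir`: `truth.csv`,
#' `masked.csv`, one `filled_<method>.csv` (with a `source` column) and
#' `report_<method>.json` per method, a `manifest.json` echoing the model
#' summary fields (input length, output length, layer sizes, algorithm,
#' epochs, batch size, seeds) and `run.log` with per-stage timing.  Any
#' stage failure aborts naming the stage, after flushing the log.
#'
#' @param config A [run_config()].
#' @return The output directory, invisibly; the comparison table is
#'   attached as attribute `"comparison"`.
#' @export
run_benchmark <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  log_lines <- character(0L)
  log_stage <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
    writeLines(log_lines, log_path)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      log_stage("stage '%s' FAILED: %s", name, conditionMessage(e))
      stop(sprintf("benchmark stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    log_stage("stage '%s' done in %.1fs", name,
              proc.time()[["elapsed"]] - t0)
    out
  }

  log_stage("benchmark scenario '%s', master seed %d", config$scenario,
            config$seed)
  scen <- stage("simulate", make_benchmark_scenario(
    config$scenario, seed = config$seed,
    total_length = config$total_length, gap_length = config$gap_length,
    samples_per_day = config$samples_per_day))
  truth <- scen$truth; gap <- scen$gap; masked <- scen$masked
  write_series_csv(truth, file.path(config$out_dir, "truth.csv"),
                   covariates = scen$covariates)
  write_series_csv(masked, file.path(config$out_dir, "masked.csv"))

  mk_arch <- function(kind) {
    fn <- if (kind == "lstm") default_lstm_architecture
          else default_rnn_architecture
    fn(units = config$units, dropout = config$dropout,
       window_length = config$window_length,
       batch_size = config$batch_size)
  }
  tc <- list(epochs = config$epochs,
             learning_rate = config$learning_rate)
  bl_cfg <- function(method) {
    baseline_config(method, max_order = config$max_order,
                    context_length = min(gap$start - 1L, 1000L))
  }
  # per-method seeds derived deterministically from the master seed
  method_seed <- function(j) config$seed + 100L * j

  results <- list()
  bidir_cache <- list()
  run_recurrent <- function(kind, scheme, j) {
    key <- kind
    if (is.null(bidir_cache[[key]])) {
      bidir_cache[[key]] <<- fill_bidirectional(
        mk_arch(kind), masked, gap, scheme = "bidir_decreasing",
        train_config = tc, seed = method_seed(j))
    }
    cached <- bidir_cache[[key]]
    switch(scheme,
      forward = cached$components$forward,
      reverse = cached$components$reverse,
      bidir_equal = combine_equal(cached$components$forward,
                                  cached$components$reverse),
      bidir_decreasing = cached,
      bidir_segmented = combine_segmented(cached$components$forward,
                                          cached$components$reverse))
  }
  for (j in seq_along(config$methods)) {
    m <- config$methods[j]
    results[[m]] <- stage(m, switch(m,
      lstm_forward = run_recurrent("lstm", "forward", 1L),
      lstm_reverse = run_recurrent("lstm", "reverse", 1L),
      bidir_equal = run_recurrent("lstm", "bidir_equal", 1L),
      bidir_decreasing = run_recurrent("lstm", "bidir_decreasing", 1L),
      bidir_segmented = run_recurrent("lstm", "bidir_segmented", 1L),
      rnn_forward = run_recurrent("rnn", "forward", 2L),
      rnn_reverse = run_recurrent("rnn", "reverse", 2L),
      spline = fill_interpolation(masked, gap, "spline",
                                  context_length = min(gap$start - 1L,
                                                       1000L)),
      pchip = fill_interpolation(masked, gap, "pchip",
                                 context_length = min(gap$start - 1L,
                                                      1000L)),
      arma = fill_forecast(masked, gap, "arma", bl_cfg("arma")),
      arima = fill_forecast(masked, gap, "arima", bl_cfg("arima"))))
  }

  cmp <- stage("evaluate", compare_methods(results, truth))
  for (m in names(results)) {
    res <- results[[m]]
    src <- rep("observed", length(truth))
    src[gap_indices(gap)] <- "filled"
    write_series_csv(apply_fill(masked, res),
                     file.path(config$out_dir,
                               sprintf("filled_%s.csv", m)),
                     source = src)
    report_to_json(cmp$reports[[m]], scheme = m,
                   provenance = res$provenance,
                   path = file.path(config$out_dir,
                                    sprintf("report_%s.json", m)))
  }

  n_side <- gap$start - 1L
  manifest <- list(
    scenario = config$scenario,
    input_length = min(n_side, length(truth) - (gap$start + gap$length - 1L)),
    output_length = gap$length,
    layers = paste0(length(config$units), "layer:",
                    paste(config$units, collapse = "*")),
    algorithms = config$methods,
    epochs = config$epochs,
    batch_size = config$batch_size,
    window_length = config$window_length,
    learning_rate = config$learning_rate,
    master_seed = config$seed,
    method_seeds = list(lstm = method_seed(1L), rnn = method_seed(2L)),
    total_length = length(truth),
    gap = list(start = gap$start, length = gap$length))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_stage("benchmark complete: %d methods", length(results))
  out <- config$out_dir
  attr(out, "comparison") <- cmp
  invisible(out)
}
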