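# Seeded synthetic generator of stem-moisture-like diurnal series and
# correlated micro-environment covariates.
#
# The generator emulates the qualitative features of capacitance-sensor
# stem-moisture records: a diurnal oscillation (sunrise/sunset driven) at a
# fixed number of samples per day, a slow multi-day drift, autocorrelated
# measurement noise, and a bounded physical value band.  It is a minimal
# statistical stand-in, not a mechanistic plant-hydraulics model.

#' Configuration of the stem-moisture simulator
#'
#' Defaults emulate the published record characteristics: 10-min cadence
#' (144 samples/day), values fluctuating inside a 43--57 % band around a
#' 50 % base level.
#'
#' @param n_days Number of simulated days (positive).
#' @param samples_per_day Samples per day (>= 2; default 144).
#' @param base_level Mean stem moisture, percent (default 50).
#' @param diurnal_amplitude Amplitude of the daily sinusoid, percent
#'   (default 5).
#' @param trend_amplitude Standard deviation of the slow multi-day drift,
#'   percent (default 1.5).
#' @param noise_sd Marginal standard deviation of the AR(1) noise, percent
#'   (default 0.3).
#' @param noise_ar1 AR(1) coefficient of the noise, in \[0, 1) (default 0.7).
#' @param value_band Two-element physical band the signal is clipped to
#'   (default `c(43, 57)`).
#' @param seed Integer seed; identical configs give identical series.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_days,
                              samples_per_day = 144L,
                              base_level = 50,
                              diurnal_amplitude = 5,
                              trend_amplitude = 1.5,
                              noise_sd = 0.3,
                              noise_ar1 = 0.7,
                              value_band = c(43, 57),
                              seed = 1L) {
  stopifnot(n_days >= 1, samples_per_day >= 2,
            noise_sd >= 0, trend_amplitude >= 0,
            noise_ar1 >= 0, noise_ar1 < 1,
            length(value_band) == 2L)
  if (value_band[1L] >= value_band[2L]) {
    stop("value_band must satisfy low < high", call. = FALSE)
  }
  if (base_level < value_band[1L] || base_level > value_band[2L]) {
    stop("base_level must lie inside value_band", call. = FALSE)
  }
  structure(
    list(n_days = as.integer(n_days),
         samples_per_day = as.integer(samples_per_day),
         base_level = base_level,
         diurnal_amplitude = diurnal_amplitude,
         trend_amplitude = trend_amplitude,
         noise_sd = noise_sd,
         noise_ar1 = noise_ar1,
         value_band = value_band,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Simulate a stem-moisture series
#'
#' Signal = base level + diurnal sinusoid (period `samples_per_day`,
#' seeded random phase) + slow spline-interpolated drift + AR(1) Gaussian
#' noise, clipped last to the physical band.  A warning is raised if more
#' than 1 % of samples are clipped (configs are expected to keep clipping
#' rare).
#'
#' @param config A [simulation_config()].
#' @return A fully observed [stem_series()] of length
#'   `n_days * samples_per_day` (10-min cadence when
#'   `samples_per_day = 144`).
#' @export
simulate_stem_moisture <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_days * config$samples_per_day
  spd <- config$samples_per_day
  withr::with_seed(config$seed, {
    phase <- stats::runif(1L, 0, 2 * pi)
    t <- seq_len(n) - 1L
    diurnal <- config$diurnal_amplitude * sin(2 * pi * t / spd + phase)
    trend <- rep(0, n)
    if (config$trend_amplitude > 0) {
      # one knot roughly every three days, spline-interpolated drift
      n_knots <- max(4L, ceiling(config$n_days / 3) + 1L)
      knot_x <- seq(0, n - 1L, length.out = n_knots)
      knot_y <- stats::rnorm(n_knots, 0, config$trend_amplitude)
      trend <- stats::spline(knot_x, knot_y, xout = t, method = "natural")$y
    }
    noise <- rep(0, n)
    if (config$noise_sd > 0) {
      innov_sd <- config$noise_sd * sqrt(1 - config$noise_ar1^2)
      eps <- stats::rnorm(n, 0, innov_sd)
      noise <- as.numeric(stats::filter(eps, config$noise_ar1,
                                        method = "recursive"))
    }
    x <- config$base_level + diurnal + trend + noise
  })
  lo <- config$value_band[1L]; hi <- config$value_band[2L]
  n_clip <- sum(x < lo | x > hi)
  if (n_clip > 0.01 * n) {
    warning(sprintf(
      "%.1f%% of simulated samples clipped to the value band; consider reducing amplitudes",
      100 * n_clip / n), call. = FALSE)
  }
  x <- pmin(pmax(x, lo), hi)
  cadence <- 24 * 60 / spd
  stem_series(x, cadence_minutes = cadence, channel = "stem_moisture")
}

# physical rescaling of a standardized covariate: center + scale * w,
# clipped to the channel's physical limits
.covariate_channels <- list(
  air_humidity     = list(center = 70, scale = 12, lower = 0, upper = 100),
  par              = list(center = 600, scale = 300, lower = 0, upper = Inf),
  soil_temperature = list(center = 20, scale = 3, lower = -Inf, upper = Inf)
)

#' Configuration of correlated covariate channels
#'
#' Default target correlations follow the published stem-moisture /
#' micro-environment correlation set: air humidity about +0.57, soil
#' temperature about +0.29, photosynthetically active radiation about
#' -0.30.
#'
#' @param target_correlations Named numeric vector of target Pearson
#'   correlations with the stem-moisture series, each with `|rho| < 1`;
#'   names among `air_humidity`, `par`, `soil_temperature`.
#' @param seed Integer seed.
#' @return An object of class `covariate_config`.
#' @export
covariate_config <- function(target_correlations = c(air_humidity = 0.57,
                                                     par = -0.30,
                                                     soil_temperature = 0.29),
                             seed = 1L) {
  stopifnot(length(target_correlations) >= 1L,
            !is.null(names(target_correlations)))
  if (any(abs(target_correlations) >= 1)) {
    stop("every target correlation must satisfy |rho| < 1", call. = FALSE)
  }
  unknown <- setdiff(names(target_correlations), names(.covariate_channels))
  if (length(unknown)) {
    stop(sprintf("unknown covariate channel(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  structure(list(target_correlations = target_correlations,
                 seed = as.integer(seed)),
            class = "covariate_config")
}

#' Simulate covariates correlated with a target series
#'
#' Each channel is built as `rho * standardized(target) +
#' sqrt(1 - rho^2) * noise`, then rescaled to a plausible physical range
#' (air humidity 0--100 %, PAR rectified at 0, soil temperature in deg C).
#' For series of length >= 5000 the empirical Pearson correlation with the
#' target is within about +/- 0.05 of `rho` (rectification of PAR absorbs
#' a small distortion).
#'
#' @param target A fully observed [stem_series()].
#' @param config A [covariate_config()].
#' @return Named list of [stem_series()], one per configured channel.
#' @export
simulate_covariates <- function(target, config = covariate_config()) {
  stopifnot(inherits(target, "stem_series"),
            inherits(config, "covariate_config"))
  if (anyNA(target$values)) {
    stop("target series must be fully observed", call. = FALSE)
  }
  n <- length(target$values)
  z <- as.numeric(scale(target$values))
  out <- list()
  withr::with_seed(config$seed, {
    for (nm in names(config$target_correlations)) {
      rho <- config$target_correlations[[nm]]
      w <- rho * z + sqrt(1 - rho^2) * stats::rnorm(n)
      ch <- .covariate_channels[[nm]]
      v <- ch$center + ch$scale * w
      v <- pmin(pmax(v, ch$lower), ch$upper)
      out[[nm]] <- stem_series(v, start_time = target$start_time,
                               cadence_minutes = target$cadence_minutes,
                               channel = nm)
    }
  })
  out
}

#' Build a named benchmark scenario
#'
#' `"paper-small"` reproduces the published one-dimensional layout:
#' 2200 samples with a 200-sample gap in the middle so that 1000 observed
#' samples flank it on each side (train:test ratio 5:1).  `"paper-large"`
#' is the enlarged layout: 11000 samples, central gap of 1000 (5000 per
#' side).  `"custom"` takes explicit `total_length`/`gap_length` (gap
#' centred) and any simulator overrides.
#'
#' @param name One of `"paper-small"`, `"paper-large"`, `"custom"`.
#' @param seed Master seed for signal and covariates.
#' @param total_length,gap_length Layout for `"custom"`.
#' @param samples_per_day,noise_sd,... Overrides forwarded to
#'   [simulation_config()].
#' @return List with components `truth` (fully observed series), `gap`
#'   ([gap_spec()]), `masked` (truth with the gap removed) and
#'   `covariates` (list of aligned series).
#' @export
make_benchmark_scenario <- function(name = c("paper-small", "paper-large",
                                             "custom"),
                                    seed = 1L,
                                    total_length = NULL,
                                    gap_length = NULL,
                                    samples_per_day = 144L,
                                    ...) {
  name <- match.arg(name)
  layout <- switch(name,
    "paper-small" = c(total = 2200L, gap = 200L),
    "paper-large" = c(total = 11000L, gap = 1000L),
    "custom" = {
      if (is.null(total_length) || is.null(gap_length)) {
        stop("custom scenarios need total_length and gap_length",
             call. = FALSE)
      }
      c(total = as.integer(total_length), gap = as.integer(gap_length))
    })
  total <- layout[["total"]]; gl <- layout[["gap"]]
  if (gl >= total) stop("gap_length must be smaller than total_length",
                        call. = FALSE)
  n_days <- ceiling(total / samples_per_day)
  cfg <- simulation_config(n_days = n_days,
                           samples_per_day = samples_per_day,
                           seed = seed, ...)
  truth <- simulate_stem_moisture(cfg)
  truth$values <- truth$values[seq_len(total)]
  gap <- gap_spec(start = (total - gl) %/% 2L + 1L, length = gl)
  covs <- simulate_covariates(truth,
                              covariate_config(seed = seed + 1000L))
  list(truth = truth, gap = gap, masked = mask_gap(truth, gap),
       covariates = covs)
}
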