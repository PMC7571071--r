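# Data model for uniformly sampled single-channel sensor series.
#
# A stem_series stores the sampled values (NA marks missing samples), the
# timestamp of the first sample and the constant sampling cadence.  All
# computation is index based (1-based, index i corresponds to
# start_time + (i - 1) * cadence); timestamps are carried for I/O only and
# are never resampled.

# channels whose values are percentages and must lie in [0, 100]
.percent_channels <- c("stem_moisture", "air_humidity")

#' Construct a uniformly sampled sensor series
#'
#' @param values Numeric vector of sampled values; `NA` marks missing
#'   samples.  For percentage channels (`"stem_moisture"`,
#'   `"air_humidity"`) observed values must lie in \[0, 100\].
#' @param start_time `POSIXct` timestamp of the first sample.
#' @param cadence_minutes Sampling interval in minutes (strictly positive;
#'   default 10, i.e. 144 samples per day).
#' @param channel Channel name, e.g. `"stem_moisture"` (volumetric water
#'   content, percent).
#'
#' @return An object of class `stem_series`.
#' @export
stem_series <- function(values,
                        start_time = as.POSIXct("2017-06-01 00:00:00",
                                                tz = "UTC"),
                        cadence_minutes = 10,
                        channel = "stem_moisture") {
  values <- as.numeric(values)
  if (length(values) < 1L) {
    stop("a stem_series must contain at least one sample", call. = FALSE)
  }
  if (!is.numeric(cadence_minutes) || length(cadence_minutes) != 1L ||
      !is.finite(cadence_minutes) || cadence_minutes <= 0) {
    stop("cadence_minutes must be a single positive number", call. = FALSE)
  }
  if (!inherits(start_time, "POSIXct") || length(start_time) != 1L) {
    stop("start_time must be a single POSIXct timestamp", call. = FALSE)
  }
  obs <- values[!is.na(values)]
  if (channel %in% .percent_channels && length(obs) &&
      (min(obs) < 0 || max(obs) > 100)) {
    stop(sprintf("observed '%s' values must lie in [0, 100]", channel),
         call. = FALSE)
  }
  structure(
    list(values = values, start_time = start_time,
         cadence_minutes = cadence_minutes, channel = channel),
    class = "stem_series"
  )
}

#' @export
length.stem_series <- function(x) length(x$values)

#' Extract the sampled values of a series
#'
#' @param series A [stem_series()].
#' @return Numeric vector (with `NA` at missing indices).
#' @export
series_values <- function(series) {
  stopifnot(inherits(series, "stem_series"))
  series$values
}

#' Missing-sample mask of a series
#'
#' @param series A [stem_series()].
#' @return Logical vector, `TRUE` where the sample is missing.
#' @export
is_missing <- function(series) {
  stopifnot(inherits(series, "stem_series"))
  is.na(series$values)
}

#' Timestamps of every sample
#'
#' @param series A [stem_series()].
#' @return `POSIXct` vector of length `length(series)`.
#' @export
series_timestamps <- function(series) {
  stopifnot(inherits(series, "stem_series"))
  series$start_time + (seq_along(series$values) - 1) *
    series$cadence_minutes * 60
}

#' @export
print.stem_series <- function(x, ...) {
  n <- length(x$values)
  nm <- sum(is.na(x$values))
  cat(sprintf("<stem_series> channel '%s': %d samples @ %g min, %d missing\n",
              x$channel, n, x$cadence_minutes, nm))
  cat(sprintf("  start %s\n", format(x$start_time, "%Y-%m-%dT%H:%M:%S")))
  obs <- x$values[!is.na(x$values)]
  if (length(obs)) {
    cat(sprintf("  observed range [%.3f, %.3f]\n", min(obs), max(obs)))
  }
  invisible(x)
}

#' @export
as.data.frame.stem_series <- function(x, ...) {
  data.frame(timestamp = series_timestamps(x), value = x$values)
}

#' Describe a contiguous missing segment
#'
#' Indices are 1-based and inclusive: the gap covers
#' `start, ..., start + length - 1`.  (The study's prose range
#' "1001 to 1200" is therefore written `gap_spec(1001, 200)`.)
#'
#' @param start First gap index (1-based).
#' @param length Number of consecutive missing samples (positive).
#' @return An object of class `gap_spec`.
#' @export
gap_spec <- function(start, length) {
  if (!is.numeric(start) || length(start) != 1L || start < 1 ||
      start != round(start)) {
    stop("gap start must be a positive integer index", call. = FALSE)
  }
  if (!is.numeric(length) || base::length(length) != 1L || length < 1 ||
      length != round(length)) {
    stop("gap length must be a positive integer", call. = FALSE)
  }
  structure(list(start = as.integer(start), length = as.integer(length)),
            class = "gap_spec")
}

#' @export
print.gap_spec <- function(x, ...) {
  cat(sprintf("<gap_spec> indices %d..%d (length %d)\n",
              x$start, x$start + x$length - 1L, x$length))
  invisible(x)
}

gap_indices <- function(gap) seq.int(gap$start, gap$start + gap$length - 1L)

check_gap_bounds <- function(series, gap) {
  stopifnot(inherits(series, "stem_series"), inherits(gap, "gap_spec"))
  if (gap$start + gap$length - 1L > length(series$values)) {
    stop(sprintf("gap %d..%d exceeds series length %d",
                 gap$start, gap$start + gap$length - 1L,
                 length(series$values)), call. = FALSE)
  }
  invisible(TRUE)
}

#' Mask a contiguous segment as missing
#'
#' Returns a copy of `series` with the gap indices set to missing; the
#' input is never modified and all values outside the gap are untouched.
#'
#' @param series A fully observed (over the gap) [stem_series()].
#' @param gap A [gap_spec()] inside the series bounds.
#' @return A new `stem_series` with the gap missing.
#' @export
mask_gap <- function(series, gap) {
  check_gap_bounds(series, gap)
  idx <- gap_indices(gap)
  if (anyNA(series$values[idx])) {
    stop("series must be fully observed on the gap being masked",
         call. = FALSE)
  }
  out <- series
  out$values[idx] <- NA_real_
  out
}

#' Substitute values into a gap
#'
#' Writes `fill$filled` into the gap indices of `series`; every index
#' outside the gap is left untouched (conservation).
#'
#' @param series A [stem_series()] missing (or not) on the gap.
#' @param fill A [fill_result()] whose gap lies inside the series.
#' @return A new `stem_series` with the gap populated.
#' @export
apply_fill <- function(series, fill) {
  stopifnot(inherits(fill, "fill_result"))
  check_gap_bounds(series, fill$gap)
  out <- series
  out$values[gap_indices(fill$gap)] <- fill$filled
  out
}

#' Time-reverse a series
#'
#' Values and missing mask are reversed; index `i` maps to
#' `n - i + 1`.  Reversing twice is the identity.  `rev()` dispatches
#' here for `stem_series` objects.
#'
#' @param series A [stem_series()].
#' @return The reversed `stem_series`.
#' @export
reverse_series <- function(series) {
  stopifnot(inherits(series, "stem_series"))
  out <- series
  out$values <- rev(series$values)
  out
}

#' @export
rev.stem_series <- function(x) reverse_series(x)

#' Mirror a gap under time reversal
#'
#' @param gap A [gap_spec()].
#' @param n Series length.
#' @return The `gap_spec` covering the same samples in the reversed series.
#' @export
mirror_gap <- function(gap, n) {
  stopifnot(inherits(gap, "gap_spec"))
  gap_spec(n - (gap$start + gap$length - 1L) + 1L, gap$length)
}

# ---- CSV I/O ---------------------------------------------------------------

.ts_formats <- c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S")

parse_timestamps <- function(x) {
  for (fmt in .ts_formats) {
    out <- as.POSIXct(as.character(x), format = fmt, tz = "UTC")
    if (!anyNA(out)) return(out)
  }
  stop("could not parse timestamp column as ISO-8601", call. = FALSE)
}

#' Read a sensor series from CSV
#'
#' The dialect is a header row with a `timestamp` column (ISO-8601) and a
#' numeric `value` column; empty or `NaN` cells mark missing samples.  The
#' cadence is inferred from the first two timestamps and validated against
#' every consecutive pair; a non-uniform step is rejected naming the first
#' offending data row.
#'
#' @param path CSV file path.
#' @param column_map Named character vector mapping the roles `timestamp`
#'   and `value` to column names in the file.
#' @param cadence_minutes Cadence to assume when the file has a single row.
#' @param channel Channel name for the returned series.
#' @return A [stem_series()].
#' @export
read_series_csv <- function(path,
                            column_map = c(timestamp = "timestamp",
                                           value = "value"),
                            cadence_minutes = 10,
                            channel = "stem_moisture") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA", "NaN", "nan"))
  if (nrow(df) == 0L) stop("empty series file", call. = FALSE)
  for (role in c("timestamp", "value")) {
    if (!column_map[[role]] %in% names(df)) {
      stop(sprintf("column '%s' (role %s) not present in %s",
                   column_map[[role]], role, path), call. = FALSE)
    }
  }
  ts <- parse_timestamps(df[[column_map[["timestamp"]]]])
  vals <- suppressWarnings(as.numeric(df[[column_map[["value"]]]]))
  if (length(ts) > 1L) {
    steps <- as.numeric(diff(ts), units = "mins")
    cadence <- steps[1L]
    bad <- which(abs(steps - cadence) > 1e-6)
    if (length(bad)) {
      stop(sprintf(
        "non-uniform cadence: row %d is %g min after its predecessor (expected %g)",
        bad[1L] + 1L, steps[bad[1L]], cadence), call. = FALSE)
    }
  } else {
    cadence <- cadence_minutes
  }
  stem_series(vals, start_time = ts[1L], cadence_minutes = cadence,
              channel = channel)
}

#' Write a series (and optional covariates) to CSV
#'
#' Values are written with 15 significant digits so a read/write/read
#' round trip preserves them to numerical identity; missing samples are
#' written as empty cells.
#'
#' @param series A [stem_series()].
#' @param path Output CSV path.
#' @param covariates Optional named list of aligned [stem_series()]
#'   (e.g. `air_humidity`, `par`, `soil_temperature`) written as extra
#'   columns.
#' @param source Optional character vector (`"observed"`/`"filled"`)
#'   written as a `source` column.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path, covariates = NULL,
                             source = NULL) {
  stopifnot(inherits(series, "stem_series"))
  fmt_num <- function(x) ifelse(is.na(x), "", sprintf("%.15g", x))
  df <- data.frame(
    timestamp = format(series_timestamps(series), "%Y-%m-%dT%H:%M:%S",
                       tz = "UTC"),
    value = fmt_num(series$values),
    stringsAsFactors = FALSE
  )
  if (!is.null(covariates)) {
    for (nm in names(covariates)) {
      cov <- covariates[[nm]]
      stopifnot(inherits(cov, "stem_series"),
                length(cov) == length(series))
      df[[nm]] <- fmt_num(cov$values)
    }
  }
  if (!is.null(source)) {
    stopifnot(length(source) == length(series))
    df$source <- source
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- min-max normalization -------------------------------------------------

#' Fit a min-max normalization on a training segment
#'
#' Maps the observed values of the fitting segment affinely onto \[0, 1\]
#' (the minimal scaling compatible with sigmoid/tanh recurrent gates).
#' The transform is fit on training data only and shared by the forward
#' and reverse models of one experiment.
#'
#' @param series A [stem_series()].
#' @param segment Integer vector of indices to fit on (default: all
#'   observed indices).
#' @return An object of class `minmax_transform` with fields `min`, `max`.
#' @export
fit_minmax <- function(series, segment = NULL) {
  stopifnot(inherits(series, "stem_series"))
  vals <- series$values
  if (!is.null(segment)) vals <- vals[segment]
  vals <- vals[!is.na(vals)]
  if (length(unique(vals)) < 2L) {
    stop("min-max fit segment must contain at least two distinct observed values",
         call. = FALSE)
  }
  structure(list(min = min(vals), max = max(vals)),
            class = "minmax_transform")
}

#' Normalize values with a fitted transform
#' @param x Numeric vector (original units).
#' @param transform A [fit_minmax()] transform.
#' @return Numeric vector in normalized units.
#' @export
normalize_values <- function(x, transform) {
  stopifnot(inherits(transform, "minmax_transform"))
  (x - transform$min) / (transform$max - transform$min)
}

#' Invert a min-max transform
#' @param z Numeric vector in normalized units.
#' @param transform A [fit_minmax()] transform.
#' @return Numeric vector in original units.
#' @export
denormalize_values <- function(z, transform) {
  stopifnot(inherits(transform, "minmax_transform"))
  z * (transform$max - transform$min) + transform$min
}

#' Apply a fitted min-max transform to a whole series
#' @param series A [stem_series()].
#' @param transform A [fit_minmax()] transform.
#' @return A `stem_series` with normalized values (channel suffixed).
#' @export
normalize_series <- function(series, transform) {
  out <- series
  out$values <- normalize_values(series$values, transform)
  out$channel <- paste0(series$channel, "_normalized")
  out
}
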