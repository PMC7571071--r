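# Error-evaluation suite for fill results.
#
# Two unit conventions coexist and are kept explicit: maximum, minimum
# and MAPE are summaries of the per-point *relative* error
# e = |x_p - x| / x (reported x100), while MAE and RMSE are in the
# channel's own units (percentage points for stem moisture).  With truth
# around 50 % this makes MAE roughly MAPE/2, matching the reported error
# tables.  Threshold proportions count the share of points whose relative
# error is strictly below each threshold.

#' Relative one-point error
#'
#' `e = |predicted - truth| / truth`, dimensionless; defined only for
#' strictly positive truth (stem moisture is a positive-valued channel).
#'
#' @param predicted Numeric vector of filled values.
#' @param truth Numeric vector of true values, all > 0.
#' @return Numeric vector of relative errors.
#' @export
relative_error <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop("predicted and truth must have equal length", call. = FALSE)
  }
  if (any(!is.finite(truth)) || any(truth <= 0)) {
    stop("relative error is undefined for non-positive truth values",
         call. = FALSE)
  }
  abs(predicted - truth) / truth
}

#' Five-statistic error report with thresholded error distribution
#'
#' @param predicted,truth Equal-length numeric vectors (original units);
#'   truth strictly positive.
#' @param thresholds Relative-error thresholds for the distribution table
#'   (default 1 %..5 %).
#' @return An object of class `error_report`: `n`, `maximum`, `minimum`,
#'   `mape` (all on relative errors, x100), `mae`, `rmse` (channel
#'   units), and `threshold_proportions` (percent of points with relative
#'   error strictly below each threshold).
#' @export
error_report <- function(predicted, truth,
                         thresholds = c(0.01, 0.02, 0.03, 0.04, 0.05)) {
  if (length(predicted) != length(truth)) {
    stop("predicted and truth must have equal length", call. = FALSE)
  }
  stopifnot(length(truth) >= 1L)
  rel <- relative_error(predicted, truth)
  abs_err <- abs(predicted - truth)
  props <- vapply(thresholds, function(th) 100 * mean(rel < th),
                  numeric(1L))
  names(props) <- sprintf("%g", thresholds)
  structure(list(n = length(truth),
                 maximum = 100 * max(rel),
                 minimum = 100 * min(rel),
                 mae = mean(abs_err),
                 mape = 100 * mean(rel),
                 rmse = sqrt(mean(abs_err^2)),
                 threshold_proportions = props),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf(
    "<error_report> n=%d  max %.3f%%  min %.3f%%  MAE %.3f  MAPE %.3f%%  RMSE %.3f\n",
    x$n, x$maximum, x$minimum, x$mae, x$mape, x$rmse))
  cat("  relative error <",
      paste(sprintf("%s: %.1f%%", names(x$threshold_proportions),
                    x$threshold_proportions), collapse = "  "), "\n")
  invisible(x)
}

#' @export
as.data.frame.error_report <- function(x, ...) {
  df <- data.frame(n = x$n, maximum = x$maximum, minimum = x$minimum,
                   mae = x$mae, mape = x$mape, rmse = x$rmse)
  for (nm in names(x$threshold_proportions)) {
    df[[paste0("lt_", nm)]] <- x$threshold_proportions[[nm]]
  }
  df
}

#' Compare several fill results against the truth
#'
#' All results must cover the same gap; the truth series must be observed
#' on it.  Rows follow the input order (never sorted by error).
#'
#' @param results Named or unnamed list of [fill_result()]s over one gap.
#' @param truth A [stem_series()] observed on the gap.
#' @param thresholds Passed to [error_report()].
#' @return An object of class `method_comparison`: list with
#'   `statistics` (scheme, n, maximum, minimum, mae, mape, rmse) and
#'   `distribution` (scheme plus one column per threshold), both
#'   `data.frame`s aligned to the reported table layout.
#' @export
compare_methods <- function(results, truth,
                            thresholds = c(0.01, 0.02, 0.03, 0.04, 0.05)) {
  stopifnot(length(results) >= 1L, inherits(truth, "stem_series"))
  g0 <- results[[1L]]$gap
  for (r in results) {
    stopifnot(inherits(r, "fill_result"))
    if (r$gap$start != g0$start || r$gap$length != g0$length) {
      stop("all fill results must cover the same gap", call. = FALSE)
    }
  }
  check_gap_bounds(truth, g0)
  tv <- truth$values[gap_indices(g0)]
  if (anyNA(tv)) stop("truth series must be observed on the gap",
                      call. = FALSE)
  labels <- names(results)
  if (is.null(labels)) labels <- vapply(results, `[[`, character(1L),
                                        "scheme")
  reports <- lapply(results, function(r) {
    error_report(r$filled, tv, thresholds)
  })
  stat <- do.call(rbind, lapply(seq_along(reports), function(j) {
    rp <- reports[[j]]
    data.frame(scheme = labels[j], n = rp$n, maximum = rp$maximum,
               minimum = rp$minimum, mae = rp$mae, mape = rp$mape,
               rmse = rp$rmse)
  }))
  dist <- do.call(rbind, lapply(seq_along(reports), function(j) {
    rp <- reports[[j]]
    row <- data.frame(scheme = labels[j])
    for (nm in names(rp$threshold_proportions)) {
      row[[paste0("lt_", nm)]] <- rp$threshold_proportions[[nm]]
    }
    row
  }))
  structure(list(statistics = stat, distribution = dist,
                 reports = stats::setNames(reports, labels)),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("Error statistics (max/min/MAPE relative x100; MAE/RMSE in channel units):\n")
  print(x$statistics, row.names = FALSE)
  cat("\nShare of points with relative error below threshold (%):\n")
  print(x$distribution, row.names = FALSE)
  invisible(x)
}

report_to_json <- function(report, scheme = NULL, provenance = NULL,
                           path = NULL) {
  obj <- list(scheme = scheme, n = report$n, maximum = report$maximum,
              minimum = report$minimum, mae = report$mae,
              mape = report$mape, rmse = report$rmse,
              thresholds = as.list(report$threshold_proportions),
              provenance = provenance)
  if (is.null(path)) return(obj)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
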