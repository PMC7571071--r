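test_that("interpolation recovers polynomial truths through a gap", {
  # linear truth: both spline and pchip are exact
  lin <- stem_series(40 + 0.02 * (0:499), channel = "other")
  gap <- gap_spec(201L, 100L)
  masked <- mask_gap(lin, gap)
  truth_gap <- lin$values[gap_indices_of(gap)]
  for (m in c("spline", "pchip")) {
    res <- fill_interpolation(masked, gap, m, context_length = 100L)
    expect_equal(res$filled, truth_gap, tolerance = 1e-9)
    expect_identical(res$scheme, paste0("baseline:", m))
  }

  # quadratic truth: the cubic spline stays exact away from the
  # natural boundary
  x <- 0:499
  quad <- stem_series(50 + 1e-5 * (x - 250)^2, channel = "other")
  masked_q <- mask_gap(quad, gap)
  res_q <- fill_interpolation(masked_q, gap, "spline",
                              context_length = 150L)
  expect_equal(res_q$filled, quad$values[gap_indices_of(gap)],
               tolerance = 1e-6)
})

test_that("interpolation joins the flanks continuously and checks preconditions", {
  scen <- scaled_scenario(seed = 6L)
  res <- fill_interpolation(scen$masked, scen$gap, "spline",
                            context_length = 200L)
  v <- scen$masked$values
  g <- scen$gap
  expect_lt(abs(res$filled[1L] - v[g$start - 1L]),
            abs(v[g$start - 1L] - v[g$start - 2L]) + 0.5)
  # exact continuity at the knots themselves: interpolant passes through
  # the flanking observed points
  fl_first <- fill_interpolation(scen$masked, gap_spec(g$start, 1L) , "spline",
                                 context_length = 200L)
  expect_true(is.finite(fl_first$filled))

  tiny <- mask_gap(stem_series(c(50, 51, 52, 53, 50, 51, 52)),
                   gap_spec(4L, 1L))
  expect_error(fill_interpolation(tiny, gap_spec(4L, 1L), "spline"),
               "4 observed")
})

test_that("pchip preserves monotone flanks where the spline may overshoot", {
  # monotone data with a sharp bend right at the gap
  vals <- c(seq(43, 50, length.out = 30), rep(50.5, 6),
            seq(51, 57, length.out = 30))
  s <- stem_series(vals, channel = "other")
  gap <- gap_spec(31L, 6L)
  masked <- mask_gap(s, gap)
  pchip <- fill_interpolation(masked, gap, "pchip", context_length = 30L)
  lo <- masked$values[30L]; hi <- masked$values[37L]
  expect_true(all(pchip$filled >= lo - 1e-9 & pchip$filled <= hi + 1e-9))
  expect_true(all(diff(pchip$filled) >= -1e-9))
})

test_that("forecast baselines behave analytically on simple processes", {
  # near-constant series: forecast returns the constant
  set.seed(8)
  const <- stem_series(rep(50, 300) + rnorm(300, 0, 1e-8))
  gap <- gap_spec(251L, 30L)
  masked <- mask_gap(const, gap)
  # the near-degenerate ML fit may warn about optim convergence; the
  # contract is that it fills, not that optim is happy
  res <- suppressWarnings(
    fill_forecast(masked, gap, "arma",
                  baseline_config("arma", arma_order = c(1L, 0L),
                                  context_length = 250L)))
  expect_equal(res$filled, rep(50, 30L), tolerance = 1e-6)

  # seeded AR(1): auto order picks a small p and the forecast decays
  # toward the series mean
  set.seed(9)
  ar1 <- stats::arima.sim(list(ar = 0.8), n = 1000L, sd = 0.5)
  s <- stem_series(as.numeric(50 + ar1))
  gap2 <- gap_spec(901L, 100L)
  masked2 <- mask_gap(s, gap2)
  res2 <- fill_forecast(masked2, gap2, "arma",
                        baseline_config("arma", max_order = c(2L, 0L, 2L),
                                        context_length = 900L))
  expect_true(res2$provenance$order[1L] %in% 1:2)
  mu <- mean(s$values[1:900])
  dev <- abs(res2$filled - mu)
  expect_lt(dev[100L], dev[1L])  # geometric decay toward the mean

  # linear trend: d = 1 continues the slope
  trend <- stem_series(40 + 0.01 * (0:599) + rnorm(600, 0, 0.01),
                       channel = "other")
  gap3 <- gap_spec(501L, 100L)
  masked3 <- mask_gap(trend, gap3)
  res3 <- suppressWarnings(
    fill_forecast(masked3, gap3, "arima",
                  baseline_config("arima", arima_order = c(1L, 1L, 1L),
                                  context_length = 500L)))
  slope <- mean(diff(res3$filled))
  expect_lt(abs(slope - 0.01) / 0.01, 0.2)
})

test_that("the gap-length sweep reports one row per feasible length", {
  scen <- scaled_scenario(seed = 7L, total_length = 1440L,
                          gap_length = 96L)
  sweep <- gap_length_sweep(scen$truth,
                            lengths = c(10L, 20L, 30L, 40L, 50L, 100L,
                                        150L, 200L),
                            method = "spline")
  expect_identical(nrow(sweep), 8L)
  expect_identical(sweep$length, c(10L, 20L, 30L, 40L, 50L, 100L, 150L,
                                   200L))
  # the longer the filled sequence, the worse the interpolation fit
  expect_gt(sweep$mape[sweep$length == 200L],
            sweep$mape[sweep$length == 10L])

  tiny <- gap_length_sweep(scen$truth, lengths = c(1L),
                           method = "spline")
  expect_lt(tiny$mape, 1)

  expect_warning(
    skipped <- gap_length_sweep(scen$truth, lengths = c(10L, 5000L),
                                method = "spline"),
    "infeasible")
  expect_identical(nrow(skipped), 1L)
  expect_identical(attr(skipped, "skipped"), 5000L)
})
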