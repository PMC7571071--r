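test_that("a constant-output oracle fills the gap with that constant", {
  s <- sinusoid_series(600L, period = 144L)
  gap <- gap_spec(301L, 100L)
  masked <- mask_gap(s, gap)
  tf <- fit_minmax(s, 1:300)
  orc <- oracle_model(function(w) 0.25, window_length = 200L,
                      transform = tf)
  res <- fill_directional(orc, masked, gap, "forward")
  expect_identical(res$scheme, "forward")
  expect_length(res$filled, 100L)
  # closed form of the recursion with a constant predictor
  expect_equal(res$filled, rep(denormalize_values(0.25, tf), 100L))
})

test_that("a perfect one-step oracle reproduces a noiseless sinusoid", {
  s <- sinusoid_series(2200L, period = 144L)
  gap <- gap_spec(1001L, 200L)
  masked <- mask_gap(s, gap)
  tf <- fit_minmax(s, c(1:1000, 1201:2200))
  truth_norm <- normalize_values(s$values, tf)

  fwd_oracle <- oracle_model(function(w, step) {
    truth_norm[gap$start + step - 1L]
  }, window_length = 200L, transform = tf)
  rev_truth_norm <- rev(truth_norm)
  rgap <- mirror_gap(gap, 2200L)
  rev_oracle <- oracle_model(function(w, step) {
    rev_truth_norm[rgap$start + step - 1L]
  }, window_length = 200L, transform = tf)

  truth_gap <- s$values[1001:1200]
  f <- fill_directional(fwd_oracle, masked, gap, "forward")
  r <- fill_directional(rev_oracle, masked, gap, "reverse")
  expect_equal(f$filled, truth_gap, tolerance = 1e-6)
  expect_equal(r$filled, truth_gap, tolerance = 1e-6)
  for (combined in list(combine_equal(f, r), combine_decreasing(f, r),
                        combine_segmented(f, r))) {
    expect_equal(combined$filled, truth_gap, tolerance = 1e-6)
  }
})

test_that("directional filling validates its run-up and window", {
  s <- sinusoid_series(300L)
  gap <- gap_spec(150L, 20L)
  masked <- mask_gap(s, gap)
  orc <- oracle_model(function(w) 0.5, window_length = 200L)
  expect_error(fill_directional(orc, masked, gap), "preceding the gap")
  orc2 <- oracle_model(function(w) 0.5, window_length = 100L)
  expect_silent(fill_directional(orc2, masked, gap))
  # reverse needs the run-up after the gap
  gap_tail <- gap_spec(250L, 51L)
  masked2 <- mask_gap(s, gap_tail)
  expect_error(fill_directional(orc2, masked2, gap_tail, "reverse"),
               "preceding the gap")
})

test_that("equal-weight fusion is the arithmetic mean with (0.5, 0.5) weights", {
  gap <- gap_spec(10L, 3L)
  f <- fill_result("forward", gap, c(50, 50, 52))
  r <- fill_result("reverse", gap, c(50, 52, 54))
  z <- combine_equal(f, r)
  expect_equal(z$filled, c(50, 51, 53))
  expect_true(all(z$weights == 0.5))
  expect_identical(z$scheme, "bidir_equal")
  # symmetric in the values
  swapped <- combine_equal(fill_result("forward", gap, r$filled),
                           fill_result("reverse", gap, f$filled))
  expect_equal(swapped$filled, z$filled)

  other <- fill_result("reverse", gap_spec(11L, 3L), c(1, 2, 3))
  expect_error(combine_equal(f, other), "different gaps")
  expect_error(combine_equal(r, f), "forward")
})

test_that("decreasing-weight fusion follows the 0.05-gradient staircase", {
  L <- 200L
  gap <- gap_spec(1001L, L)
  f <- fill_result("forward", gap, rep(1, L))
  r <- fill_result("reverse", gap, rep(0, L))
  z <- combine_decreasing(f, r)
  w <- z$weights
  # endpoints (1.00, 0.00) and (0.05, 0.95)
  expect_equal(unname(w[1L, ]), c(1, 0))
  expect_equal(unname(w[L, ]), c(0.05, 0.95))
  expect_equal(z$filled[1L], 1)
  # weights sum to one everywhere, descend in 0.05 steps, 20 levels of 10
  expect_equal(rowSums(w), rep(1, L), tolerance = 1e-12)
  expect_identical(length(unique(w[, 1L])), 20L)
  expect_identical(as.integer(table(w[, 1L]))[1L], 10L)
  expect_true(all(diff(w[, 1L]) <= 0))

  # remainder indices go to the earliest blocks
  gap23 <- gap_spec(1L, 23L)
  z23 <- combine_decreasing(fill_result("forward", gap23, rep(1, 23)),
                            fill_result("reverse", gap23, rep(0, 23)))
  sizes <- as.integer(table(factor(z23$weights[, 1L],
                                   levels = rev(sort(unique(z23$weights[, 1L]))))))
  expect_identical(sizes, c(2L, 2L, 2L, rep(1L, 17L)))

  expect_error(combine_decreasing(f, r, gradient = 0.07), "evenly")
})

test_that("segmented fusion splits at the ceiling midpoint", {
  gap <- gap_spec(1001L, 200L)
  f <- fill_result("forward", gap, rep(1, 200))
  r <- fill_result("reverse", gap, rep(2, 200))
  z <- combine_segmented(f, r)
  expect_equal(z$filled, c(rep(1, 100), rep(2, 100)))

  gap1 <- gap_spec(5L, 1L)
  z1 <- combine_segmented(fill_result("forward", gap1, 7),
                          fill_result("reverse", gap1, 9))
  expect_equal(z1$filled, 7)  # single index comes from the forward fill

  same <- combine_segmented(f, fill_result("reverse", gap, rep(1, 200)))
  expect_equal(same$filled, f$filled)
})

test_that("fused values are convex combinations of the directional fills", {
  set.seed(11)
  gap <- gap_spec(1L, 57L)
  f <- fill_result("forward", gap, runif(57, 43, 57))
  r <- fill_result("reverse", gap, runif(57, 43, 57))
  for (z in list(combine_equal(f, r), combine_decreasing(f, r))) {
    expect_true(all(z$filled >= pmin(f$filled, r$filled) - 1e-12))
    expect_true(all(z$filled <= pmax(f$filled, r$filled) + 1e-12))
  }
})

test_that("end-to-end bidirectional fill trains both sides and conserves data", {
  scen <- scaled_scenario(seed = 2L)
  res <- fill_bidirectional(scaled_lstm_arch(), scen$masked, scen$gap,
                            scheme = "bidir_equal",
                            train_config = list(epochs = 3L), seed = 2L)
  expect_identical(res$scheme, "bidir_equal")
  expect_length(res$filled, scen$gap$length)
  expect_identical(res$components$forward$scheme, "forward")
  expect_identical(res$components$reverse$scheme, "reverse")
  expect_equal(res$filled,
               0.5 * res$components$forward$filled +
                 0.5 * res$components$reverse$filled)

  filled <- apply_fill(scen$masked, res)
  idx <- gap_indices_of(scen$gap)
  expect_identical(filled$values[-idx], scen$masked$values[-idx])
  expect_false(anyNA(filled$values))

  expect_error(fill_bidirectional(scaled_lstm_arch(), scen$masked,
                                  scen$gap, scheme = "nonsense"),
               "unknown scheme")
  # one-sided shortage is rejected naming the deficient side
  short <- scaled_scenario(seed = 2L, total_length = 600L,
                           gap_length = 96L)
  tail_gap <- gap_spec(580L, 21L)
  masked2 <- mask_gap(short$truth, tail_gap)
  expect_error(fill_bidirectional(scaled_lstm_arch(), masked2, tail_gap,
                                  train_config = list(epochs = 1L)),
               "post-gap side")
})
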