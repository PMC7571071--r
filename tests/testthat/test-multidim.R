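make_linear_frame <- function(n = 700L, seed = 31L) {
  # target is a known noiseless linear map of the covariates, so a
  # converged model must reproduce it almost exactly
  scen <- scaled_scenario(seed = seed, total_length = n,
                          gap_length = 48L)
  covs <- scen$covariates
  z <- function(s) as.numeric(scale(s$values))
  target_vals <- 50 + 2 * z(covs$air_humidity) - 1.5 * z(covs$par) +
    1 * z(covs$soil_temperature)
  target <- stem_series(pmin(pmax(target_vals, 0), 100),
                        cadence_minutes = covs$par$cadence_minutes)
  covariate_frame(target, covs)
}

test_that("covariate frames validate alignment and channel subsets", {
  frame <- make_linear_frame()
  expect_identical(frame$input_subset,
                   c("air_humidity", "par", "soil_temperature"))
  f1 <- covariate_frame(frame$target, frame$covariates,
                        input_subset = "PAR")
  expect_identical(f1$input_subset, "par")
  expect_error(covariate_frame(frame$target, frame$covariates,
                               input_subset = character(0)), "at least one")
  expect_error(covariate_frame(frame$target, frame$covariates,
                               input_subset = "XYZ"), "unknown")
  short <- stem_series(frame$covariates$par$values[1:10], channel = "par")
  expect_error(covariate_frame(frame$target, list(par = short), "PAR"),
               "aligned")
})

test_that("the architecture builder matches the published covariate stacks", {
  a3d <- covariate_architecture(3L, 50L, keep_prob = 0.8,
                                input_features = 3L)
  kinds <- vapply(a3d$layers, `[[`, character(1L), "kind")
  expect_identical(kinds, c("lstm", "dropout", "lstm", "lstm", "dense"))
  expect_equal(a3d$layers[[2L]]$rate, 0.2)  # keep-probability 0.8
  expect_identical(a3d$input_features, 3L)
  a1 <- covariate_architecture(3L, 50L, keep_prob = 0.8,
                               input_features = 1L)
  expect_identical(a1$input_features, 1L)
  a2 <- covariate_architecture(2L, 50L, keep_prob = NULL,
                               input_features = 3L)
  expect_identical(vapply(a2$layers, `[[`, character(1L), "kind"),
                   c("lstm", "lstm", "dense"))
})

test_that("a deterministic linear target is learned to low error", {
  frame <- make_linear_frame()
  arch <- covariate_architecture(2L, 16L, keep_prob = NULL,
                                 input_features = 3L,
                                 window_length = 24L)
  model <- train_covariate_model(frame, arch, train_range = 1:500,
                                 epochs = 40L, seed = 5L,
                                 learning_rate = 0.01)
  gap <- gap_spec(521L, 150L)
  res <- fill_from_covariates(model, frame, gap)
  truth <- frame$target$values[gap_indices_of(gap)]
  expect_lt(error_report(res$filled, truth)$mape, 1)
})

test_that("covariate fills are pointwise, order-independent and unbounded", {
  frame <- make_linear_frame()
  arch <- covariate_architecture(2L, 8L, keep_prob = 0.8,
                                 input_features = 3L,
                                 window_length = 24L)
  model <- train_covariate_model(frame, arch, train_range = 1:400,
                                 epochs = 2L, seed = 1L)
  gap <- gap_spec(401L, 300L)
  res <- fill_from_covariates(model, frame, gap)
  expect_length(res$filled, 300L)

  # a sub-gap fill equals the corresponding slice: no recursion state
  sub <- gap_spec(551L, 50L)
  res_sub <- fill_from_covariates(model, frame, sub)
  expect_equal(res_sub$filled, res$filled[151:200])
  single <- fill_from_covariates(model, frame, gap_spec(600L, 1L))
  expect_equal(single$filled, res$filled[200L])

  # missing covariate inside the fill window is rejected naming the index
  broken <- frame
  broken$covariates$par$values[450L] <- NA
  expect_error(fill_from_covariates(model, broken, gap),
               "missing at index 450")
  # subset mismatch between model and frame
  f1 <- covariate_frame(frame$target, frame$covariates, "PAR")
  expect_error(fill_from_covariates(model, f1, gap), "subset")
})

test_that("input-subset comparison ranks a PAR-driven target correctly", {
  scen <- scaled_scenario(seed = 13L, total_length = 700L,
                          gap_length = 48L)
  covs <- scen$covariates
  # target driven by PAR alone (plus the frame's other channels as noise)
  z <- as.numeric(scale(covs$par$values))
  target <- stem_series(pmin(pmax(50 + 3 * z, 0), 100),
                        cadence_minutes = covs$par$cadence_minutes)
  frame <- covariate_frame(target, covs)
  gap <- gap_spec(551L, 100L)
  tab <- compare_input_subsets(frame, gap,
                               subsets = list("PAR", "ST"),
                               units = 12L, n_layers = 2L,
                               keep_prob = NULL, window_length = 24L,
                               epochs = 25L, seed = 3L,
                               learning_rate = 0.01)
  expect_identical(nrow(tab), 2L)
  expect_identical(tab$subset, c("PAR", "ST"))
  expect_lt(tab$mape[1L], tab$mape[2L])

  # duplicated subsets are reproducible under the shared seed
  tab2 <- compare_input_subsets(frame, gap,
                                subsets = list("PAR", "PAR"),
                                units = 8L, n_layers = 2L,
                                keep_prob = NULL, window_length = 24L,
                                epochs = 2L, seed = 3L)
  expect_equal(tab2$mape[1L], tab2$mape[2L])
})

test_that("the architecture harness reproduces the three-row comparison", {
  frame <- make_linear_frame(n = 500L)
  gap <- gap_spec(421L, 60L)
  tab <- compare_architectures(
    frame, gap,
    archs = list(
      "2*50" = covariate_architecture(2L, 10L, NULL, 3L, 24L),
      "3*50" = covariate_architecture(3L, 10L, NULL, 3L, 24L),
      "3*50*0.8" = covariate_architecture(3L, 10L, 0.8, 3L, 24L)),
    epochs = 2L, seed = 1L)
  expect_identical(nrow(tab), 3L)
  expect_identical(tab$architecture, c("2*50", "3*50", "3*50*0.8"))
  expect_true(all(is.finite(tab$mape)))
})
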