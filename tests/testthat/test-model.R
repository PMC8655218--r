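test_that("fully connected layer matches its closed forms and per-neuron oracle", {
  l <- c(1.5, -2, 0.25)
  p_id <- list(W = diag(3), b = rep(0, 3), activation = "identity", dropout = 0)
  expect_equal(fc_layer(l, p_id), l)

  p_b <- list(W = matrix(rnorm(6), 3, 2), b = c(7, -1), activation = "identity",
              dropout = 0)
  expect_equal(fc_layer(c(0, 0, 0), p_b), p_b$b)

  set.seed(31)
  for (rep in 1:10) {
    d_in <- sample(2:8, 1); d_out <- sample(1:6, 1)
    x <- rnorm(d_in)
    p <- list(W = matrix(rnorm(d_in * d_out), d_in, d_out), b = rnorm(d_out),
              activation = "identity", dropout = 0)
    oracle <- vapply(seq_len(d_out),
                     function(j) sum(x * p$W[, j]) + p$b[j], numeric(1))
    expect_lt(max(abs(fc_layer(x, p) - oracle)), 1e-9)
  }
  expect_error(fc_layer(c(1, 2), p_id), class = "polygcn_shape_error")
})

test_that("a quick fit predicts deterministically and within tolerance in-distribution", {
  ds <- tiny_clean_dataset(seed = 7, n_units = 3)
  sp <- split_dataset(ds, seed = 2)
  fit <- train(sp$train, sp$validation, tiny_model_config(seed = 4, epochs = 40))
  model <- fit$model

  form <- list(dp = 150, conc = 7.5, surfactant = 0)
  y1 <- predict_size(MMA_SMILES, form, model)
  y2 <- predict_size(MMA_SMILES, form, model)
  expect_identical(y1, y2)  # evaluation mode is bit-deterministic
  expect_true(is.finite(y1) && y1 > 0)

  # in-distribution prediction close to the generator's ground truth
  truth <- ground_truth_size(MMA_SMILES, form)
  expect_lt(abs(y1 - truth) / truth, 0.15)

  # same molecular graph written as a different SMILES: same prediction
  alt <- "C(*)(C(=O)OC)(C)C*"
  expect_equal(predict_size(alt, form, model), y1, tolerance = 1e-9)

  # unfitted model and invalid inputs refuse politely
  raw_model <- polygcn:::new_size_model(tiny_model_config())
  expect_error(predict_size(MMA_SMILES, form, raw_model),
               class = "polygcn_state_error")
  expect_error(predict_size(MMA_SMILES, list(dp = -5, conc = 1, surfactant = 0), model),
               class = "polygcn_validation_error")

  # finite predictions over an extreme Dp sweep
  for (dp in c(1, 100, 1e4)) {
    expect_true(is.finite(predict_size(MMA_SMILES,
                                       list(dp = dp, conc = 10, surfactant = 0), model)))
  }
})

test_that("input standardization round-trips and uses training statistics", {
  scaling <- list(x_mean = c(100, 10, 0.001), x_sd = c(50, 8, 0.002), y_scale = 1)
  X <- cbind(dp = c(60, 400), conc = c(1, 30), surfactant = c(0, 0.0025))
  Z <- polygcn:::standardize_numeric(X, scaling)
  expect_lt(max(abs(polygcn:::destandardize_numeric(Z, scaling) - X)), 1e-12)
})

test_that("prediction surface agrees with the point predictor and exports long CSV", {
  ds <- tiny_clean_dataset(seed = 3, n_units = 2)
  sp <- split_dataset(ds, seed = 2)
  fit <- train(sp$train, sp$validation, tiny_model_config(seed = 8, epochs = 5))

  surf <- prediction_surface(MMA_SMILES, fit$model, dp_range = c(50, 200),
                             conc_range = c(1, 30), grid_steps = 2,
                             surfactant_concentration = 0)
  expect_identical(nrow(surf), 4L)
  expect_identical(names(surf), c("dp", "conc", "predicted_size_nm"))
  expect_identical(surf$dp, c(50, 50, 200, 200))  # row-major: Dp outer
  for (r in seq_len(nrow(surf))) {
    # equal to the point predictor up to BLAS batch-vs-single rounding
    expect_equal(surf$predicted_size_nm[r],
                 predict_size(MMA_SMILES,
                              list(dp = surf$dp[r], conc = surf$conc[r],
                                   surfactant = 0), fit$model),
                 tolerance = 1e-12)
  }
  path <- tempfile(fileext = ".csv")
  write_surface_csv(surf, path)
  expect_equal(read.csv(path), surf, tolerance = 1e-12)

  expect_error(prediction_surface(MMA_SMILES, fit$model, dp_range = c(100, 10)),
               class = "polygcn_validation_error")
  expect_error(prediction_surface(MMA_SMILES, fit$model, conc_range = c(0, 30)),
               class = "polygcn_validation_error")
})

test_that("model bundles reload to a bit-identical predictor", {
  ds <- tiny_clean_dataset(seed = 13, n_units = 2)
  sp <- split_dataset(ds, seed = 2)
  fit <- train(sp$train, sp$validation, tiny_model_config(seed = 6, epochs = 5))
  path <- tempfile(fileext = ".json")
  save_model(fit$model, path)
  reloaded <- load_model(path)
  expect_true(reloaded$fitted)
  form <- list(dp = 77, conc = 3, surfactant = 0.0025)
  expect_identical(predict_size(MMA_SMILES, form, reloaded),
                   predict_size(MMA_SMILES, form, fit$model))
})
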