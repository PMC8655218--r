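test_that("the network memorizes a single repeated record (capacity sanity)", {
  rec <- data.frame(polymer = "mma", smiles = MMA_SMILES, dp = 150, conc = 7.5,
                    surfactant = 0, size_nm = 180)
  ds <- formulation_dataset(rec[rep(1, 12), ])
  cfg <- model_config(conv_dims = c(16L, 16L), fc_dims = c(16L),
                      epochs = 60, batch_size = 12, seed = 2, dropout = 0)
  fit <- train(ds, ds, cfg)
  expect_lt(fit$report$train_mape, 1)
  expect_identical(nrow(fit$report$history), 60L)
  expect_true(all(c("train_mape", "train_rmse", "val_mape", "val_rmse")
                  %in% names(fit$report$history)))
})

test_that("training is reproducible given the seed", {
  ds <- tiny_clean_dataset(seed = 5, n_units = 2, n = 120)
  sp <- split_dataset(ds, seed = 1)
  cfg <- tiny_model_config(seed = 11, epochs = 4)
  f1 <- train(sp$train, sp$validation, cfg)
  f2 <- train(sp$train, sp$validation, cfg)
  expect_identical(f1$report$history, f2$report$history)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("dropout makes training-mode predictions noisier than evaluation mode", {
  ds <- tiny_clean_dataset(seed = 9, n_units = 2, n = 200)
  sp <- split_dataset(ds, seed = 1)
  fit <- train(sp$train, sp$validation, tiny_model_config(seed = 3, epochs = 30))
  model <- fit$model
  eval_mape <- fit$report$train_mape
  # forward passes with dropout active on the converged parameters
  tr <- as.data.frame(sp$train)
  X <- polygcn:::numeric_inputs(tr)
  Z <- polygcn:::standardize_numeric(X, model$scaling)
  set.seed(99)
  fp_dim <- 2L * tail(tiny_model_config()$conv_dims, 1)
  train_mapes <- replicate(10, {
    fps <- matrix(0, nrow(tr), fp_dim)
    for (s in unique(tr$smiles)) {
      entry <- polygcn:::model_graph(model, s)
      cc <- polygcn:::conv_forward_train(model$params$conv, model$params$gate,
                                         entry$A_hat, entry$graph$H0, TRUE)
      fps[tr$smiles == s, ] <- matrix(cc$fp, sum(tr$smiles == s), fp_dim,
                                      byrow = TRUE)
    }
    fc <- polygcn:::fc_forward_train(model$params$fc, cbind(fps, Z), TRUE)
    mape(fc$out * model$scaling$y_scale, tr$size_nm)
  })
  expect_gt(mean(train_mapes), eval_mape)
})

test_that("leave-one-polymer-out removes every held-out record from training", {
  ds <- tiny_clean_dataset(seed = 15, n_units = 3, n = 300)
  cfg <- tiny_model_config(seed = 5, epochs = 8)
  held_name <- "ethyl methacrylate"
  reports <- leave_one_polymer_out(ds, holdouts = list(held_name), cfg)
  r <- reports[[1]]
  expect_s3_class(r, "train_report")
  expect_identical(r$held_out, held_name)
  expect_identical(r$n_test, sum(ds$polymer == held_name))
  for (f in c("mape_test", "mape_test_without_worst", "mape_all",
              "mape_all_without_worst", "worst_group", "train_mape")) {
    expect_false(is.null(r[[f]]))
  }
  expect_true(is.finite(r$mape_test))
  # excluding the worst group can only help when it is worse than average
  expect_lte(r$mape_test_without_worst, r$mape_test + 1e-9)

  expect_error(leave_one_polymer_out(ds, holdouts = list("nonexistent polymer"), cfg),
               class = "polygcn_validation_error")
  expect_error(leave_one_polymer_out(ds, holdouts = list(unique(ds$polymer)), cfg),
               class = "polygcn_validation_error")
})

test_that("joint two-polymer holdouts produce a single combined report", {
  ds <- tiny_clean_dataset(seed = 16, n_units = 4, n = 360)
  pair <- c("propyl methacrylate", "butyl methacrylate")
  reports <- leave_one_polymer_out(ds, holdouts = list(pair),
                                   tiny_model_config(seed = 6, epochs = 8))
  expect_length(reports, 1)
  r <- reports[[1]]
  expect_identical(r$held_out, pair)
  expect_identical(r$n_test, sum(ds$polymer %in% pair))
})

test_that("training reports export as CSV history plus JSON summary", {
  ds <- tiny_clean_dataset(seed = 17, n_units = 2, n = 100)
  sp <- split_dataset(ds, seed = 1)
  fit <- train(sp$train, sp$validation, tiny_model_config(seed = 2, epochs = 3))
  csvp <- tempfile(fileext = ".csv"); jsonp <- tempfile(fileext = ".json")
  write_train_report(fit$report, csv_path = csvp, json_path = jsonp)
  hist <- read.csv(csvp)
  expect_identical(nrow(hist), 3L)
  js <- jsonlite::fromJSON(jsonp)
  expect_equal(js$val_mape, fit$report$val_mape, tolerance = 1e-12)
})
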