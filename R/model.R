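#' Model configuration for the fused GCN + FC size regressor
#'
#' The polymer's cyclic graph is convolved through `conv_dims` layers, the
#' pooled fingerprint (length `2 * tail(conv_dims, 1)`) is concatenated
#' with the standardized numeric inputs (degree of polymerization, polymer
#' concentration, surfactant concentration) and regressed through fully
#' connected hidden layers `fc_dims` down to a single predicted diameter.
#'
#' @param spec An [atom_feature_spec].
#' @param conv_dims Output widths of the graph-convolution layers
#'   (default four layers of 64).
#' @param fc_dims Hidden widths of the fully connected part
#'   (default 128, 64, 32; the output layer of width 1 is implicit).
#' @param ring_size Repeat units in the cyclic representation (default 10).
#' @param dropout Dropout rate for every convolutional and hidden fully
#'   connected layer, training mode only (default 0.1).
#' @param activation Hidden-layer activation (default `"relu"`; the output
#'   head is linear).
#' @param sum_mode Readout weighted-sum mode, see [pool_readout()].
#' @param learning_rate,batch_size,epochs Adaptive-moment (Adam) training
#'   schedule defaults: 1e-3, 64, 300.
#' @param seed RNG seed controlling initialization, batch shuffling and
#'   dropout; training is fully reproducible given the seed.
#' @param verbose Print a metrics line every `verbose` epochs (0 = silent).
#' @return A `model_config` list.
#' @export
model_config <- function(spec = atom_feature_spec(),
                         conv_dims = rep(64L, 4),
                         fc_dims = c(128L, 64L, 32L),
                         ring_size = 10L,
                         dropout = 0.1,
                         activation = "relu",
                         sum_mode = "gated",
                         learning_rate = 1e-3,
                         batch_size = 64L,
                         epochs = 300L,
                         seed = 1L,
                         verbose = 0L) {
  stopifnot(inherits(spec, "atom_feature_spec"))
  check_scalar_number(ring_size, "ring_size", lower = 3)
  check_scalar_number(dropout, "dropout", 0, 1 - 1e-9)
  check_scalar_number(learning_rate, "learning_rate", lower = 1e-12)
  check_scalar_number(epochs, "epochs", lower = 1)
  structure(list(
    spec = spec, conv_dims = as.integer(conv_dims), fc_dims = as.integer(fc_dims),
    ring_size = as.integer(ring_size), dropout = dropout, activation = activation,
    sum_mode = sum_mode, learning_rate = learning_rate,
    batch_size = as.integer(batch_size), epochs = as.integer(epochs),
    seed = as.integer(seed), verbose = as.integer(verbose)
  ), class = "model_config")
}

# fresh, unfitted model with seeded parameter initialization
new_size_model <- function(config) {
  n_numeric <- 3L  # Dp, polymer conc, surfactant conc
  fp_dim <- 2L * utils::tail(config$conv_dims, 1)
  params <- with_seed(config$seed, {
    p <- init_gcn_stack(config$spec$total_dim, config$conv_dims,
                        config$activation, config$dropout)
    p$fc <- list()
    d_prev <- fp_dim + n_numeric
    for (i in seq_along(config$fc_dims)) {
      p$fc[[i]] <- list(W = glorot(d_prev, config$fc_dims[i]),
                        b = numeric(config$fc_dims[i]),
                        activation = config$activation, dropout = config$dropout)
      d_prev <- config$fc_dims[i]
    }
    # linear output head; the relative loss keeps predictions positive in
    # practice, so no clamp that could hide pathologies
    p$fc[[length(config$fc_dims) + 1L]] <-
      list(W = glorot(d_prev, 1L), b = 1, activation = "identity", dropout = 0)
    p
  })
  structure(list(
    config = config, params = params, scaling = NULL, fitted = FALSE,
    graph_cache = new.env(parent = emptyenv())
  ), class = "size_gcn")
}

#' @export
print.size_gcn <- function(x, ...) {
  cat(sprintf("<size_gcn> %s | conv %s -> fingerprint %d | fc %s -> 1 | ring_size %d\n",
              if (x$fitted) "fitted" else "unfitted",
              paste(x$config$conv_dims, collapse = "-"),
              2L * utils::tail(x$config$conv_dims, 1),
              paste(x$config$fc_dims, collapse = "-"), x$config$ring_size))
  invisible(x)
}

# cyclic graph + adjacency for a repeat unit, cached per model
model_graph <- function(model, smiles) {
  key <- smiles
  cache <- model$graph_cache
  if (!is.null(cache[[key]])) return(cache[[key]])
  graph <- build_cyclic_polymer(smiles, model$config$ring_size, model$config$spec)
  check_ring_wrap(graph, length(model$config$conv_dims))
  entry <- list(graph = graph, A_hat = normalized_adjacency(graph))
  cache[[key]] <- entry
  entry
}

#' Apply one fully connected layer
#'
#' \deqn{l_{n+1} = \sigma(l_n W_{n+1} + b_{n+1})}
#' Accepts a single input vector or a batch (rows). Dropout is applied to
#' the output in training mode only.
#'
#' @param l Input vector (or matrix with one sample per row).
#' @param params List with `W`, `b`, `activation`, `dropout`.
#' @param training Dropout switch.
#' @return Output vector (or matrix of rows).
#' @export
fc_layer <- function(l, params, training = FALSE) {
  single <- is.null(dim(l))
  X <- if (single) matrix(l, nrow = 1) else as.matrix(l)
  if (ncol(X) != nrow(params$W)) {
    abort(sprintf("shape mismatch: input of length %d but W expects %d",
                  ncol(X), nrow(params$W)), "polygcn_shape_error")
  }
  act <- get_activation(params$activation)
  P <- X %*% params$W
  P <- sweep(P, 2, params$b, "+")
  out <- act$f(P)
  if (training && params$dropout > 0) {
    keep <- matrix(stats::rbinom(length(out), 1, 1 - params$dropout),
                   nrow(out), ncol(out))
    out <- out * keep / (1 - params$dropout)
  }
  if (single) drop(out) else out
}

standardize_numeric <- function(x, scaling) {
  sweep(sweep(x, 2, scaling$x_mean, "-"), 2, scaling$x_sd, "/")
}

destandardize_numeric <- function(z, scaling) {
  sweep(sweep(z, 2, scaling$x_sd, "*"), 2, scaling$x_mean, "+")
}

# Dp and polymer concentration are ratio-scale and enter on the log scale
# (equal model resolution per fold change); the surfactant level keeps its
# linear scale because 0 encodes "absent".
numeric_inputs <- function(data) {
  if (any(data$dp <= 0) || any(data$conc <= 0)) {
    abort("dp and conc must be > 0", "polygcn_validation_error")
  }
  cbind(log_dp = log(data$dp), log_conc = log(data$conc),
        surfactant = data$surfactant)
}

# evaluation-mode forward pass for aligned vectors of smiles + numeric rows
model_forward_eval <- function(model, smiles, X_num) {
  Z <- standardize_numeric(X_num, model$scaling)
  fp_dim <- 2L * utils::tail(model$config$conv_dims, 1)
  fps <- matrix(0, length(smiles), fp_dim)
  for (s in unique(smiles)) {
    entry <- model_graph(model, s)
    H <- entry$graph$H0
    for (p in model$params$conv) H <- gcn_layer(H, entry$A_hat, p, training = FALSE)
    fp <- pool_readout(H, model$params$gate, model$config$sum_mode)
    fps[smiles == s, ] <- matrix(fp, sum(smiles == s), fp_dim, byrow = TRUE)
  }
  X <- cbind(fps, Z)
  for (p in model$params$fc) X <- fc_layer(X, p, training = FALSE)
  drop(X) * model$scaling$y_scale
}

#' Predict the nanoparticle diameter for one formulation
#'
#' Deterministic in evaluation mode: repeated calls with identical inputs
#' return bit-identical values. Numeric inputs are standardized with the
#' statistics stored at fit time before entering the fully connected part.
#'
#' @param unit Repeat unit or marked SMILES.
#' @param form List or one-row data frame with `dp` (> 0), `conc` (g/L,
#'   >= 0) and `surfactant` (g/L, 0 = none).
#' @param model A fitted `size_gcn`.
#' @return Predicted z-average diameter in nm.
#' @export
predict_size <- function(unit, form, model) {
  stopifnot(inherits(model, "size_gcn"))
  if (!model$fitted || is.null(model$scaling)) {
    abort("model not fitted: train it (or load a fitted bundle) before predicting",
          "polygcn_state_error")
  }
  check_scalar_number(form$dp, "dp", lower = 1e-9)
  check_scalar_number(form$conc, "conc", lower = 1e-12)
  check_scalar_number(form$surfactant, "surfactant", lower = 0)
  unit <- as_repeat_unit(unit)
  y <- model_forward_eval(model, unit$smiles,
                          numeric_inputs(list(dp = form$dp, conc = form$conc,
                                              surfactant = form$surfactant)))
  if (y <= 0) warning(sprintf("non-positive size predicted (%.3g nm)", y), call. = FALSE)
  unname(y)
}

#' Predict for every record of a dataset
#'
#' @param object A fitted `size_gcn`.
#' @param newdata A `formulation_dataset` (or coercible data frame).
#' @param ... Unused.
#' @return Numeric vector of predicted diameters (nm).
#' @export
predict.size_gcn <- function(object, newdata, ...) {
  if (!object$fitted) abort("model not fitted", "polygcn_state_error")
  newdata <- as.data.frame(newdata)
  model_forward_eval(object, newdata$smiles, numeric_inputs(newdata))
}

#' Evaluate a prediction surface over Dp and concentration
#'
#' Evaluates the fitted model for one repeat unit over a rectangular grid
#' of degrees of polymerization and polymer concentrations at a fixed
#' surfactant level, row-major (Dp outer, concentration inner) — the
#' "particle size map" a formulation scientist reads the required
#' conditions from.
#'
#' @param unit Repeat unit or marked SMILES.
#' @param model A fitted `size_gcn`.
#' @param dp_range Two-element range of Dp (default c(10, 300)).
#' @param conc_range Two-element range of polymer concentration in g/L,
#'   lower bound > 0 (default c(1, 30)).
#' @param grid_steps Grid points per axis (scalar or length 2).
#' @param surfactant_concentration Fixed surfactant level, g/L.
#' @return Data frame with columns `dp`, `conc`, `predicted_size_nm`.
#' @export
prediction_surface <- function(unit, model, dp_range = c(10, 300),
                               conc_range = c(1, 30), grid_steps = 30,
                               surfactant_concentration = 0) {
  stopifnot(inherits(model, "size_gcn"))
  if (!model$fitted) abort("model not fitted", "polygcn_state_error")
  if (length(grid_steps) == 1L) grid_steps <- rep(grid_steps, 2)
  if (any(grid_steps < 1) || dp_range[1] > dp_range[2] || conc_range[1] > conc_range[2]) {
    abort("empty grid: check ranges and grid_steps", "polygcn_validation_error")
  }
  if (conc_range[1] <= 0) {
    abort("polymer concentration must be > 0", "polygcn_validation_error")
  }
  unit <- as_repeat_unit(unit)
  dps <- seq(dp_range[1], dp_range[2], length.out = grid_steps[1])
  concs <- seq(conc_range[1], conc_range[2], length.out = grid_steps[2])
  grid <- expand.grid(conc = concs, dp = dps)[, c("dp", "conc")]  # row-major: dp outer
  y <- model_forward_eval(model, rep(unit$smiles, nrow(grid)),
                          numeric_inputs(list(dp = grid$dp, conc = grid$conc,
                                              surfactant = rep(surfactant_concentration,
                                                               nrow(grid)))))
  data.frame(dp = grid$dp, conc = grid$conc, predicted_size_nm = y)
}

#' Write a prediction surface as long-format CSV
#'
#' Comma-separated, header row, "." decimal separator; columns `dp`,
#' `conc`, `predicted_size_nm`.
#'
#' @param surface Data frame from [prediction_surface()].
#' @param path Output path.
#' @export
write_surface_csv <- function(surface, path) {
  utils::write.csv(surface, path, row.names = FALSE)
  invisible(path)
}

#' Save or load a fitted model as a single version-tagged JSON bundle
#'
#' The bundle holds the full configuration, the input-scaling statistics
#' and every layer checkpoint; doubles are stored with 17 significant
#' digits so a load reproduces the model bit-exactly.
#'
#' @param model A `size_gcn`.
#' @param path Bundle path.
#' @return `load_model` returns the restored `size_gcn`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "size_gcn"))
  cfg <- model$config
  flat_layer <- function(l) list(dim = dim(l$W), W = as.numeric(l$W),
                                 b = as.numeric(l$b), activation = l$activation,
                                 dropout = l$dropout)
  payload <- list(
    format_version = "polygcn-model-1",
    fitted = model$fitted,
    config = list(
      featurizers = cfg$spec$featurizers, element_set = cfg$spec$element_set,
      conv_dims = cfg$conv_dims, fc_dims = cfg$fc_dims, ring_size = cfg$ring_size,
      dropout = cfg$dropout, activation = cfg$activation, sum_mode = cfg$sum_mode,
      learning_rate = cfg$learning_rate, batch_size = cfg$batch_size,
      epochs = cfg$epochs, seed = cfg$seed
    ),
    scaling = model$scaling,
    params = list(conv = lapply(model$params$conv, flat_layer),
                  gate = list(w = as.numeric(model$params$gate$w),
                              c = as.numeric(model$params$gate$c)),
                  fc = lapply(model$params$fc, flat_layer))
  )
  write_json_exact(payload, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- read_json(path)
  if (!identical(payload$format_version, "polygcn-model-1")) {
    abort(sprintf("unsupported model bundle format: %s", payload$format_version),
          "polygcn_io_error")
  }
  cfg <- payload$config
  spec <- atom_feature_spec(featurizers = cfg$featurizers,
                            element_set = cfg$element_set)
  config <- model_config(spec = spec, conv_dims = cfg$conv_dims,
                         fc_dims = cfg$fc_dims, ring_size = cfg$ring_size,
                         dropout = cfg$dropout, activation = cfg$activation,
                         sum_mode = cfg$sum_mode, learning_rate = cfg$learning_rate,
                         batch_size = cfg$batch_size, epochs = cfg$epochs,
                         seed = cfg$seed)
  restore_layer <- function(l) list(
    W = matrix(as.numeric(l$W), l$dim[1], l$dim[2]), b = as.numeric(l$b),
    activation = l$activation, dropout = as.numeric(l$dropout))
  model <- new_size_model(config)
  model$params <- list(conv = lapply(payload$params$conv, restore_layer),
                       gate = list(w = as.numeric(payload$params$gate$w),
                                   c = as.numeric(payload$params$gate$c)),
                       fc = lapply(payload$params$fc, restore_layer))
  if (!is.null(payload$scaling)) {
    model$scaling <- list(x_mean = as.numeric(payload$scaling$x_mean),
                          x_sd = as.numeric(payload$scaling$x_sd),
                          y_scale = as.numeric(payload$scaling$y_scale))
  }
  model$fitted <- isTRUE(payload$fitted)
  model
}
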