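#' Training, leave-one-polymer-out evaluation and reporting
#'
#' Gradient computation is exact reverse-mode differentiation of the
#' forward pass (graph convolutions, max + gated-sum readout, fully
#' connected layers, relative loss), optimized with the adaptive-moment
#' (Adam) scheme. Records sharing a polymer also share the graph forward
#' and backward pass within a batch, which keeps an epoch over a few
#' thousand records cheap.
#'
#' @name metrics_training
NULL

# ---- forward/backward with caches ------------------------------------------

conv_forward_train <- function(params_conv, gate, A_hat, H0, dropout_on) {
  L <- length(params_conv)
  Zs <- vector("list", L); Ps <- vector("list", L); masks <- vector("list", L)
  H <- H0
  for (l in seq_len(L)) {
    p <- params_conv[[l]]
    Z <- A_hat %*% H
    P <- sweep(Z %*% p$W, 2, p$b, "+")
    act <- get_activation(p$activation)
    H <- act$f(P)
    if (dropout_on && p$dropout > 0) {
      m <- matrix(stats::rbinom(length(H), 1, 1 - p$dropout) / (1 - p$dropout),
                  nrow(H), ncol(H))
      H <- H * m
      masks[[l]] <- m
    }
    Zs[[l]] <- Z; Ps[[l]] <- P
  }
  s <- drop(H %*% gate$w) + gate$c
  g <- sigmoid(s)
  amax <- apply(H, 2, which.max)
  fp <- c(apply(H, 2, max), drop(crossprod(H, g)))
  list(fp = fp, H = H, g = g, amax = amax, Zs = Zs, Ps = Ps, masks = masks)
}

conv_backward <- function(cache, d_fp, params_conv, gate, A_hat) {
  d <- ncol(cache$H)
  dmax <- d_fp[seq_len(d)]; dsum <- d_fp[d + seq_len(d)]
  H <- cache$H; g <- cache$g
  dH <- matrix(0, nrow(H), d)
  dH[cbind(cache$amax, seq_len(d))] <- dmax
  dH <- dH + outer(g, dsum)
  ds <- drop(H %*% dsum) * g * (1 - g)
  g_gate <- list(w = drop(crossprod(H, ds)), c = sum(ds))
  dH <- dH + outer(ds, gate$w)

  L <- length(params_conv)
  g_conv <- vector("list", L)
  for (l in rev(seq_len(L))) {
    p <- params_conv[[l]]
    if (!is.null(cache$masks[[l]])) dH <- dH * cache$masks[[l]]
    act <- get_activation(p$activation)
    dP <- dH * act$df(cache$Ps[[l]])
    g_conv[[l]] <- list(W = crossprod(cache$Zs[[l]], dP), b = colSums(dP))
    dH <- A_hat %*% (dP %*% t(p$W))  # A_hat is symmetric
  }
  list(conv = g_conv, gate = g_gate)
}

fc_forward_train <- function(params_fc, X, dropout_on) {
  M <- length(params_fc)
  Xs <- vector("list", M); Ps <- vector("list", M); masks <- vector("list", M)
  for (l in seq_len(M)) {
    p <- params_fc[[l]]
    Xs[[l]] <- X
    P <- sweep(X %*% p$W, 2, p$b, "+")
    act <- get_activation(p$activation)
    X <- act$f(P)
    if (dropout_on && p$dropout > 0) {
      m <- matrix(stats::rbinom(length(X), 1, 1 - p$dropout) / (1 - p$dropout),
                  nrow(X), ncol(X))
      X <- X * m
      masks[[l]] <- m
    }
    Ps[[l]] <- P
  }
  list(out = drop(X), Xs = Xs, Ps = Ps, masks = masks)
}

fc_backward <- function(cache, d_out, params_fc) {
  M <- length(params_fc)
  g_fc <- vector("list", M)
  dX <- matrix(d_out, ncol = 1)
  for (l in rev(seq_len(M))) {
    p <- params_fc[[l]]
    if (!is.null(cache$masks[[l]])) dX <- dX * cache$masks[[l]]
    act <- get_activation(p$activation)
    dP <- dX * act$df(cache$Ps[[l]])
    g_fc[[l]] <- list(W = crossprod(cache$Xs[[l]], dP), b = colSums(dP))
    dX <- dP %*% t(p$W)
  }
  list(fc = g_fc, dX = dX)
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  zero_like <- function(x) x * 0
  layer_state <- function(l) list(W = zero_like(l$W), b = zero_like(l$b))
  list(t = 0L,
       m = list(conv = lapply(params$conv, layer_state),
                gate = list(w = zero_like(params$gate$w), c = 0),
                fc = lapply(params$fc, layer_state)),
       v = list(conv = lapply(params$conv, layer_state),
                gate = list(w = zero_like(params$gate$w), c = 0),
                fc = lapply(params$fc, layer_state)))
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(p = p, m = m, v = v)
  }
  for (l in seq_along(params$conv)) {
    for (nm in c("W", "b")) {
      r <- upd(params$conv[[l]][[nm]], grads$conv[[l]][[nm]],
               state$m$conv[[l]][[nm]], state$v$conv[[l]][[nm]])
      params$conv[[l]][[nm]] <- r$p
      state$m$conv[[l]][[nm]] <- r$m; state$v$conv[[l]][[nm]] <- r$v
    }
  }
  for (nm in c("w", "c")) {
    r <- upd(params$gate[[nm]], grads$gate[[nm]],
             state$m$gate[[nm]], state$v$gate[[nm]])
    params$gate[[nm]] <- r$p
    state$m$gate[[nm]] <- r$m; state$v$gate[[nm]] <- r$v
  }
  for (l in seq_along(params$fc)) {
    for (nm in c("W", "b")) {
      r <- upd(params$fc[[l]][[nm]], grads$fc[[l]][[nm]],
               state$m$fc[[l]][[nm]], state$v$fc[[l]][[nm]])
      params$fc[[l]][[nm]] <- r$p
      state$m$fc[[l]][[nm]] <- r$m; state$v$fc[[l]][[nm]] <- r$v
    }
  }
  list(params = params, state = state)
}

add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (l in seq_along(b$conv)) {
    a$conv[[l]]$W <- a$conv[[l]]$W + b$conv[[l]]$W
    a$conv[[l]]$b <- a$conv[[l]]$b + b$conv[[l]]$b
  }
  a$gate$w <- a$gate$w + b$gate$w
  a$gate$c <- a$gate$c + b$gate$c
  a
}

# ---- training loop ----------------------------------------------------------

#' Train the size model on a training/validation pair
#'
#' Minimizes the relative (MAPE) loss with Adam, records per-epoch training
#' and validation MAPE/RMSE in evaluation mode, and keeps the parameters of
#' the best-validation-MAPE epoch. Fully reproducible given `config$seed`.
#'
#' @param train_set,val_set `formulation_dataset`s (non-empty).
#' @param config A [model_config()].
#' @return List with `model` (fitted `size_gcn`) and `report` (a
#'   `train_report`: per-epoch `history`, `best_epoch`, final metrics).
#' @export
train <- function(train_set, val_set, config = model_config()) {
  train_set <- as_formulation_dataset(train_set)
  val_set <- as_formulation_dataset(val_set)
  model <- new_size_model(config)

  X_tr <- numeric_inputs(train_set)
  x_sd <- apply(X_tr, 2, stats::sd)
  x_sd[!is.finite(x_sd) | x_sd == 0] <- 1
  model$scaling <- list(x_mean = colMeans(X_tr), x_sd = x_sd,
                        y_scale = mean(train_set$size_nm))
  model$fitted <- TRUE  # scaling fixed; parameters refined below

  # pre-build graphs and standardized inputs
  smiles_tr <- train_set$smiles
  for (s in unique(c(smiles_tr, val_set$smiles))) model_graph(model, s)
  Z_tr <- standardize_numeric(X_tr, model$scaling)
  y_tr <- train_set$size_nm
  n <- nrow(train_set)
  fp_dim <- 2L * utils::tail(config$conv_dims, 1)

  params <- model$params
  state <- adam_init(params)
  history <- vector("list", config$epochs)
  best <- list(val_mape = Inf, params = params, epoch = 0L)

  set.seed(config$seed + 1L)  # shuffling + dropout stream
  for (epoch in seq_len(config$epochs)) {
    idx <- if (n > 1) sample.int(n) else 1L
    batches <- split(idx, ceiling(seq_along(idx) / config$batch_size))
    for (batch in batches) {
      B <- length(batch)
      sm <- smiles_tr[batch]
      uniq <- unique(sm)
      caches <- vector("list", length(uniq)); names(caches) <- uniq
      fps <- matrix(0, B, fp_dim)
      for (s in uniq) {
        entry <- model$graph_cache[[s]]
        caches[[s]] <- conv_forward_train(params$conv, params$gate,
                                          entry$A_hat, entry$graph$H0,
                                          dropout_on = TRUE)
        fps[sm == s, ] <- matrix(caches[[s]]$fp, sum(sm == s), fp_dim, byrow = TRUE)
      }
      Xb <- cbind(fps, Z_tr[batch, , drop = FALSE])
      fcc <- fc_forward_train(params$fc, Xb, dropout_on = TRUE)
      y_hat <- fcc$out * model$scaling$y_scale
      yb <- y_tr[batch]
      loss <- mean(abs(y_hat - yb) / yb)
      if (!is.finite(loss)) {
        abort(sprintf("training diverged at epoch %d (non-finite loss)", epoch),
              "polygcn_training_error")
      }
      d_yhat <- sign(y_hat - yb) / yb / B
      d_out <- d_yhat * model$scaling$y_scale
      fb <- fc_backward(fcc, d_out, params$fc)
      grads <- list(fc = fb$fc)
      gg <- NULL
      for (s in uniq) {
        rows <- which(sm == s)
        d_fp <- colSums(fb$dX[rows, seq_len(fp_dim), drop = FALSE])
        gg <- add_grads(gg, conv_backward(caches[[s]], d_fp, params$conv,
                                          params$gate,
                                          model$graph_cache[[s]]$A_hat))
      }
      grads$conv <- gg$conv; grads$gate <- gg$gate
      r <- adam_step(params, grads, state, config$learning_rate)
      params <- r$params; state <- r$state
    }

    model$params <- params
    pred_tr <- model_forward_eval(model, smiles_tr, X_tr)
    pred_val <- model_forward_eval(model, val_set$smiles, numeric_inputs(val_set))
    h <- data.frame(epoch = epoch,
                    train_mape = mape(pred_tr, y_tr),
                    train_rmse = rmse(pred_tr, y_tr),
                    val_mape = mape(pred_val, val_set$size_nm),
                    val_rmse = rmse(pred_val, val_set$size_nm))
    history[[epoch]] <- h
    if (h$val_mape < best$val_mape) {
      best <- list(val_mape = h$val_mape, params = params, epoch = epoch)
    }
    if (config$verbose > 0 && epoch %% config$verbose == 0) {
      message(sprintf("epoch %4d | train MAPE %6.2f%% RMSE %7.2f | val MAPE %6.2f%% RMSE %7.2f",
                      epoch, h$train_mape, h$train_rmse, h$val_mape, h$val_rmse))
    }
  }

  history <- do.call(rbind, history)
  model$params <- best$params
  pred_tr <- model_forward_eval(model, smiles_tr, X_tr)
  pred_val <- model_forward_eval(model, val_set$smiles, numeric_inputs(val_set))
  report <- structure(list(
    history = history,
    best_epoch = best$epoch,
    train_mape = mape(pred_tr, y_tr),
    train_rmse = rmse(pred_tr, y_tr),
    val_mape = mape(pred_val, val_set$size_nm),
    val_rmse = rmse(pred_val, val_set$size_nm)
  ), class = "train_report")
  list(model = model, report = report)
}

#' @export
print.train_report <- function(x, ...) {
  cat(sprintf("<train_report> best epoch %d | train MAPE %.2f%% | val MAPE %.2f%%\n",
              x$best_epoch, x$train_mape, x$val_mape))
  if (!is.null(x$mape_test)) {
    cat(sprintf("  held out %s: test MAPE %.2f%% (%.2f%% excl. worst group '%s'); all %.2f%% (%.2f%%)\n",
                paste(x$held_out, collapse = " + "), x$mape_test,
                x$mape_test_without_worst, x$worst_group,
                x$mape_all, x$mape_all_without_worst))
  }
  invisible(x)
}

#' Leave-one-polymer-out evaluation
#'
#' For each holdout (a polymer id, or a vector of ids evaluated jointly)
#' all of its records are removed, the remainder is 8:2 split and a model
#' is trained from scratch. The held-out records serve as the test set for
#' the unseen-polymer generalization question; the "all" metrics pool the
#' validation split with the held-out records. The worst-performing group
#' of the held-out polymer (by Dp, concentration or additive) is identified
#' and both metrics are additionally reported with that group excluded.
#'
#' @param data A `formulation_dataset` covering several polymers.
#' @param holdouts List of holdouts; each element is a character vector of
#'   polymer ids (default: each polymer in turn).
#' @param config A [model_config()].
#' @return List of `train_report`s, one per holdout, each extended with
#'   `held_out`, `mape_test`, `mape_test_without_worst`, `mape_all`,
#'   `mape_all_without_worst`, `worst_group`, `n_test`.
#' @export
leave_one_polymer_out <- function(data, holdouts = NULL, config = model_config()) {
  data <- as_formulation_dataset(data)
  polymers <- unique(data$polymer)
  if (is.null(holdouts)) holdouts <- as.list(polymers)
  reports <- vector("list", length(holdouts))
  names(reports) <- vapply(holdouts, paste, character(1), collapse = " + ")
  for (i in seq_along(holdouts)) {
    ids <- holdouts[[i]]
    missing_ids <- setdiff(ids, polymers)
    if (length(missing_ids)) {
      abort(sprintf("holdout polymer(s) with zero records: %s",
                    paste(missing_ids, collapse = ", ")), "polygcn_validation_error")
    }
    if (length(setdiff(polymers, ids)) == 0L) {
      abort("cannot hold out every polymer", "polygcn_validation_error")
    }
    held <- data[data$polymer %in% ids, , drop = FALSE]
    rest <- data[!data$polymer %in% ids, , drop = FALSE]
    stopifnot(!any(held$polymer %in% rest$polymer))  # leakage audit
    sp <- split_dataset(rest, ratio = 0.8, seed = config$seed)
    fit <- train(sp$train, sp$validation, config)

    pred_test <- predict(fit$model, held)
    wga <- worst_group_analysis(pred_test, held)
    all_set <- rbind(as.data.frame(sp$validation), as.data.frame(held))
    pred_all <- c(predict(fit$model, sp$validation), pred_test)

    report <- fit$report
    report$held_out <- ids
    report$n_test <- nrow(held)
    report$mape_test <- mape(pred_test, held$size_nm)
    report$mape_all <- mape(pred_all, all_set$size_nm)
    if (!is.null(wga)) {
      report$worst_group <- wga$worst_group
      report$mape_test_without_worst <- wga$mape_without
      keep_all <- !(all_set$polymer %in% ids & all_set[[wga$key]] == wga$worst_group)
      report$mape_all_without_worst <- mape(pred_all[keep_all], all_set$size_nm[keep_all])
      report$worst_group_table <- wga$group_table
    } else {
      report$worst_group <- NA_character_
      report$mape_test_without_worst <- report$mape_test
      report$mape_all_without_worst <- report$mape_all
    }
    reports[[i]] <- report
  }
  reports
}

#' Export a training report
#'
#' Writes the per-epoch metric history as CSV and/or a JSON summary whose
#' fields mirror the leave-one-polymer-out result table (train MAPE, test
#' MAPE with and without the worst group, pooled metrics, worst group id).
#'
#' @param report A `train_report`.
#' @param csv_path,json_path Output paths (either may be `NULL`).
#' @export
write_train_report <- function(report, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "train_report"))
  if (!is.null(csv_path)) utils::write.csv(report$history, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    summary_fields <- report[setdiff(names(report), c("history", "worst_group_table"))]
    write_json_exact(summary_fields, json_path)
  }
  invisible(report)
}
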