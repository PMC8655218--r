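#' Mean absolute percentage error
#'
#' \deqn{\mathrm{MAPE} = \frac{100}{n}\sum_i \frac{|\hat y_i - y_i|}{y_i}}
#' The relative form is used both as the training loss and as the headline
#' metric: it weights small particles as heavily as large ones.
#'
#' @param y_hat Predicted sizes.
#' @param y Measured sizes (all > 0).
#' @return MAPE in percent.
#' @examples
#' mape(c(110), c(100))        # 10
#' mape(c(60, 180), c(50, 200)) # 15
#' @export
mape <- function(y_hat, y) {
  check_metric_args(y_hat, y)
  if (any(y <= 0)) abort("MAPE requires all reference sizes > 0", "polygcn_domain_error")
  100 * mean(abs(y_hat - y) / y)
}

#' Root-mean-square error
#'
#' @param y_hat Predicted sizes.
#' @param y Measured sizes.
#' @return RMSE in the units of `y` (nm).
#' @export
rmse <- function(y_hat, y) {
  check_metric_args(y_hat, y)
  sqrt(mean((y_hat - y)^2))
}

check_metric_args <- function(y_hat, y) {
  if (length(y_hat) != length(y)) {
    abort(sprintf("shape mismatch: %d predictions vs %d references",
                  length(y_hat), length(y)), "polygcn_shape_error")
  }
  if (length(y) < 1L) abort("need at least one observation", "polygcn_validation_error")
  invisible(TRUE)
}

#' Split a dataset into training and validation parts
#'
#' A seeded uniform random split. The validation size is
#' `round((1 - ratio) * n)` (round-half-to-even, R's `round`), the
#' remainder trains; e.g. 2813 records at 8:2 give 2250 training and 563
#' validation records. The split is disjoint, exhaustive and reproducible
#' for a given seed.
#'
#' @param data A `formulation_dataset` (or any data frame).
#' @param ratio Training fraction (default 0.8).
#' @param seed RNG seed (mandatory).
#' @return List with elements `train` and `validation`.
#' @export
split_dataset <- function(data, ratio = 0.8, seed) {
  if (missing(seed)) abort("`seed` is required for a reproducible split", "polygcn_validation_error")
  check_scalar_number(ratio, "ratio", 1e-6, 1 - 1e-6)
  n <- nrow(data)
  if (is.null(n) || n < 5L) {
    abort("dataset too small to split (need >= 5 records)", "polygcn_validation_error")
  }
  n_val <- round((1 - ratio) * n)
  if (n_val < 1L || n_val >= n) {
    abort("degenerate split: one part would be empty", "polygcn_validation_error")
  }
  idx_val <- with_seed(seed, sample.int(n, n_val))
  list(train = data[setdiff(seq_len(n), idx_val), , drop = FALSE],
       validation = data[sort(idx_val), , drop = FALSE])
}

#' Worst-performing-group error decomposition
#'
#' Large test errors on a held-out polymer usually trace back to a single
#' group of formulations with peripheral parameters (an extreme degree of
#' polymerization, the lowest concentration, or no surfactant). Records
#' are grouped by the exact recorded value under each grouping key; the
#' group with the highest MAPE across all keys is reported, together with
#' the overall MAPE including and excluding it. Ties are broken toward the
#' larger group, then lexicographically by group id.
#'
#' @param predictions Predicted sizes, aligned with `records`.
#' @param records A `formulation_dataset` (provides the group labels).
#' @param grouping_keys Label columns to scan (default the Dp,
#'   concentration and additive groups).
#' @return List with `worst_group` (label, e.g. `"Dp=1000"`), `key` (the
#'   grouping column it came from), `mape_with` (overall), `mape_without`
#'   (overall excluding the worst group), `group_table` (per-group MAPE and
#'   size), or `NULL` with a message when only one group exists.
#' @export
worst_group_analysis <- function(predictions, records,
                                 grouping_keys = c("dp_group", "conc_group",
                                                   "additive_group")) {
  records <- as_formulation_dataset(records)
  if (length(predictions) != nrow(records)) {
    abort(sprintf("shape mismatch: %d predictions vs %d records",
                  length(predictions), nrow(records)), "polygcn_shape_error")
  }
  missing_keys <- setdiff(grouping_keys, names(records))
  if (length(missing_keys)) {
    abort(sprintf("records lack grouping column(s): %s",
                  paste(missing_keys, collapse = ", ")), "polygcn_validation_error")
  }

  rows <- list()
  for (key in grouping_keys) {
    for (lev in unique(records[[key]])) {
      in_grp <- records[[key]] == lev
      rows[[length(rows) + 1L]] <- data.frame(
        key = key, group = lev, n = sum(in_grp),
        mape = mape(predictions[in_grp], records$size_nm[in_grp]))
    }
  }
  tab <- do.call(rbind, rows)
  n_levels <- vapply(grouping_keys, function(k) length(unique(records[[k]])), numeric(1))
  if (all(n_levels <= 1)) {
    message("worst-group analysis skipped: only a single group under every key")
    return(NULL)
  }
  # worst = max MAPE; ties -> largest group, then lexicographic id
  ord <- order(-tab$mape, -tab$n, tab$group)
  worst <- tab[ord[1], ]
  in_worst <- records[[worst$key]] == worst$group
  overall <- mape(predictions, records$size_nm)
  without <- if (all(in_worst)) NA_real_ else
    mape(predictions[!in_worst], records$size_nm[!in_worst])
  list(worst_group = worst$group, key = worst$key, n = worst$n,
       mape_with = overall, mape_without = without, group_table = tab)
}
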