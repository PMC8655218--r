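#' Cleaning of raw replicate DLS measurement tables
#'
#' Raw nanoprecipitation screens carry rows in which no particles formed,
#' dynamic light scattering recorded an artifact, or a single replicate
#' went wrong. Cleaning proceeds in two stages: per-row validity filtering
#' ([filter_invalid()]) and within-formulation replicate-outlier rejection
#' ([remove_replicate_outliers()]); [assemble_dataset()] then turns the
#' survivors into the modeling dataset. Every removed row carries a
#' machine-readable reason code and `|kept| + |rejected| = |input|` holds
#' at every stage.
#'
#' @name preprocessing
NULL

#' Filtering thresholds
#'
#' Defaults follow standard dynamic-light-scattering practice: a
#' polydispersity index above 0.3 indicates a broad or invalid size
#' distribution, z-average diameters outside 10–1000 nm are outside the
#' instrument's trustworthy window for these formulations, replicates
#' deviating more than 30 percent from their formulation median are
#' outliers, and a formulation keeps its measurements only if at least 3
#' survive. All values are configurable.
#'
#' @param pdi_max Maximum acceptable polydispersity index.
#' @param size_min,size_max Sanity bounds on the z-average diameter, nm.
#' @param outlier_rel Relative median-deviation threshold for replicate
#'   outliers.
#' @param min_measurements Minimum surviving measurements per formulation.
#' @return A `filter_config` list.
#' @export
filter_config <- function(pdi_max = 0.3, size_min = 10, size_max = 1000,
                          outlier_rel = 0.3, min_measurements = 3) {
  check_scalar_number(pdi_max, "pdi_max", lower = 1e-9)
  check_scalar_number(size_min, "size_min", lower = 0)
  check_scalar_number(size_max, "size_max", lower = size_min)
  check_scalar_number(outlier_rel, "outlier_rel", lower = 1e-9)
  structure(list(pdi_max = pdi_max, size_min = size_min, size_max = size_max,
                 outlier_rel = outlier_rel,
                 min_measurements = as.integer(min_measurements)),
            class = "filter_config")
}

raw_required_cols <- c("polymer", "smiles", "dp", "conc", "surfactant",
                       "replicate", "measurement", "size_nm", "pdi")

check_raw_table <- function(raw) {
  missing_cols <- setdiff(raw_required_cols, names(raw))
  if (length(missing_cols)) {
    abort(sprintf("raw table is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")), "polygcn_validation_error")
  }
  if (nrow(raw) == 0L) abort("raw table is empty", "polygcn_validation_error")
  invisible(raw)
}

#' Remove invalid measurements
#'
#' Rejects rows with a missing size (no particles formed / measurement
#' failed), a polydispersity index above the threshold, or a size outside
#' the sanity bounds. Decisions are per-row, so the result does not depend
#' on row order.
#'
#' @param raw Raw measurement data frame (columns `polymer`, `smiles`,
#'   `dp`, `conc`, `surfactant`, `replicate`, `measurement`, `size_nm`,
#'   `pdi`).
#' @param cfg A [filter_config()].
#' @return List with `kept` (data frame) and `rejected` (data frame with a
#'   `reason` column: `missing_size`, `high_dispersity`,
#'   `size_out_of_bounds`).
#' @export
filter_invalid <- function(raw, cfg = filter_config()) {
  check_raw_table(raw)
  reason <- rep(NA_character_, nrow(raw))
  bad_size <- !is.finite(raw$size_nm)
  reason[bad_size] <- "missing_size"
  high_pdi <- !bad_size & (is.na(raw$pdi) | raw$pdi > cfg$pdi_max)
  reason[high_pdi] <- "high_dispersity"
  oob <- !bad_size & !high_pdi &
    (raw$size_nm < cfg$size_min | raw$size_nm > cfg$size_max)
  reason[oob] <- "size_out_of_bounds"
  rejected <- raw[!is.na(reason), , drop = FALSE]
  rejected$reason <- reason[!is.na(reason)]
  list(kept = raw[is.na(reason), , drop = FALSE], rejected = rejected)
}

formulation_key <- function(df) {
  paste(df$polymer, df$dp, df$conc, df$surfactant, sep = "\r")
}

#' Reject replicate outliers within each formulation
#'
#' Each formulation (polymer, Dp, concentration, surfactant level) carries
#' up to nine measurements (three formulations, each measured three
#' times). Rows whose size deviates from the formulation median by more
#' than `outlier_rel` of the median are removed; formulations left with
#' fewer than `min_measurements` rows are dropped entirely (reason
#' `insufficient_replicates`).
#'
#' @param kept Data frame of valid rows (from [filter_invalid()]).
#' @param cfg A [filter_config()].
#' @return List with `surviving` and `outliers` (with a `reason` column:
#'   `replicate_outlier`, `insufficient_replicates`).
#' @export
remove_replicate_outliers <- function(kept, cfg = filter_config()) {
  if (nrow(kept) == 0L) {
    return(list(surviving = kept, outliers = cbind(kept, reason = character(0))))
  }
  key <- formulation_key(kept)
  med <- stats::ave(kept$size_nm, key, FUN = stats::median)
  is_outlier <- abs(kept$size_nm - med) > cfg$outlier_rel * med
  n_left <- stats::ave(as.numeric(!is_outlier), key, FUN = sum)
  too_few <- !is_outlier & n_left < cfg$min_measurements
  reason <- ifelse(is_outlier, "replicate_outlier",
                   ifelse(too_few, "insufficient_replicates", NA_character_))
  outliers <- kept[!is.na(reason), , drop = FALSE]
  outliers$reason <- reason[!is.na(reason)]
  list(surviving = kept[is.na(reason), , drop = FALSE], outliers = outliers)
}

#' Assemble the modeling dataset from surviving measurements
#'
#' One record per surviving measurement — replicate measurements are kept
#' as independent records rather than averaged, matching the fact that the
#' modeling unit downstream is the single measurement.
#'
#' @param surviving Data frame of surviving rows.
#' @return A [formulation_dataset()].
#' @export
assemble_dataset <- function(surviving) {
  if (is.null(surviving) || nrow(surviving) == 0L) {
    abort("no measurements survived preprocessing", "polygcn_validation_error")
  }
  formulation_dataset(surviving[, c("polymer", "smiles", "dp", "conc",
                                    "surfactant", "size_nm"), drop = FALSE])
}

#' Run the full cleaning pipeline
#'
#' [filter_invalid()], then [remove_replicate_outliers()], then
#' [assemble_dataset()].
#'
#' @param raw Raw measurement table.
#' @param cfg A [filter_config()].
#' @return List with `dataset` (a `formulation_dataset`), `rejected` (all
#'   removed rows with reason codes) and `n_input`, `n_surviving`.
#' @export
preprocess_raw <- function(raw, cfg = filter_config()) {
  f1 <- filter_invalid(raw, cfg)
  f2 <- remove_replicate_outliers(f1$kept, cfg)
  rejected <- rbind(f1$rejected, f2$outliers)
  stopifnot(nrow(f2$surviving) + nrow(rejected) == nrow(raw))  # conservation
  list(dataset = assemble_dataset(f2$surviving), rejected = rejected,
       n_input = nrow(raw), n_surviving = nrow(f2$surviving))
}

#' Read / write raw measurement tables as CSV
#'
#' Comma-separated UTF-8 with header; columns as in [filter_invalid()].
#'
#' @param path CSV path.
#' @param raw Raw table data frame.
#' @export
read_raw_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path), "polygcn_io_error")
  check_raw_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_raw_csv
#' @export
write_raw_csv <- function(raw, path) {
  utils::write.csv(raw, path, row.names = FALSE)
  invisible(path)
}
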