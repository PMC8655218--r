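#' Assemble a modeling dataset of formulation records
#'
#' One record per surviving measurement (measurements are deliberately not
#' averaged over replicates: each one is an independent training example).
#' Group labels used by the worst-group error decomposition are attached
#' from the exact recorded values — records belong to the same group when
#' they share the recorded degree of polymerization, polymer concentration
#' or additive status, mirroring discrete synthesis/formulation batches.
#'
#' @param df Data frame with columns `polymer` (id), `smiles` (marked
#'   repeat-unit SMILES), `dp` (degree of polymerization), `conc` (polymer
#'   concentration, g/L), `surfactant` (surfactant concentration, g/L; 0 =
#'   none) and `size_nm` (measured z-average diameter).
#' @return A `formulation_dataset` (a data frame) with added label columns
#'   `dp_group`, `conc_group`, `additive_group`.
#' @export
formulation_dataset <- function(df) {
  required <- c("polymer", "smiles", "dp", "conc", "surfactant", "size_nm")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    abort(sprintf("dataset is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")), "polygcn_validation_error")
  }
  if (nrow(df) == 0L) abort("dataset has no records", "polygcn_validation_error")
  if (any(!is.finite(df$size_nm) | df$size_nm <= 0)) {
    abort("all measured sizes must be finite and > 0", "polygcn_domain_error")
  }
  if (any(df$dp <= 0)) abort("all Dp values must be > 0", "polygcn_validation_error")
  if (any(df$conc < 0) || any(df$surfactant < 0)) {
    abort("concentrations must be >= 0", "polygcn_validation_error")
  }
  df$dp_group <- paste0("Dp=", format(df$dp, trim = TRUE, scientific = FALSE))
  df$conc_group <- paste0("c=", format(df$conc, trim = TRUE, scientific = FALSE), " g/L")
  df$additive_group <- ifelse(df$surfactant > 0, "with surfactant", "without surfactant")
  class(df) <- c("formulation_dataset", "data.frame")
  df
}

is_formulation_dataset <- function(x) inherits(x, "formulation_dataset")

as_formulation_dataset <- function(x) {
  if (is_formulation_dataset(x)) return(x)
  formulation_dataset(as.data.frame(x))
}

#' Read / write formulation datasets as CSV
#'
#' Plain comma-separated UTF-8 files with a header row and "." as decimal
#' separator; columns as documented in [formulation_dataset()].
#'
#' @param path CSV file path.
#' @param data A `formulation_dataset` (or coercible data frame).
#' @return `read_dataset_csv` returns a `formulation_dataset`;
#'   `write_dataset_csv` returns the path invisibly.
#' @export
read_dataset_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path), "polygcn_io_error")
  formulation_dataset(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_dataset_csv
#' @export
write_dataset_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}
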