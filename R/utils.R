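# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded package functions do not
#' disturb the caller's random stream.
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Stop with a classed condition
#' @noRd
abort <- function(message, class) {
  stop(structure(
    class = c(class, "polygcn_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name), "polygcn_validation_error")
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` = %g outside [%g, %g]", name, x, lower, upper),
          "polygcn_validation_error")
  }
  invisible(x)
}

# Activation functions used by both the convolutional and fully connected
# layers; each entry holds the map and its derivative w.r.t. the
# pre-activation (as a function of the pre-activation).
.activations <- list(
  relu     = list(f = function(x) pmax(x, 0), df = function(x) (x > 0) * 1),
  identity = list(f = function(x) x,          df = function(x) x * 0 + 1),
  tanh     = list(f = tanh,                   df = function(x) 1 - tanh(x)^2)
)

get_activation <- function(id) {
  act <- .activations[[id]]
  if (is.null(act)) {
    abort(sprintf("unknown activation '%s' (available: %s)",
                  id, paste(names(.activations), collapse = ", ")),
          "polygcn_validation_error")
  }
  act
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Serialize a numeric payload to JSON preserving full double precision
#'
#' 17 significant digits round-trip IEEE doubles exactly, which backs the
#' bit-exact checkpoint contract.
#' @noRd
write_json_exact <- function(x, path) {
  json <- jsonlite::toJSON(x, digits = I(17), auto_unbox = TRUE, null = "null")
  writeLines(json, path)
  invisible(path)
}

read_json <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), "polygcn_io_error")
  }
  jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                     simplifyMatrix = FALSE)
}
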