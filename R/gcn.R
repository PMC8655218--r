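#' Graph convolutional core
#'
#' The convolution layer updates the node feature matrix as
#' \deqn{H_{n+1} = \sigma(\hat A H_n W_n + b_n)}
#' with \eqn{\hat A} the symmetric-normalized self-loop adjacency
#' ([normalized_adjacency()]). Stacking layers widens each node's awareness
#' range by one hop per layer; the readout then collapses the convolved
#' graph into a fixed-length fingerprint by concatenating a column-wise max
#' pool with a gated weighted sum.
#'
#' @name gcn_core
NULL

#' Construct parameters for one graph-convolution layer
#'
#' @param in_dim,out_dim Feature dimensions entering and leaving the layer.
#' @param activation Activation identifier (`"relu"`, `"identity"`,
#'   `"tanh"`).
#' @param dropout Dropout rate in \[0, 1), applied to the layer output in
#'   training mode only (default 0.1).
#' @param init One of `"glorot"` (seeded random) or `"zero"`; for random
#'   init the caller controls the RNG stream.
#' @return A list with `W` (`in_dim x out_dim`), `b` (`out_dim`),
#'   `activation`, `dropout`.
#' @export
gcn_layer_params <- function(in_dim, out_dim, activation = "relu",
                             dropout = 0.1, init = "glorot") {
  check_scalar_number(dropout, "dropout", 0, 1 - 1e-9)
  get_activation(activation)
  W <- if (init == "zero") matrix(0, in_dim, out_dim) else glorot(in_dim, out_dim)
  list(W = W, b = numeric(out_dim), activation = activation, dropout = dropout)
}

glorot <- function(n_in, n_out) {
  limit <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -limit, limit), n_in, n_out)
}

#' Apply one graph-convolution layer
#'
#' @param H Node feature matrix (nodes x features).
#' @param A_hat Normalized adjacency of the same node order.
#' @param params Layer parameters from [gcn_layer_params()].
#' @param training When `TRUE`, inverted dropout is applied to the output;
#'   evaluation mode is deterministic.
#' @return The updated node feature matrix.
#' @export
gcn_layer <- function(H, A_hat, params, training = FALSE) {
  H <- as.matrix(H)
  if (nrow(H) != nrow(A_hat) || nrow(A_hat) != ncol(A_hat)) {
    abort(sprintf("shape mismatch: H is %dx%d but A_hat is %dx%d",
                  nrow(H), ncol(H), nrow(A_hat), ncol(A_hat)), "polygcn_shape_error")
  }
  if (ncol(H) != nrow(params$W)) {
    abort(sprintf("shape mismatch: H has %d feature columns but W expects %d",
                  ncol(H), nrow(params$W)), "polygcn_shape_error")
  }
  act <- get_activation(params$activation)
  P <- A_hat %*% H %*% params$W
  P <- sweep(P, 2, params$b, "+")
  out <- act$f(P)
  if (training && params$dropout > 0) {
    keep <- matrix(stats::rbinom(length(out), 1, 1 - params$dropout),
                   nrow(out), ncol(out))
    out <- out * keep / (1 - params$dropout)
  }
  out
}

#' Run a stack of graph convolutions over a polymer graph
#'
#' Applies the layers sequentially to the graph's feature matrix; the
#' topology is unchanged, only the node features are convolved. For cyclic
#' graphs a wrap guard warns when the awareness range (one hop per layer)
#' could reach around the macrocycle, which would break the equivalence to
#' an infinite linear chain.
#'
#' @param graph A `molecular_graph`.
#' @param layers List of layer parameter sets ([gcn_layer_params()]); an
#'   empty list returns `H0` unchanged.
#' @param training Dropout switch, see [gcn_layer()].
#' @param A_hat Optional precomputed normalized adjacency.
#' @return Convolved node feature matrix.
#' @export
stack_convolutions <- function(graph, layers, training = FALSE, A_hat = NULL) {
  stopifnot(inherits(graph, "molecular_graph"))
  check_ring_wrap(graph, length(layers))
  if (length(layers) == 0L) return(graph$H0)
  if (is.null(A_hat)) A_hat <- normalized_adjacency(graph)
  H <- graph$H0
  for (params in layers) H <- gcn_layer(H, A_hat, params, training = training)
  H
}

check_ring_wrap <- function(graph, n_layers) {
  if (isTRUE(graph$cyclic) &&
      graph$n_units * graph$backbone_per_unit <= 2 * n_layers) {
    warning(sprintf(
      paste0("awareness range (%d layers) can wrap around the %d-atom backbone ",
             "cycle; increase ring_size or reduce the layer count to preserve ",
             "the infinite-chain equivalence"),
      n_layers, graph$n_units * graph$backbone_per_unit),
      call. = FALSE)
  }
  invisible(TRUE)
}

#' Pool a convolved graph into a fixed-length fingerprint
#'
#' First half: column-wise max over all nodes. Second half: gated weighted
#' sum — each node row is scaled by a learned logistic gate
#' \eqn{g_i = \mathrm{logistic}(h_i \cdot w + c)} and the scaled rows are
#' summed (`sum_mode = "plain"` disables the gate for ablation). Both
#' halves are permutation-invariant and their length is independent of the
#' node count.
#'
#' @param H Convolved node feature matrix (>= 1 node).
#' @param gate_params List with vector `w` (length `ncol(H)`) and scalar
#'   `c`; ignored for `sum_mode = "plain"`.
#' @param sum_mode `"gated"` (default) or `"plain"`.
#' @return Numeric fingerprint of length `2 * ncol(H)`.
#' @export
pool_readout <- function(H, gate_params = NULL, sum_mode = "gated") {
  H <- as.matrix(H)
  if (nrow(H) < 1L) abort("cannot pool an empty graph", "polygcn_validation_error")
  max_half <- apply(H, 2, max)
  if (sum_mode == "plain") {
    sum_half <- colSums(H)
  } else {
    if (is.null(gate_params)) {
      abort("gate_params required for gated readout", "polygcn_validation_error")
    }
    if (length(gate_params$w) != ncol(H)) {
      abort(sprintf("shape mismatch: gate w has length %d but H has %d columns",
                    length(gate_params$w), ncol(H)), "polygcn_shape_error")
    }
    g <- sigmoid(drop(H %*% gate_params$w) + gate_params$c)
    sum_half <- drop(crossprod(H, g))
  }
  c(max_half, sum_half)
}

#' Euclidean distance between two fingerprints
#'
#' @param a,b Fingerprints of equal length.
#' @return Non-negative scalar.
#' @export
fingerprint_distance <- function(a, b) {
  if (length(a) != length(b)) {
    abort(sprintf("shape mismatch: fingerprints of length %d vs %d",
                  length(a), length(b)), "polygcn_shape_error")
  }
  sqrt(sum((a - b)^2))
}

#' Compute the fingerprint of a polymer graph under given parameters
#'
#' Convenience wrapper: [stack_convolutions()] followed by
#' [pool_readout()], in evaluation mode.
#'
#' @param graph A `molecular_graph`.
#' @param params List with elements `conv` (list of layer parameter sets)
#'   and `gate` (list `w`, `c`); e.g. a model's `$params`.
#' @param sum_mode Readout mode, see [pool_readout()].
#' @param per_unit When `TRUE`, the weighted-sum half is divided by the
#'   number of repeat units, giving an intensive per-unit fingerprint — the
#'   scale on which a cyclic graph and a long linear chain describe the
#'   same infinite polymer.
#' @param A_hat Optional precomputed adjacency.
#' @return Numeric fingerprint.
#' @export
polymer_fingerprint <- function(graph, params, sum_mode = "gated",
                                per_unit = FALSE, A_hat = NULL) {
  H <- stack_convolutions(graph, params$conv, training = FALSE, A_hat = A_hat)
  fp <- pool_readout(H, params$gate, sum_mode = sum_mode)
  if (per_unit) {
    d <- length(fp) / 2
    fp[(d + 1):(2 * d)] <- fp[(d + 1):(2 * d)] / graph$n_units
  }
  fp
}

#' Fingerprint convergence of linear chains toward the cyclic representation
#'
#' Builds the cyclic `ring_size` graph and linear chains of increasing
#' length for one repeat unit, computes per-unit fingerprints under fixed
#' random layer weights, and reports the Euclidean distance of each linear
#' chain's fingerprint to the cyclic one (absolute and relative to the
#' cyclic fingerprint norm).
#'
#' @param unit Repeat unit or marked SMILES.
#' @param n_max Longest linear chain to evaluate.
#' @param ring_size Cyclic representation size (default 10).
#' @param n_layers,hidden_dim Architecture of the random convolution stack.
#' @param seed RNG seed for the random weights.
#' @param spec An [atom_feature_spec].
#' @return Data frame with columns `n_units`, `distance`, `relative`.
#' @export
fingerprint_convergence <- function(unit, n_max = 30, ring_size = 10,
                                    n_layers = 4, hidden_dim = 64, seed = 1,
                                    spec = atom_feature_spec()) {
  unit <- as_repeat_unit(unit)
  params <- with_seed(seed, init_gcn_stack(spec$total_dim,
                                           rep(hidden_dim, n_layers)))
  cyc <- build_cyclic_polymer(unit, ring_size, spec)
  fp_c <- polymer_fingerprint(cyc, params, per_unit = TRUE)
  norm_c <- sqrt(sum(fp_c^2))
  res <- lapply(seq_len(n_max), function(n) {
    lin <- build_linear_polymer(unit, n, spec)
    d <- fingerprint_distance(fp_c, polymer_fingerprint(lin, params, per_unit = TRUE))
    data.frame(n_units = n, distance = d, relative = d / norm_c)
  })
  do.call(rbind, res)
}

# random conv stack + gate, drawn from the current RNG stream
init_gcn_stack <- function(in_dim, dims, activation = "relu", dropout = 0.1) {
  conv <- list()
  d_prev <- in_dim
  for (i in seq_along(dims)) {
    conv[[i]] <- gcn_layer_params(d_prev, dims[i], activation, dropout)
    d_prev <- dims[i]
  }
  gate <- list(w = stats::rnorm(d_prev, sd = 1 / sqrt(d_prev)), c = 0)
  list(conv = conv, gate = gate)
}

#' Save or load network parameters as a flat JSON checkpoint
#'
#' The checkpoint is a flat, documented schema — a `format_version` tag,
#' the convolution layers indexed in order (each with `W`, `b`,
#' `activation`, `dropout`), the readout gate, and any fully connected
#' layers — serialized with 17 significant digits so that save/load
#' round-trips are bit-exact.
#'
#' @param params Parameter list (elements `conv`, `gate`, optionally `fc`).
#' @param path File path.
#' @return `save_checkpoint` returns the path invisibly; `load_checkpoint`
#'   returns the parameter list.
#' @export
save_checkpoint <- function(params, path) {
  flat_layer <- function(l) list(
    dim = dim(l$W), W = as.numeric(l$W), b = as.numeric(l$b),
    activation = l$activation, dropout = l$dropout)
  payload <- list(
    format_version = "polygcn-checkpoint-1",
    conv = lapply(params$conv, flat_layer),
    gate = list(w = as.numeric(params$gate$w), c = as.numeric(params$gate$c)),
    fc = lapply(params$fc, flat_layer)
  )
  write_json_exact(payload, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  payload <- read_json(path)
  if (!identical(payload$format_version, "polygcn-checkpoint-1")) {
    abort(sprintf("unsupported checkpoint format: %s", payload$format_version),
          "polygcn_io_error")
  }
  restore_layer <- function(l) list(
    W = matrix(as.numeric(l$W), l$dim[1], l$dim[2]),  # column-major, as stored
    b = as.numeric(l$b), activation = l$activation, dropout = as.numeric(l$dropout))
  list(
    conv = lapply(payload$conv, restore_layer),
    gate = list(w = as.numeric(payload$gate$w), c = as.numeric(payload$gate$c)),
    fc = lapply(payload$fc, restore_layer)
  )
}
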