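#' Polymer graph construction
#'
#' Builders that replicate a repeat unit into a featurized heavy-atom
#' molecular graph: either a finite linear chain (end sites capped with
#' implicit hydrogens) or the cyclic "pseudo-infinite" representation in
#' which the last unit bonds back onto the first. In the cyclic graph every
#' repeat unit has an identical local topology, so — provided no featurizer
#' encodes ring membership and the convolutional awareness range does not
#' wrap around the macrocycle — each node sees exactly what it would see in
#' an infinitely long chain.
#'
#' @name polymer_graph
NULL

# Standard valences used to place implicit hydrogens on the final topology.
.default_valence <- c(C = 4, N = 3, O = 2, S = 2, P = 3,
                      F = 1, Cl = 1, Br = 1, I = 1)

#' Build a linear polymer graph
#'
#' Connects `n_units` copies of the repeat unit head-to-tail through the
#' attachment atoms. The two terminal attachment sites are left open and are
#' satisfied with implicit hydrogens when hydrogen counts are derived, the
#' simplest neutral end cap.
#'
#' @param unit A [repeat_unit] (or marked SMILES string).
#' @param n_units Number of repeat units (>= 1).
#' @param spec An [atom_feature_spec].
#' @return A `molecular_graph`; see [build_cyclic_polymer()] for fields.
#' @examples
#' g <- build_linear_polymer("*CC(*)(C)C(=O)OC", n_units = 5)
#' g$n_nodes  # 35
#' @export
build_linear_polymer <- function(unit, n_units, spec = atom_feature_spec()) {
  unit <- as_repeat_unit(unit)
  check_scalar_number(n_units, "n_units", lower = 1)
  build_polymer_graph(unit, as.integer(n_units), cyclic = FALSE, spec = spec)
}

#' Build the cyclic (pseudo-infinite) polymer graph
#'
#' Connects `ring_size` copies of the repeat unit head-to-tail and closes
#' the macrocycle by bonding the last unit back onto the first. No end caps
#' exist, so corresponding atoms of all units are exactly equivalent.
#'
#' @param unit A [repeat_unit] (or marked SMILES string).
#' @param ring_size Number of repeat units in the macrocycle (>= 3,
#'   default 10).
#' @param spec An [atom_feature_spec].
#' @return An object of class `molecular_graph` with fields `n_nodes`,
#'   `atoms` (element, formal_charge, unit_index, atom_in_unit, degree,
#'   h_count, hybridization, partial_charge), `bonds` (`i`, `j`, `order`,
#'   1-based, stored once per bond), `H0` (node feature matrix), `spec`,
#'   `cyclic`, `n_units`, `k` (atoms per unit) and `backbone_per_unit`.
#' @export
build_cyclic_polymer <- function(unit, ring_size = 10, spec = atom_feature_spec()) {
  unit <- as_repeat_unit(unit)
  check_scalar_number(ring_size, "ring_size", lower = 3)
  build_polymer_graph(unit, as.integer(ring_size), cyclic = TRUE, spec = spec)
}

build_polymer_graph <- function(unit, m, cyclic, spec) {
  k <- unit$k
  n <- m * k
  atoms <- data.frame(
    element = rep(unit$atoms$element, m),
    formal_charge = rep(unit$atoms$formal_charge, m),
    unit_index = rep(seq_len(m), each = k),
    atom_in_unit = rep(seq_len(k), m)
  )
  offs <- rep((seq_len(m) - 1L) * k, each = nrow(unit$bonds))
  bonds <- data.frame(
    i = rep(unit$bonds$i, m) + offs,
    j = rep(unit$bonds$j, m) + offs,
    order = rep(unit$bonds$order, m)
  )
  # head-to-tail: tail attachment atom of unit t bonds the head attachment
  # atom of unit t + 1 (single bonds, vinyl-type backbone)
  if (m > 1L || cyclic) {
    t_from <- seq_len(if (cyclic) m else m - 1L)
    t_to <- if (cyclic) c(seq_len(m)[-1], 1L) else t_from + 1L
    inter <- data.frame(
      i = (t_from - 1L) * k + unit$attach[2],
      j = (t_to - 1L) * k + unit$attach[1],
      order = 1
    )
    bonds <- rbind(bonds, inter)
  }

  graph <- structure(list(
    n_nodes = n, atoms = atoms, bonds = bonds, spec = spec,
    cyclic = cyclic, n_units = m, k = k,
    backbone_per_unit = length(unique(unit$attach)),
    unit_name = unit$name, unit_smiles = unit$smiles
  ), class = "molecular_graph")
  graph <- derive_node_properties(graph)
  graph$H0 <- featurize_atoms(graph, spec)
  graph
}

# degree, implicit H count, hybridization and partial charge, all computed
# on the final (possibly cyclic) topology
derive_node_properties <- function(graph) {
  n <- graph$n_nodes
  b <- graph$bonds
  deg <- tabulate(c(b$i, b$j), nbins = n)
  order_sum <- numeric(n)
  sums <- rowsum(c(b$order, b$order), c(b$i, b$j))
  order_sum[as.integer(rownames(sums))] <- sums[, 1]

  val <- .default_valence[graph$atoms$element]
  val[is.na(val)] <- order_sum[is.na(val)]  # exotic elements: no implicit H
  h <- pmax(0, round(val - order_sum))

  n_double <- n_triple <- numeric(n)
  dd <- b[b$order == 2, ]; tt <- b[b$order == 3, ]
  n_double <- tabulate(c(dd$i, dd$j), nbins = n)
  n_triple <- tabulate(c(tt$i, tt$j), nbins = n)
  hyb <- ifelse(n_triple > 0 | n_double >= 2, "sp",
         ifelse(n_double > 0, "sp2", "sp3"))
  hyb[!graph$atoms$element %in% c("C", "N", "O", "S", "P")] <-
    ifelse(graph$atoms$element[!graph$atoms$element %in% c("C", "N", "O", "S", "P")]
           %in% c("F", "Cl", "Br", "I"), "sp3", "other")

  graph$atoms$degree <- deg
  graph$atoms$h_count <- as.integer(h)
  graph$atoms$hybridization <- hyb
  graph$atoms$partial_charge <-
    partial_charges(graph$atoms$element, graph$atoms$h_count,
                    graph$bonds, graph$atoms$formal_charge)
  graph
}

#' Iterative electronegativity-equalization partial charges
#'
#' A damped charge-transfer iteration in the spirit of classic
#' partial-equalization schemes: each atom carries an electronegativity
#' linear in its current charge, and every bond transfers charge from the
#' less to the more electronegative partner with a damping of 0.5 per
#' round. Implicit hydrogens participate as a pooled pseudo-neighbor.
#' Because information travels one bond per round, `n_iter` rounds give the
#' charges a finite awareness range, preserving the exact unit-to-unit
#' symmetry of cyclic polymer graphs.
#'
#' @param elements Character vector of element symbols.
#' @param h_counts Integer vector of implicit hydrogens per atom.
#' @param bonds Data frame with columns `i`, `j` (1-based, one row per bond).
#' @param formal_charges Starting charges (default all zero).
#' @param n_iter Number of damped rounds (default 6).
#' @return Numeric vector of partial charges.
#' @export
partial_charges <- function(elements, h_counts, bonds,
                            formal_charges = numeric(length(elements)),
                            n_iter = 6) {
  # chi(q) = a + b q; values follow the classic PEOE parameterization
  pars <- list(
    H  = c(7.17, 6.24),  C  = c(7.98, 9.18),  N  = c(11.54, 10.82),
    O  = c(14.18, 12.92), S = c(10.14, 9.13), P  = c(8.90, 8.24),
    F  = c(14.66, 13.85), Cl = c(11.00, 9.69), Br = c(10.08, 8.47),
    I  = c(9.90, 7.96)
  )
  fallback <- c(7.98, 9.18)
  a <- vapply(elements, function(e) if (!is.null(pars[[e]])) pars[[e]][1] else fallback[1], numeric(1))
  bl <- vapply(elements, function(e) if (!is.null(pars[[e]])) pars[[e]][2] else fallback[2], numeric(1))
  aH <- pars$H[1]; bH <- pars$H[2]

  q <- as.numeric(formal_charges)
  qh <- numeric(length(elements))  # charge on each atom's hydrogen pool, per H
  for (t in seq_len(n_iter)) {
    damp <- 0.5^t
    chi <- a + bl * q
    if (nrow(bonds)) {
      chi_i <- chi[bonds$i]; chi_j <- chi[bonds$j]
      flow <- damp * (chi_j - chi_i) / (bl[bonds$i] + bl[bonds$j])
      dq <- rowsum(c(flow, -flow), c(bonds$i, bonds$j))
      idx <- as.integer(rownames(dq))
    } else {
      dq <- NULL
    }
    # hydrogen pool exchange (per attached H)
    chiH <- aH + bH * qh
    flowH <- damp * (chiH - chi) / (bl + bH) * h_counts
    q <- q + flowH
    qh <- qh - ifelse(h_counts > 0, flowH / pmax(h_counts, 1), 0)
    if (!is.null(dq)) q[idx] <- q[idx] + dq[, 1]
  }
  unname(q)
}

#' Symmetric-normalized adjacency with self-loops
#'
#' Computes \eqn{\hat A = \tilde D^{-1/2} \tilde A \tilde D^{-1/2}} where
#' \eqn{\tilde A = A + I} adds a self-loop to every node (self-awareness)
#' and \eqn{\tilde D} is the degree matrix of \eqn{\tilde A}. This is the
#' propagation operator of the graph convolution.
#'
#' @param graph A `molecular_graph`.
#' @return A dense symmetric matrix with entries in \[0, 1\].
#' @export
normalized_adjacency <- function(graph) {
  stopifnot(inherits(graph, "molecular_graph"))
  n <- graph$n_nodes
  A <- matrix(0, n, n)
  if (nrow(graph$bonds)) {
    ij <- cbind(graph$bonds$i, graph$bonds$j)
    A[ij] <- 1
    A[ij[, 2:1, drop = FALSE]] <- 1
  }
  diag(A) <- 1
  d <- rowSums(A)
  inv_sqrt <- 1 / sqrt(d)
  A * outer(inv_sqrt, inv_sqrt)
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("<molecular_graph> %s: %d nodes, %d bonds (%s, %d units x %d atoms)\n",
              x$unit_name, x$n_nodes, nrow(x$bonds),
              if (x$cyclic) "cyclic" else "linear", x$n_units, x$k))
  invisible(x)
}

#' Export a molecular graph for inspection
#'
#' Writes a node table (`node_id`, `element`, `unit_index`, `atom_in_unit`,
#' `degree`, `h_count`, `hybridization`, `formal_charge`, `partial_charge`),
#' an edge table (`i`, `j`, `order`) and optionally a dense dump of the
#' normalized adjacency.
#'
#' @param graph A `molecular_graph`.
#' @param node_path,edge_path CSV output paths.
#' @param adjacency_path Optional path for a whitespace-delimited dump of
#'   [normalized_adjacency()].
#' @return Invisibly, the paths written.
#' @export
write_graph_csv <- function(graph, node_path, edge_path, adjacency_path = NULL) {
  stopifnot(inherits(graph, "molecular_graph"))
  nodes <- cbind(node_id = seq_len(graph$n_nodes),
                 graph$atoms[c("element", "unit_index", "atom_in_unit", "degree",
                               "h_count", "hybridization", "formal_charge",
                               "partial_charge")])
  utils::write.csv(nodes, node_path, row.names = FALSE)
  utils::write.csv(graph$bonds, edge_path, row.names = FALSE)
  paths <- c(node_path, edge_path)
  if (!is.null(adjacency_path)) {
    utils::write.table(normalized_adjacency(graph), adjacency_path,
                       row.names = FALSE, col.names = FALSE)
    paths <- c(paths, adjacency_path)
  }
  invisible(paths)
}
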