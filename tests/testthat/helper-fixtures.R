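# Shared fixtures: built in code at test time, no stored data.

MMA_SMILES <- "*CC(*)(C)C(=O)OC"

mma_unit <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) cached <<- parse_repeat_unit(MMA_SMILES, "methyl methacrylate")
    cached
  }
})

# random undirected simple graph as an edge matrix (each edge once)
random_edges <- function(n_nodes, p = 0.4) {
  pairs <- which(upper.tri(matrix(TRUE, n_nodes, n_nodes)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < p
  pairs[keep, , drop = FALSE]
}

# element-wise oracle for the normalized self-loop adjacency
adjacency_oracle <- function(n_nodes, edges) {
  A <- diag(n_nodes)
  for (r in seq_len(nrow(edges))) {
    A[edges[r, 1], edges[r, 2]] <- 1
    A[edges[r, 2], edges[r, 1]] <- 1
  }
  d <- rowSums(A)
  out <- A
  for (i in seq_len(n_nodes)) for (j in seq_len(n_nodes)) {
    out[i, j] <- A[i, j] / sqrt(d[i] * d[j])
  }
  out
}

# wrap an edge set into a minimal molecular_graph so graph-level ops accept it
toy_graph <- function(n_nodes, edges) {
  structure(list(
    n_nodes = n_nodes,
    bonds = data.frame(i = edges[, 1], j = edges[, 2],
                       order = rep(1, nrow(edges))),
    cyclic = FALSE, n_units = 1L, k = n_nodes, backbone_per_unit = 1L,
    unit_name = "toy", unit_smiles = ""
  ), class = "molecular_graph")
}

# BFS hop distances from a source node over an edge list
hop_distances <- function(n_nodes, bonds, from) {
  adj <- vector("list", n_nodes)
  for (r in seq_len(nrow(bonds))) {
    adj[[bonds$i[r]]] <- c(adj[[bonds$i[r]]], bonds$j[r])
    adj[[bonds$j[r]]] <- c(adj[[bonds$j[r]]], bonds$i[r])
  }
  dist <- rep(Inf, n_nodes)
  dist[from] <- 0
  frontier <- from
  while (length(frontier)) {
    nxt <- unique(unlist(adj[frontier]))
    nxt <- nxt[dist[nxt] == Inf]
    dist[nxt] <- dist[frontier[1]] + 1
    frontier <- nxt
  }
  dist
}

# small, fast model configuration for training tests
tiny_model_config <- function(seed = 1, epochs = 30, ...) {
  model_config(conv_dims = c(32L, 32L), fc_dims = c(32L, 16L),
               epochs = epochs, seed = seed, ...)
}

# small synthetic dataset (subset of the battery keeps graphs cheap)
tiny_clean_dataset <- function(seed = 7, n_units = 4, n = NULL) {
  battery <- default_monomer_battery()[seq_len(n_units), ]
  cfg <- synth_config(battery = battery, seed = seed)
  generate_clean_dataset(cfg, n = n)
}
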