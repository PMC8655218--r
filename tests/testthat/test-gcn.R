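test_that("graph convolution matches its closed forms", {
  # two-node path with identity weights reproduces the averaged adjacency
  A_hat <- matrix(0.5, 2, 2)
  p <- list(W = diag(2), b = c(0, 0), activation = "identity", dropout = 0)
  expect_equal(gcn_layer(diag(2), A_hat, p), matrix(0.5, 2, 2))

  # zero weights: every row collapses to the bias
  set.seed(1)
  e <- random_edges(6); g <- toy_graph(6, e)
  H <- matrix(rnorm(6 * 3), 6, 3)
  pz <- list(W = matrix(0, 3, 4), b = c(1, -2, 0.5, 3), activation = "identity",
             dropout = 0)
  out <- gcn_layer(H, normalized_adjacency(g), pz)
  expect_equal(out, matrix(rep(pz$b, each = 6), 6, 4))

  expect_error(gcn_layer(H, matrix(0, 5, 5), pz), class = "polygcn_shape_error")
  expect_error(gcn_layer(H[, 1:2], normalized_adjacency(g), pz),
               class = "polygcn_shape_error")
})

test_that("matrix-form convolution equals the per-node message-passing oracle", {
  set.seed(11)
  for (rep in 1:30) {
    n <- sample(2:12, 1)
    e <- random_edges(n)
    A_hat <- normalized_adjacency(toy_graph(n, e))
    d_in <- sample(2:6, 1); d_out <- sample(2:6, 1)
    H <- matrix(rnorm(n * d_in), n, d_in)
    p <- list(W = matrix(rnorm(d_in * d_out), d_in, d_out), b = rnorm(d_out),
              activation = "relu", dropout = 0)
    got <- gcn_layer(H, A_hat, p)
    # oracle: each node sums adjacency-weighted neighbor-plus-self messages
    oracle <- matrix(0, n, d_out)
    for (i in seq_len(n)) {
      msg <- numeric(d_in)
      for (j in seq_len(n)) msg <- msg + A_hat[i, j] * H[j, ]
      oracle[i, ] <- pmax(drop(msg %*% p$W) + p$b, 0)
    }
    expect_lt(max(abs(got - oracle)), 1e-6)
  }
})

test_that("stacking zero layers returns H0; convolution respects locality", {
  mma <- mma_unit()
  g <- build_linear_polymer(mma, 8)
  expect_identical(stack_convolutions(g, list()), g$H0)

  n_layers <- 3
  params <- polygcn:::with_seed(5, polygcn:::init_gcn_stack(g$spec$total_dim,
                                                            rep(16, n_layers)))
  A_hat <- normalized_adjacency(g)
  run <- function(H0) {
    H <- H0
    for (p in params$conv) H <- gcn_layer(H, A_hat, p)
    H
  }
  base <- run(g$H0)
  H0p <- g$H0
  target <- 1L  # perturb the first atom's features
  H0p[target, ] <- H0p[target, ] + 0.37
  pert <- run(H0p)
  dist <- hop_distances(g$n_nodes, g$bonds, target)
  far <- dist > n_layers
  expect_true(any(far))
  expect_identical(pert[far, ], base[far, ])          # bit-identical beyond range
  expect_gt(max(abs(pert[!far, ] - base[!far, ])), 0) # and felt within range
})

test_that("all repeat units convolve identically on the cyclic graph", {
  g <- build_cyclic_polymer(mma_unit(), 10)
  params <- polygcn:::with_seed(9, polygcn:::init_gcn_stack(g$spec$total_dim,
                                                            c(32, 32, 32)))
  H <- stack_convolutions(g, params$conv)
  for (pos in seq_len(g$k)) {
    rows <- H[g$atoms$atom_in_unit == pos, , drop = FALSE]
    expect_lt(max(abs(sweep(rows, 2, rows[1, ]))), 1e-6)
  }
})

test_that("readout is permutation-invariant, size-independent and additive", {
  set.seed(21)
  H <- matrix(rnorm(9 * 5), 9, 5)
  gate <- list(w = rnorm(5), c = 0.3)
  fp <- pool_readout(H, gate)
  expect_length(fp, 10)

  perm <- sample(9)
  fp_perm <- pool_readout(H[perm, ], gate)
  expect_identical(fp_perm[1:5], fp[1:5])              # max half: bit-exact
  expect_equal(fp_perm, fp, tolerance = 1e-12)         # sum half: reassociation only

  # single node: max half is the row; sum half is gate(row) * row
  h1 <- H[4, , drop = FALSE]
  g1 <- 1 / (1 + exp(-(sum(h1 * gate$w) + gate$c)))
  expect_equal(pool_readout(h1, gate), c(h1, g1 * h1))

  # duplicated graph: max half unchanged, weighted-sum half doubled
  fp2 <- pool_readout(rbind(H, H), gate)
  expect_equal(fp2[1:5], fp[1:5])
  expect_equal(fp2[6:10], 2 * fp[6:10])

  expect_error(pool_readout(H[0, , drop = FALSE], gate),
               class = "polygcn_validation_error")
  expect_error(pool_readout(H, list(w = rnorm(3), c = 0)),
               class = "polygcn_shape_error")
})

test_that("fingerprint distance is the Euclidean norm of the difference", {
  expect_identical(fingerprint_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_identical(fingerprint_distance(c(0, 0), c(3, 4)), 5)
  expect_error(fingerprint_distance(1:3, 1:4), class = "polygcn_shape_error")
})

test_that("linear-chain fingerprints approach the cyclic representation monotonically", {
  res <- fingerprint_convergence(MMA_SMILES, n_max = 20, n_layers = 3,
                                 hidden_dim = 24, seed = 2)
  # beyond small n the distance is non-increasing and keeps decaying
  tail_rel <- res$relative[8:20]
  expect_true(all(diff(tail_rel) <= 1e-12))
  expect_lt(res$relative[20], res$relative[8])
})

test_that("checkpoints round-trip bit-exactly through the flat JSON schema", {
  params <- polygcn:::with_seed(3, {
    p <- polygcn:::init_gcn_stack(12, c(8, 6))
    p$fc <- list(list(W = polygcn:::glorot(15, 4), b = rnorm(4),
                      activation = "relu", dropout = 0.1),
                 list(W = polygcn:::glorot(4, 1), b = 0.5,
                      activation = "identity", dropout = 0))
    p
  })
  path <- tempfile(fileext = ".json")
  save_checkpoint(params, path)
  restored <- load_checkpoint(path)
  expect_identical(restored$conv, params$conv)
  expect_identical(restored$gate, params$gate)
  expect_identical(restored$fc, params$fc)
  expect_error(load_checkpoint(tempfile()), class = "polygcn_io_error")
})
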