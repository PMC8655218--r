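test_that("repeat-unit parsing validates markers and counts heavy atoms", {
  mma <- mma_unit()
  expect_s3_class(mma, "repeat_unit")
  expect_identical(mma$k, 7L)          # de-marked methyl methacrylate
  expect_length(mma$attach, 2)
  expect_true(all(mma$attach >= 1 & mma$attach <= mma$k))

  single <- parse_repeat_unit("*C*")   # methylene backbone: both markers on one atom
  expect_identical(single$k, 1L)

  expect_error(parse_repeat_unit("CC(C)C(=O)OC"), "found 0")
  expect_error(parse_repeat_unit("*CC(C)C(=O)OC"), "found 1")
  expect_error(parse_repeat_unit(""), class = "polygcn_validation_error")
})

test_that("linear builder replicates units head-to-tail with hydrogen end caps", {
  mma <- mma_unit()
  g1 <- build_linear_polymer(mma, 1)
  expect_identical(g1$n_nodes, 7L)
  # n = 1: intra-unit edge set equals the de-marked molecule's bond set
  expect_equal(g1$bonds[c("i", "j")], mma$bonds[c("i", "j")], ignore_attr = TRUE)

  g50 <- build_linear_polymer(mma, 50)
  expect_identical(g50$n_nodes, 350L)
  n_inter <- sum(g50$bonds$i > 0 &
                   g50$atoms$unit_index[g50$bonds$i] != g50$atoms$unit_index[g50$bonds$j])
  expect_identical(n_inter, 49L)

  # terminal attachment atoms gain an implicit hydrogen relative to interior
  interior_h <- g50$atoms$h_count[g50$atoms$unit_index == 25]
  terminal_h <- g50$atoms$h_count[g50$atoms$unit_index == 1]
  expect_identical(sum(terminal_h) - sum(interior_h), 1L)
})

test_that("cyclic builder closes the macrocycle and is unit-transitive", {
  for (m in c(3L, 5L, 10L)) {
    g <- build_cyclic_polymer(mma_unit(), m)
    expect_identical(g$n_nodes, m * 7L)  # |N| = ring_size * k
    inter <- g$atoms$unit_index[g$bonds$i] != g$atoms$unit_index[g$bonds$j]
    expect_identical(sum(inter), as.integer(m))
    # degrees at corresponding positions identical across all units
    deg <- matrix(g$atoms$degree, nrow = 7)
    expect_true(all(deg == deg[, 1]))
  }
  expect_error(build_cyclic_polymer(mma_unit(), 2), class = "polygcn_validation_error")

  # interior unit of a long chain has the same within-unit bonds as a cyclic unit
  gc <- build_cyclic_polymer(mma_unit(), 10)
  gl <- build_linear_polymer(mma_unit(), 10)
  intra <- function(g, u) {
    b <- g$bonds[g$atoms$unit_index[g$bonds$i] == u & g$atoms$unit_index[g$bonds$j] == u, ]
    b$i <- (b$i - 1) %% g$k + 1; b$j <- (b$j - 1) %% g$k + 1
    b[order(b$i, b$j), c("i", "j", "order")]
  }
  expect_equal(intra(gc, 4), intra(gl, 5), ignore_attr = TRUE)
})

test_that("cyclic feature rows are exactly identical across repeat units", {
  g <- build_cyclic_polymer(mma_unit(), 10)
  for (pos in seq_len(g$k)) {
    rows <- g$H0[g$atoms$atom_in_unit == pos, , drop = FALSE]
    expect_true(all(rows == rep(rows[1, ], each = nrow(rows))))
  }
})

test_that("featurization produces valid one-hot blocks after topology is final", {
  spec <- atom_feature_spec()
  g <- build_cyclic_polymer(mma_unit(), 5, spec)
  H <- featurize_atoms(g, spec)
  expect_identical(dim(H), c(35L, spec$total_dim))
  # block boundaries: element (10), degree (6), charge (1), hyb (4), H (5), pc (1)
  elem <- H[, 1:10]; hyb <- H[, 18:21]; hc <- H[, 22:26]
  expect_true(all(rowSums(elem) == 1))
  expect_true(all(rowSums(hyb) == 1))
  expect_true(all(rowSums(hc) == 1))
  # carbonyl oxygen (element O, sp2), ester oxygen (O, sp3), quaternary C (sp3, 0 H)
  o_sp2 <- which(g$atoms$element == "O" & g$atoms$hybridization == "sp2")[1]
  expect_equal(H[o_sp2, 3], 1)   # element block: O slot
  expect_equal(H[o_sp2, 19], 1)  # hybridization block: sp2 slot
  cq <- which(g$atoms$degree == 4)[1]
  expect_equal(H[cq, 20], 1)     # sp3
  expect_equal(H[cq, 22], 1)     # 0 hydrogens
})

test_that("ring-membership featurizers are rejected", {
  expect_error(atom_feature_spec(c("element", "ring_membership")),
               "ring-membership")
  expect_error(atom_feature_spec(c("element", "in_ring_size")),
               "ring-membership")
  expect_error(atom_feature_spec(c("element", "nonsense")), "unknown featurizer")
})

test_that("normalized adjacency matches its closed forms and element-wise oracle", {
  # single node: just the self-loop
  g1 <- toy_graph(1, matrix(numeric(0), 0, 2))
  expect_equal(normalized_adjacency(g1), matrix(1, 1, 1))
  # two nodes, one edge: all entries 1/2
  g2 <- toy_graph(2, matrix(c(1, 2), 1, 2))
  expect_equal(normalized_adjacency(g2), matrix(0.5, 2, 2))

  set.seed(404)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    e <- random_edges(n)
    A_hat <- normalized_adjacency(toy_graph(n, e))
    expect_identical(A_hat, t(A_hat))          # exact symmetry
    expect_true(all(A_hat >= 0 & A_hat <= 1))
    expect_equal(A_hat, adjacency_oracle(n, e), tolerance = 1e-12)
  }
})

test_that("awareness-range wrap around the macrocycle triggers a warning", {
  g <- build_cyclic_polymer(mma_unit(), 3)  # 6-atom backbone cycle
  layers <- replicate(3, gcn_layer_params(g$spec$total_dim, 4, init = "zero"),
                      simplify = FALSE)
  layers[[2]]$W <- matrix(0, 4, 4); layers[[3]]$W <- matrix(0, 4, 4)
  expect_warning(stack_convolutions(g, layers), "wrap")
  g10 <- build_cyclic_polymer(mma_unit(), 10)
  layers10 <- list(gcn_layer_params(g10$spec$total_dim, 4, init = "zero"))
  expect_silent(stack_convolutions(g10, layers10))
})

test_that("graph CSV export round-trips nodes and edges", {
  g <- build_cyclic_polymer(mma_unit(), 3)
  np <- tempfile(fileext = ".csv"); ep <- tempfile(fileext = ".csv")
  ap <- tempfile(fileext = ".txt")
  write_graph_csv(g, np, ep, ap)
  nodes <- read.csv(np); edges <- read.csv(ep)
  expect_identical(nrow(nodes), g$n_nodes)
  expect_identical(nrow(edges), nrow(g$bonds))
  A <- as.matrix(read.table(ap))
  expect_equal(unname(A), normalized_adjacency(g), tolerance = 1e-12)
})
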