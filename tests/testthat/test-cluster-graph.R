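# Molecule graphs, connected clusters, distance matrices, size kinetics.

test_that("the molecule graph is simple and roster-validated", {
  g <- buildGraph(data.frame(molecule_a = integer(), molecule_b = integer()),
                  roster = 1:5)
  expect_equal(igraph::gorder(g), 5)
  expect_equal(igraph::gsize(g), 0)
  # two site-bonds between the same molecule pair collapse to one edge
  g2 <- buildGraph(data.frame(molecule_a = c(1, 1), molecule_b = c(2, 2)), 1:3)
  expect_equal(igraph::gsize(g2), 1)
  # random bond lists: edge set equals the unique-pair collapse oracle
  for (seed in 1:3) {
    e <- random_edges(20, 40, seed)
    g3 <- buildGraph(data.frame(molecule_a = e[, 1], molecule_b = e[, 2]), 1:20)
    want <- unique(t(apply(e, 1, sort)))
    expect_equal(igraph::gsize(g3), nrow(want))
  }
  expect_error(buildGraph(data.frame(molecule_a = 9, molecule_b = 1), 1:5),
               "roster")
})

test_that("connected clusters partition the roster like union-find", {
  # edgeless graph: N singletons
  g <- buildGraph(data.frame(molecule_a = integer(), molecule_b = integer()),
                  1:7)
  cl <- connectedClusters(g)
  expect_equal(lengths(cl), rep(1, 7))
  # chain of k molecules: one cluster of size k
  g2 <- buildGraph(data.frame(molecule_a = 1:5, molecule_b = 2:6), 1:6)
  expect_equal(connectedClusters(g2), list(1:6))
  # random graphs vs an independent union-find
  for (seed in 4:8) {
    n <- 40
    e <- random_edges(n, 25, seed)
    g3 <- buildGraph(data.frame(molecule_a = e[, 1], molecule_b = e[, 2]),
                     1:n)
    got <- connectedClusters(g3)
    want <- oracle_union_find(1:n, e)
    key <- function(p) sort(vapply(p, paste, "", collapse = ","))
    expect_identical(key(got), key(want))
    # partition property: sizes sum to the molecule count
    expect_equal(sum(lengths(got)), n)
    # ordering: decreasing size, ties by smallest member
    sz <- lengths(got)
    expect_true(all(diff(sz) <= 0))
  }
  # monotonicity: adding an edge never increases the component count
  e <- random_edges(30, 10, 9)
  gA <- buildGraph(data.frame(molecule_a = e[, 1], molecule_b = e[, 2]), 1:30)
  nA <- length(connectedClusters(gA))
  e2 <- rbind(e, c(1, 30))
  gB <- buildGraph(data.frame(molecule_a = e2[, 1], molecule_b = e2[, 2]), 1:30)
  expect_lte(length(connectedClusters(gB)), nA)
})

test_that("topological distances equal Floyd-Warshall and obey the triangle
          inequality", {
  g <- buildGraph(data.frame(molecule_a = 1:3, molecule_b = 2:4), 1:4)
  d <- topologicalDistanceMatrix(g)
  expect_equal(max(d), 3)
  expect_equal(unname(diag(d)), rep(0, 4))
  # disconnected pair: unreachable marker
  g2 <- buildGraph(data.frame(molecule_a = 1, molecule_b = 2), 1:3)
  d2 <- topologicalDistanceMatrix(g2)
  expect_true(is.infinite(d2[1, 3]))
  expect_equal(d2, t(d2))
  # random graphs up to 50 nodes against the independent all-pairs oracle
  for (seed in 1:3) {
    n <- 50
    e <- random_edges(n, 60, seed + 20)
    g3 <- buildGraph(data.frame(molecule_a = e[, 1], molecule_b = e[, 2]),
                     1:n)
    adj <- matrix(0, n, n)
    adj[e] <- 1; adj[e[, 2:1]] <- 1
    expect_equal(unname(topologicalDistanceMatrix(g3)),
                 oracle_floyd_warshall(adj))
  }
  # triangle inequality, exhaustively on a <= 30-node graph
  e <- random_edges(25, 35, 31)
  g4 <- buildGraph(data.frame(molecule_a = e[, 1], molecule_b = e[, 2]), 1:25)
  d4 <- topologicalDistanceMatrix(g4)
  ok <- TRUE
  for (k in 1:25) {
    via <- outer(d4[, k], d4[k, ], "+")
    ok <- ok && all(d4 <= via + 1e-9 | !is.finite(via))
  }
  expect_true(ok)
})

test_that("clustergram ordering groups each component contiguously", {
  # two disjoint cliques
  cl1 <- t(combn(1:4, 2)); cl2 <- t(combn(5:9, 2))
  e <- rbind(cl1, cl2)
  g <- buildGraph(data.frame(molecule_a = e[, 1], molecule_b = e[, 2]), 1:9)
  d <- topologicalDistanceMatrix(g)
  ord <- clustergramOrder(d)
  lab <- as.integer(ord$labels)
  memb <- lab <= 4
  expect_true(all(diff(which(memb)) == 1))    # clique 1 contiguous
  expect_true(all(diff(which(!memb)) == 1))   # clique 2 contiguous
  # reordered matrix is block-diagonal: off-block entries all unreachable
  m <- ord$matrix
  expect_true(all(is.infinite(m[memb, !memb])))
  # singleton graph: identity permutation
  g1 <- buildGraph(data.frame(molecule_a = integer(), molecule_b = integer()),
                   1)
  expect_equal(clustergramOrder(topologicalDistanceMatrix(g1))$order, 1L)
  # random two-component graph: blocks match component labels
  eA <- cbind(1:9, c(2:9, 1)); eB <- cbind(10:19, c(11:19, 10))
  e2 <- rbind(eA, eB)
  g2 <- buildGraph(data.frame(molecule_a = e2[, 1], molecule_b = e2[, 2]),
                   1:19)
  ord2 <- clustergramOrder(topologicalDistanceMatrix(g2))
  labs <- as.integer(ord2$labels) <= 9
  expect_true(all(diff(which(labs)) == 1))
})

test_that("size kinetics aggregates largest and mean cluster sizes", {
  singles <- replicate(6, list(1), simplify = FALSE)
  allone <- list(list(1:6))
  partitions <- list(lapply(1:6, function(i) i), allone[[1]])
  kin <- sizeKinetics(partitions, times = c(0, 1))
  expect_equal(kin$largest, c(1, 6))
  expect_equal(kin$mean, c(1, 6))
  # synthetic partition stream vs hand-computed aggregates
  p <- list(list(1:3, 4:5, 6), list(1:4, 5:6))
  kin2 <- sizeKinetics(p, times = c(0, 1))
  expect_equal(kin2$largest, c(3, 4))
  expect_equal(kin2$mean, c(mean(c(3, 2, 1)), mean(c(4, 2))))
  kin3 <- sizeKinetics(p, times = c(0, 1), includeSingletons = FALSE)
  expect_equal(kin3$mean, c(mean(c(3, 2)), mean(c(4, 2))))
  h <- clusterSizeHistogram(p[[1]])
  expect_equal(h, data.frame(size = c(1, 2, 3), count = c(1L, 1L, 1L)))
})

test_that("power-law fits recover known growth exponents", {
  t <- seq(0.01, 0.5, length.out = 50)
  expect_equal(fitPowerLaw(t, t^0.5, window = c(0, 0.5))$alpha, 0.5,
               tolerance = 1e-9)
  expect_equal(fitPowerLaw(t, rep(3, 50), window = c(0, 0.5))$alpha, 0,
               tolerance = 1e-9)
  # 5% multiplicative noise around alpha = 0.8: recovered within 0.05
  set.seed(42)
  y <- 2 * t^0.8 * exp(rnorm(50, sd = 0.05))
  expect_equal(fitPowerLaw(t, y, window = c(0, 0.5))$alpha, 0.8,
               tolerance = 0.0625)
  expect_error(fitPowerLaw(t[1:3], t[1:3], window = c(0, 0.5)), "fewer")
  expect_error(fitPowerLaw(t, c(-1, (t^2)[-1]), window = c(0, 0.5)),
               "non-positive")
})
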