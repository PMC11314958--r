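test_that("shortest paths match hand values and handle disconnection", {
  expect_equal(shortestPathLengths(toyGraph("p3"))[1, 3], 2)
  dyads <- matrix(0, 4, 4)
  dyads[1, 2] <- dyads[2, 1] <- dyads[3, 4] <- dyads[4, 3] <- 1
  d <- shortestPathLengths(dyads)
  expect_equal(d[1, 3], Inf)
  expect_equal(d[2, 4], Inf)
  expect_equal(d[1, 2], 1)
})

test_that("BFS distances equal the Floyd-Warshall oracle on random graphs", {
  set.seed(31)
  for (b in 1:60) {
    n <- sample(4:30, 1)
    a <- randomAdjacency(n, runif(1, 0.05, 0.5))
    expect_equal(shortestPathLengths(a), oracleFloydWarshall(a))
  }
})

test_that("global efficiency matches closed forms", {
  expect_equal(globalEfficiency(toyGraph("k4")), 1)
  expect_equal(globalEfficiency(toyGraph("p3")), 5 / 6)
  expect_equal(globalEfficiency(toyGraph("star4")), 0.75)
  expect_error(globalEfficiency(matrix(0, 1, 1)), "at least 2")
})

test_that("clustering matches closed forms and triangle enumeration", {
  expect_equal(nodalClustering(toyGraph("triangle")), rep(1, 3))
  expect_equal(nodalClustering(toyGraph("star4")), rep(0, 4))
  k4m <- toyGraph("k4"); k4m[1, 2] <- k4m[2, 1] <- 0
  expect_equal(meanClustering(k4m), (2 / 3 + 2 / 3 + 1 + 1) / 4)
  set.seed(32)
  for (b in 1:40) {
    a <- randomAdjacency(sample(4:25, 1), runif(1, 0.1, 0.6))
    expect_equal(nodalClustering(a), oracleClustering(a))
  }
})

test_that("eigenvector centrality matches closed forms", {
  expect_equal(eigenvectorCentrality(toyGraph("c5")), rep(1 / sqrt(5), 5))
  ec <- eigenvectorCentrality(toyGraph("star4"))
  expect_equal(ec, c(sqrt(3 / 6), rep(1 / sqrt(6), 3)))
  expect_equal(max(eigenvectorCentrality(toyGraph("star4"), norm = "max")), 1)
  expect_error(eigenvectorCentrality(matrix(0, 3, 3)), "edgeless")
})

test_that("eigenvector centrality matches power iteration on random connected graphs", {
  set.seed(33)
  for (b in 1:60) {
    n <- sample(5:30, 1)
    a <- randomConnectedAdjacency(n, runif(1, 0.05, 0.4))
    expect_equal(eigenvectorCentrality(a), oraclePowerIteration(a),
                 tolerance = 1e-8)
  }
})

test_that("degenerate twin components resolve on the smallest-index component", {
  # two disjoint triangles share the leading eigenvalue 2
  a <- matrix(0, 6, 6)
  a[1:3, 1:3] <- toyGraph("triangle")
  a[4:6, 4:6] <- toyGraph("triangle")
  expect_message(ec <- eigenvectorCentrality(a), "degenerate")
  expect_equal(ec[1:3], rep(1 / sqrt(3), 3))
  expect_equal(ec[4:6], rep(0, 3))
})

test_that("metrics are invariant under node relabeling", {
  set.seed(34)
  for (b in 1:10) {
    n <- 15
    a <- randomConnectedAdjacency(n, 0.2)
    perm <- sample(n)
    ap <- a[perm, perm]
    expect_equal(globalEfficiency(ap), globalEfficiency(a))
    expect_equal(nodalClustering(ap), nodalClustering(a)[perm])
    expect_equal(eigenvectorCentrality(ap),
                 eigenvectorCentrality(a)[perm], tolerance = 1e-8)
  }
})

test_that("global efficiency is monotone under edge addition and always finite", {
  set.seed(35)
  for (b in 1:25) {
    a <- randomAdjacency(12, 0.2)
    ge <- globalEfficiency(a)
    expect_true(is.finite(ge) && ge >= 0 && ge <= 1)
    zeros <- which(a == 0 & upper.tri(a), arr.ind = TRUE)
    if (nrow(zeros) == 0) next
    e <- zeros[sample(nrow(zeros), 1), ]
    a2 <- a; a2[e[1], e[2]] <- a2[e[2], e[1]] <- 1
    expect_gte(globalEfficiency(a2), ge)
  }
})

test_that("mean clustering of G(n, p) is near p", {
  set.seed(36)
  n <- 120; p <- 0.3
  cc <- replicate(12, meanClustering(randomAdjacency(n, p)))
  # per-node cc has ~binomial sampling noise; 3 SEs of the replicate mean
  expect_lt(abs(mean(cc) - p), 3 * sd(cc) / sqrt(length(cc)) + 0.01)
})

test_that("metrics agree with igraph as an independent implementation", {
  skip_if_not_installed("igraph")
  set.seed(37)
  for (b in 1:10) {
    a <- randomConnectedAdjacency(sample(8:25, 1), 0.2)
    ig <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
    expect_equal(globalEfficiency(a), igraph::global_efficiency(ig))
    expect_equal(nodalClustering(a),
                 ifelse(is.nan(igraph::transitivity(ig, type = "local")), 0,
                        igraph::transitivity(ig, type = "local")))
    ecIg <- igraph::eigen_centrality(ig)$vector
    expect_equal(eigenvectorCentrality(a, norm = "max"), unname(ecIg),
                 tolerance = 1e-6)
  }
})
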