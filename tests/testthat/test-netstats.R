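test_that("clustering coefficient on canonical graphs", {
  expect_equal(clusteringCoefficient(igraph::make_full_graph(5)), 1)
  expect_equal(clusteringCoefficient(igraph::make_star(5, mode = "undirected")), 0)
  expect_error(clusteringCoefficient(igraph::make_empty_graph(0, directed = FALSE)),
               "empty")
})

test_that("characteristic path length on canonical graphs", {
  expect_equal(as.numeric(characteristicPathLength(igraph::make_full_graph(5))), 1)
  # P4 ordered pairs: {1,1,1,2,2,3} -> 5/3
  p4 <- igraph::make_ring(4, circular = FALSE)
  expect_equal(as.numeric(characteristicPathLength(p4)), 5 / 3)
  expect_error(
    characteristicPathLength(igraph::make_empty_graph(3, directed = FALSE)),
    "reachable")
})

test_that("unreachable pairs are excluded and counted", {
  g <- igraph::disjoint_union(igraph::make_full_graph(3), igraph::make_full_graph(3))
  L <- characteristicPathLength(g)
  expect_equal(as.numeric(L), 1)
  expect_equal(attr(L, "unreachablePairs"), 9)
})

test_that("betweenness on canonical graphs", {
  b <- betweennessCentrality(igraph::make_star(5, mode = "undirected"))
  expect_equal(unname(b), c(6, 0, 0, 0, 0))   # (4*3)/2 pair-paths
  b4 <- betweennessCentrality(igraph::make_ring(4, circular = FALSE))
  expect_equal(unname(b4), c(0, 2, 2, 0))
})

test_that("graph statistics match brute-force oracles on seeded graphs", {
  for (seed in 1:8) {
    g <- random_test_graph(n = 12 + (seed %% 9), p = 0.3, seed = seed)
    A <- adj_of(g)
    expect_equal(clusteringCoefficient(g), oracle_clustering(A),
                 tolerance = 1e-12)
    if (igraph::ecount(g) > 0 && any(rowSums(A) > 0)) {
      expect_equal(as.numeric(characteristicPathLength(g)),
                   oracle_charpath(A), tolerance = 1e-12)
    }
    expect_equal(unname(betweennessCentrality(g)), oracle_betweenness(A),
                 tolerance = 1e-9)
  }
})

test_that("randomization preserves the degree sequence", {
  set.seed(41)
  for (i in 1:10) {
    g <- igraph::sample_gnp(30, 0.15)
    if (igraph::ecount(g) < 2) next
    gr <- suppressWarnings(degreePreservingRandomize(g, 10, seed = i))
    expect_identical(sort(igraph::degree(gr)), sort(igraph::degree(g)))
    expect_true(igraph::is_simple(gr))
  }
})

test_that("randomized clustering approaches the density expectation", {
  set.seed(5)
  g <- igraph::sample_smallworld(1, 200, 5, 0.05)
  cr <- mean(vapply(1:20, function(i)
    clusteringCoefficient(degreePreservingRandomize(g, 10, seed = i)),
    numeric(1)))
  expectation <- mean(igraph::degree(g)) / 200
  expect_lt(abs(cr - expectation) / expectation, 0.25)
})

test_that("impossible swaps return the input with a warning", {
  star <- igraph::make_star(6, mode = "undirected")
  expect_warning(gr <- degreePreservingRandomize(star, 10, seed = 1),
                 "no degree-preserving swap")
  expect_identical(sort(igraph::degree(gr)), sort(igraph::degree(star)))
  expect_warning(latticize(star, 10, seed = 1), "no degree-preserving swap")
})

test_that("null models are reproducible for a fixed seed", {
  set.seed(43)
  g <- igraph::sample_gnm(40, 120)
  e1 <- igraph::as_edgelist(degreePreservingRandomize(g, 10, seed = 9))
  e2 <- igraph::as_edgelist(degreePreservingRandomize(g, 10, seed = 9))
  expect_identical(e1, e2)
  l1 <- igraph::as_edgelist(latticize(g, 10, seed = 9))
  l2 <- igraph::as_edgelist(latticize(g, 10, seed = 9))
  expect_identical(l1, l2)
})

test_that("latticization preserves degrees and raises clustering", {
  set.seed(44)
  g <- igraph::sample_smallworld(1, 200, 5, 0.1)
  c0 <- clusteringCoefficient(g)
  hits <- 0L
  for (i in 1:20) {
    gl <- latticize(g, 10, seed = i)
    expect_identical(sort(igraph::degree(gl)), sort(igraph::degree(g)))
    if (clusteringCoefficient(gl) >= c0) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("small-worldness indices separate canonical topologies", {
  set.seed(7)
  ws <- igraph::sample_smallworld(1, 1000, 5, 0.05)
  sw <- smallWorldness(ws, nNull = 10, iterationsPerEdge = 10, seed = 2)
  expect_gt(sw@S, 2)
  expect_lt(abs(sw@omega), 0.35)

  set.seed(8)
  er <- igraph::sample_gnm(1000, igraph::ecount(ws))
  se <- smallWorldness(er, nNull = 5, iterationsPerEdge = 10, seed = 3)
  expect_gt(se@S, 0.8); expect_lt(se@S, 1.3)
  expect_gt(se@omega, 0.5)

  ring <- igraph::sample_smallworld(1, 300, 5, 0)
  sr <- smallWorldness(ring, nNull = 5, iterationsPerEdge = 10, seed = 4)
  expect_lt(sr@omega, -0.5)
})

test_that("small-worldness is bit-reproducible for a fixed seed", {
  set.seed(45)
  g <- igraph::sample_smallworld(1, 100, 3, 0.1)
  s1 <- smallWorldness(g, nNull = 3, seed = 11)
  s2 <- smallWorldness(g, nNull = 3, seed = 11)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
})

test_that("community detection and modularity identities", {
  g <- igraph::disjoint_union(igraph::make_full_graph(5), igraph::make_full_graph(5))
  cm <- detectCommunities(g)
  expect_equal(cm$Q, 0.5)
  expect_identical(length(cm$membership), 10L)
  expect_identical(length(unique(cm$membership)), 2L)
  # trivial one-block partition has zero modularity
  expect_equal(partitionModularity(g, rep(1, 10)), 0)
  # edgeless graph: singleton communities, Q = 0
  e <- detectCommunities(igraph::make_empty_graph(4, directed = FALSE))
  expect_identical(unname(e$membership), 1:4)
  expect_identical(e$Q, 0)
})

test_that("returned modularity matches the direct formula", {
  for (seed in 1:5) {
    g <- random_test_graph(15, 0.3, seed = seed + 50)
    if (igraph::ecount(g) == 0) next
    cm <- detectCommunities(g)
    expect_equal(cm$Q, oracle_modularity(adj_of(g), cm$membership),
                 tolerance = 1e-12)
  }
})
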