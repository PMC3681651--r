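test_that("window slicing arithmetic and shape", {
  r <- SpikeRaster(matrix(0L, 3, 1000))
  w <- sliceWindows(r, 250, 0.5)
  expect_length(w, 7)                       # (1000 - 250)/125 + 1
  expect_true(all(vapply(w, nBins, integer(1)) == 250L))
  w0 <- sliceWindows(r, 250, 0)
  expect_length(w0, 4)                      # disjoint tiling
  expect_error(sliceWindows(r, 2000, 0.5), "longer than the recording")
})

test_that("LFP windows slice by time", {
  lfp <- LFPSet(matrix(rnorm(2000 * 2), ncol = 2), samplingRate = 1000)
  w <- sliceWindows(lfp, 500, 0.5)
  expect_length(w, 7)
  expect_identical(nrow(signalMatrix(w[[1]])), 500L)
})

make_adj <- function(w, units = NULL) {
  n <- nrow(w); diag(w) <- 0
  new("FunctionalAdjacency", weights = w,
      units = if (is.null(units)) paste0("u", seq_len(n)) else units,
      regions = rep("R1", n), windowId = 1L, method = "ncs")
}

test_that("percentile binarization keeps the top pairs deterministically", {
  set.seed(31)
  w <- matrix(runif(100), 10, 10); w <- (w + t(w)) / 2
  fg <- binarize(make_adj(w), mode = "percentile", theta = 90)
  expect_identical(igraph::ecount(asIgraph(fg)), 5)   # ceil(0.10 * 45)
  # all-equal weights: deterministic lexicographic tie-break
  weq <- matrix(0.5, 10, 10)
  g1 <- asIgraph(binarize(make_adj(weq), theta = 90))
  g2 <- asIgraph(binarize(make_adj(weq), theta = 90))
  expect_identical(igraph::as_edgelist(g1, names = FALSE),
                   igraph::as_edgelist(g2, names = FALSE))
  expect_identical(igraph::ecount(g1), 5)
})

test_that("absolute binarization thresholds strictly", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 0.9
  w[1, 3] <- w[3, 1] <- 0.7
  w[2, 3] <- w[3, 2] <- 0.6
  w[1, 4] <- w[4, 1] <- 0.5       # equal to theta: excluded
  fg <- binarize(make_adj(w), mode = "absolute", theta = 0.5)
  expect_identical(igraph::ecount(asIgraph(fg)), 3)
  expect_error(binarize(make_adj(w), mode = "absolute", theta = 1.5), "0, 1")
})

test_that("asymmetric matrices are symmetrized by elementwise max", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- 0.9; w[2, 1] <- 0.1      # max = 0.9 -> edge at theta 0.5
  fg <- binarize(make_adj(w), mode = "absolute", theta = 0.5)
  el <- igraph::as_edgelist(asIgraph(fg), names = FALSE)
  expect_identical(nrow(el), 1L)
  expect_identical(sort(el[1, ]), c(1, 2))
})

test_that("raising the threshold never adds an edge", {
  set.seed(32)
  for (i in 1:5) {
    w <- matrix(runif(225), 15, 15)
    adj <- make_adj(w)
    e_prev <- Inf
    for (th in c(50, 70, 90, 99)) {
      e <- igraph::ecount(asIgraph(binarize(adj, theta = th)))
      expect_lte(e, e_prev)
      e_prev <- e
    }
    e_prev <- Inf
    for (th in c(0.2, 0.4, 0.6, 0.8)) {
      e <- igraph::ecount(asIgraph(binarize(adj, mode = "absolute",
                                            theta = th)))
      expect_lte(e, e_prev)
      e_prev <- e
    }
  }
})

test_that("node ids and regions survive binarization", {
  w <- matrix(0.5, 4, 4)
  adj <- new("FunctionalAdjacency", weights = w - diag(diag(w)),
             units = c("a", "b", "c", "d"),
             regions = c("VPL", "VPL", "S1", "CM"), windowId = 2L,
             method = "ncs")
  fg <- binarize(adj, theta = 90)
  expect_identical(unitIds(fg), c("a", "b", "c", "d"))
  expect_identical(regionLabels(fg), c("VPL", "VPL", "S1", "CM"))
  expect_identical(fg@windowId, 2L)
})

ring_fg <- function(n, drop = 0, windowId = 1L) {
  g <- igraph::make_ring(n)
  if (drop > 0) {
    # isolate the first `drop` vertices
    inc <- unique(unlist(igraph::incident_edges(
      g, igraph::V(g)[seq_len(drop)])))
    g <- igraph::delete_edges(g, inc)
  }
  g <- igraph::set_vertex_attr(g, "name", value = paste0("u", seq_len(n)))
  g <- igraph::set_vertex_attr(g, "region", value = rep("R1", n))
  new("FunctionalGraph", graph = igraph::simplify(g), windowId = windowId,
      theta = 90, mode = "percentile")
}

test_that("the 99% connectivity rule is applied per graph", {
  ok <- ring_fg(100, drop = 0, windowId = 1L)
  one_iso <- ring_fg(100, drop = 1, windowId = 2L)   # 99% connected: kept
  two_iso <- ring_fg(100, drop = 2, windowId = 3L)   # 98%: rejected
  res <- admissible(list(ok, one_iso, two_iso), band = c(0, 100))
  kept_ids <- vapply(res$kept, function(g) g@windowId, integer(1))
  expect_true(3L %in% res$log$windowId)
  expect_identical(res$log$stage, 1L)
  expect_setequal(kept_ids, c(1L, 2L))
})

test_that("a homogeneous list passes the outlier screen untouched", {
  gs <- lapply(1:6, function(i) ring_fg(50, windowId = i))
  res <- admissible(gs)
  expect_length(res$kept, 6)
  expect_identical(nrow(res$log), 0L)
})

test_that("size outliers are removed by the percentile band", {
  gs <- c(lapply(1:19, function(i) ring_fg(50, windowId = i)),
          list({
            fg <- ring_fg(50, windowId = 20L)
            g <- igraph::add_edges(asIgraph(fg),
                                   t(utils::combn(1:12, 2)))
            new("FunctionalGraph", graph = igraph::simplify(g),
                windowId = 20L, theta = 90, mode = "percentile")
          }))
  res <- admissible(gs)
  expect_false(20L %in% vapply(res$kept, function(g) g@windowId, integer(1)))
  expect_true(20L %in% res$log$windowId)
})
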