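small_cfg <- function(...) {
  defaults <- list(nNodes = 300L, lambda = 0.05, sizeLow = 20L,
                   sizeHigh = 40L, durationMs = 500L, seed = 7L)
  do.call(assemblyConfig, utils::modifyList(defaults, list(...)))
}

test_that("config validation enforces the structural invariants", {
  expect_error(assemblyConfig(nNodes = 100L, sizeLow = 50L, sizeHigh = 150L),
               "sizeHigh")
  expect_error(assemblyConfig(wsK = 60L, sizeLow = 50L), "wsK")
  expect_error(assemblyConfig(durationMs = 5L), "duration")
  expect_error(assemblyConfig(delayLow = 4L, delayHigh = 2L), "delay")
})

test_that("assembly count follows round(lambda * nNodes)", {
  m0 <- buildModel(small_cfg(lambda = 0))
  expect_length(m0@assemblies, 0)
  m <- buildModel(assemblyConfig(nNodes = 10000L, lambda = 0.05,
                                 durationMs = 100L, seed = 1L))
  expect_length(m@assemblies, 500)
  sizes <- vapply(m@assemblies, function(a) length(a$nodes), integer(1))
  expect_true(all(sizes >= 50 & sizes <= 150))
  expect_true(all(unlist(lapply(m@assemblies, `[[`, "nodes")) <= 10000))
})

test_that("model build and raster are reproducible from the seed", {
  m1 <- buildModel(small_cfg())
  m2 <- buildModel(small_cfg())
  expect_identical(lapply(m1@assemblies, `[[`, "nodes"),
                   lapply(m2@assemblies, `[[`, "nodes"))
  expect_identical(lapply(m1@assemblies, `[[`, "offset"),
                   lapply(m2@assemblies, `[[`, "offset"))
  r1 <- simulateRaster(m1); r2 <- simulateRaster(m2)
  expect_identical(spikeMatrix(r1), spikeMatrix(r2))
})

test_that("an empty model yields an empty raster", {
  r <- simulateRaster(buildModel(small_cfg(lambda = 0)))
  expect_identical(sum(spikeMatrix(r)), 0L)
  expect_identical(dim(spikeMatrix(r)), c(300L, 500L))
})

test_that("firing is zero without assemblies and positive with them", {
  r0 <- simulateRaster(buildModel(small_cfg(lambda = 0)))
  r1 <- simulateRaster(buildModel(small_cfg(lambda = 0.05)))
  expect_identical(sum(spikeMatrix(r0)), 0L)
  expect_gt(sum(spikeMatrix(r1)), 0L)
})

test_that("peripheral (low betweenness) members fire before central ones", {
  cfg <- assemblyConfig(nNodes = 60L, lambda = 1 / 60, sizeLow = 16L,
                        sizeHigh = 16L, wsK = 4L, durationMs = 400L,
                        seed = 21L)
  m <- buildModel(cfg)
  expect_length(m@assemblies, 1)
  a <- m@assemblies[[1]]
  r <- spikeMatrix(simulateRaster(m))
  lowest <- a$nodes[which.min(a$offset)]
  highest <- a$nodes[which.max(a$offset)]
  expect_lt(min(a$offset), max(a$offset))
  # nothing precedes the first activation, so the global first spikes are
  # primary spikes of that activation: the peripheral member leads
  expect_lte(min(which(r[lowest, ] > 0)), min(which(r[highest, ] > 0)))
  # and the model-level firing rule makes offsets non-decreasing in
  # betweenness
  b <- igraph::betweenness(a$graph, directed = FALSE)
  expect_true(all(diff(a$offset[order(b)]) >= 0))
})

test_that("unit subsampling is uniform, reproducible and id-preserving", {
  r <- simulateRaster(buildModel(small_cfg()))
  s1 <- sampleUnits(r, 50, seed = 3)
  s2 <- sampleUnits(r, 50, seed = 3)
  expect_identical(unitIds(s1), unitIds(s2))
  expect_true(all(unitIds(s1) %in% unitIds(r)))
  expect_identical(nUnits(s1), 50L)
  all_units <- sampleUnits(r, nUnits(r), seed = 1)
  expect_identical(spikeMatrix(all_units), spikeMatrix(r))
  expect_error(sampleUnits(r, nUnits(r) + 1L, seed = 1), "more units")
})

test_that("null variants flip only the rewiring probability", {
  cfg <- small_cfg()
  lat <- nullVariant(cfg, "lattice")
  rnd <- nullVariant(cfg, "random")
  expect_identical(lat@wsP, 0)
  expect_identical(rnd@wsP, 1)
  for (sl in c("nNodes", "lambda", "wsK", "sizeLow", "sizeHigh",
               "windowLen", "fireProb", "maxConcurrent", "delayLow",
               "delayHigh", "durationMs", "seed")) {
    expect_identical(slot(lat, sl), slot(cfg, sl))
    expect_identical(slot(rnd, sl), slot(cfg, sl))
  }
})

test_that("lattice variant assemblies are vertex-transitive in offsets", {
  # p = 0 gives a ring lattice: every member has equal betweenness, so all
  # intra-window offsets coincide
  m <- buildModel(nullVariant(small_cfg(), "lattice"))
  offs <- lapply(m@assemblies, `[[`, "offset")
  expect_true(all(vapply(offs, function(o) length(unique(o)) == 1L,
                         logical(1))))
  # the small-world variant spreads offsets
  msw <- buildModel(small_cfg())
  nuniq <- vapply(msw@assemblies, function(a) length(unique(a$offset)),
                  integer(1))
  expect_gt(mean(nuniq), 1)
})
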