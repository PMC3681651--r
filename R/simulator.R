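#' Build an AssemblyConfig
#'
#' Parameters of the cell-assembly generative model. A pool of
#' \code{nNodes} neurons hosts \code{round(lambda * nNodes)} embedded
#' Watts-Strogatz subnetworks ("assemblies") that may share nodes. In every
#' 10-timestep execution window at most \code{maxConcurrent} randomly chosen
#' assemblies run, each firing with probability \code{fireProb}; members
#' spike at intra-window offsets set by their betweenness rank (peripheral,
#' low-betweenness nodes first), and each firing node also drives its
#' assembly neighbors after a uniformly distributed propagation delay.
#'
#' Defaults: a 10,000-node pool (about five cortical hypercolumns),
#' assembly sizes uniform on 50-150 (microcolumn scale), ring neighbors
#' k = 5 with rewiring p = 0.05, 1-ms timesteps, and 1-3 ms propagation
#' delays.
#'
#' @param nNodes neuron pool size
#' @param lambda assemblies per node (the density explored on the grid
#'   0.01-0.5)
#' @param wsK,wsP Watts-Strogatz ring neighbors and rewiring probability
#' @param sizeLow,sizeHigh discrete-uniform assembly size bounds
#' @param windowLen execution window length in timesteps
#' @param fireProb probability an active assembly fires in a window
#' @param maxConcurrent max simultaneously active assemblies per window
#' @param delayLow,delayHigh propagation delay bounds in timesteps
#' @param durationMs simulated duration in ms
#' @param seed RNG seed (model build uses \code{seed}, spike emission
#'   \code{seed + 1})
#' @return an \linkS4class{AssemblyConfig}
#' @export
assemblyConfig <- function(nNodes = 10000L, lambda = 0.05, wsK = 5L,
                           wsP = 0.05, sizeLow = 50L, sizeHigh = 150L,
                           windowLen = 10L, fireProb = 0.99,
                           maxConcurrent = 2L, delayLow = 1L,
                           delayHigh = 3L, durationMs = 1000L, seed = 1L) {
  new("AssemblyConfig", nNodes = as.integer(nNodes), lambda = lambda,
      wsK = as.integer(wsK), wsP = wsP, sizeLow = as.integer(sizeLow),
      sizeHigh = as.integer(sizeHigh), windowLen = as.integer(windowLen),
      fireProb = fireProb, maxConcurrent = as.integer(maxConcurrent),
      delayLow = as.integer(delayLow), delayHigh = as.integer(delayHigh),
      durationMs = as.integer(durationMs), seed = as.integer(seed))
}

# Watts-Strogatz graph: ring of n nodes each tied to floor(k/2) neighbors
# per side, edges rewired with probability p; simplified to avoid
# multi-edges introduced by rewiring.
.wattsStrogatz <- function(n, k, p) {
  igraph::simplify(igraph::sample_smallworld(1, n, max(1L, k %/% 2L), p))
}

# intra-window firing offsets from betweenness: centrality values are
# scaled into the execution window, so low-betweenness (peripheral) nodes
# fire first and the SHAPE of the centrality distribution survives --
# heavy-tailed for Watts-Strogatz assemblies (most members early, few
# central members late), constant for a ring lattice (synchronous burst),
# narrow for random graphs. Scaling by rank instead would erase exactly
# this distributional difference between the structural variants.
.betweennessOffset <- function(g, windowLen) {
  b <- igraph::betweenness(g, directed = FALSE)
  mb <- max(b)
  if (mb <= 0) return(rep(0L, length(b)))
  pmin(as.integer(floor(b / mb * windowLen)), windowLen - 1L)
}

#' Build the embedded-assembly model
#'
#' Creates \code{round(lambda * nNodes)} assemblies. Each assembly draws its
#' size from DiscreteUniform(sizeLow, sizeHigh), samples that many nodes
#' uniformly without replacement from the pool (assemblies may overlap), and
#' receives a Watts-Strogatz graph plus per-member betweenness ranks.
#' Reproducible from the config seed.
#'
#' @param cfg an \linkS4class{AssemblyConfig}
#' @return an \linkS4class{AssemblyModel}
#' @export
buildModel <- function(cfg) {
  stopifnot(is(cfg, "AssemblyConfig"))
  validObject(cfg)
  nSwn <- round(cfg@lambda * cfg@nNodes)
  assemblies <- withr_seed(cfg@seed, {
    lapply(seq_len(nSwn), function(i) {
      size <- sample(cfg@sizeLow:cfg@sizeHigh, 1)
      if (size > cfg@nNodes) stop("assembly size exceeds the node pool")
      nodes <- sample.int(cfg@nNodes, size)
      g <- .wattsStrogatz(size, cfg@wsK, cfg@wsP)
      list(nodes = nodes, graph = g,
           offset = .betweennessOffset(g, cfg@windowLen))
    })
  })
  new("AssemblyModel", nNodes = cfg@nNodes, assemblies = assemblies,
      config = cfg)
}

#' Simulate the spike raster of an assembly model
#'
#' Time is tiled into \code{windowLen}-timestep execution windows. Per
#' window, up to \code{maxConcurrent} assemblies are drawn at random (the
#' draw is repeated each window); each runs with probability
#' \code{fireProb}. A running assembly emits one spike per member at the
#' window start plus the member's rank offset, and every member also
#' triggers its assembly neighbors at offset(A) + offset(B) plus a uniform
#' propagation delay. Spike times are clamped to the raster bounds; output
#' is binary at 1-ms bins.
#'
#' @param model an \linkS4class{AssemblyModel}
#' @param cfg optional config override (defaults to the model's own)
#' @return a \linkS4class{SpikeRaster} with one row per pool node
#' @export
simulateRaster <- function(model, cfg = NULL) {
  stopifnot(is(model, "AssemblyModel"))
  if (is.null(cfg)) cfg <- model@config
  Tms <- cfg@durationMs
  nA <- length(model@assemblies)
  spikes <- matrix(0L, nrow = model@nNodes, ncol = Tms)
  if (nA > 0) {
    wl <- cfg@windowLen
    nW <- Tms %/% wl
    offs <- lapply(model@assemblies, function(a) a$offset)
    neigh <- lapply(model@assemblies, function(a)
      igraph::as_adj_list(a$graph, mode = "all"))
    withr_seed(cfg@seed + 1L, {
      for (w in seq_len(nW)) {
        start <- (w - 1L) * wl
        active <- sample.int(nA, min(cfg@maxConcurrent, nA))
        for (ai in active) {
          if (runif(1) > cfg@fireProb) next
          a <- model@assemblies[[ai]]
          off <- offs[[ai]]
          nodes <- a$nodes
          # the assembly pattern lands at a random phase inside its window,
          # de-synchronizing concurrent assemblies while keeping the
          # betweenness-ordered lags within the assembly intact
          onset <- start + sample.int(wl, 1L) - 1L
          # primary spikes in centrality order
          t1 <- pmin(pmax(onset + off + 1L, 1L), Tms)
          spikes[cbind(nodes, t1)] <- 1L
          # propagation to neighbors with uniform delay
          nb <- neigh[[ai]]
          for (j in seq_along(nodes)) {
            bs <- as.integer(nb[[j]])
            if (!length(bs)) next
            delay <- sample(cfg@delayLow:cfg@delayHigh, length(bs),
                            replace = TRUE)
            tb <- pmin(pmax(onset + off[j] + off[bs] + delay + 1L, 1L), Tms)
            spikes[cbind(nodes[bs], tb)] <- 1L
          }
        }
      }
    })
  }
  SpikeRaster(spikes, units = paste0("n", seq_len(model@nNodes)),
              regions = rep("SIM", model@nNodes), binMs = 1)
}

#' Randomly subsample recorded units
#'
#' Uniform sampling without replacement, emulating the ~100 units a
#' multi-array session yields; unit ids and regions are carried along (rows
#' kept in pool order).
#'
#' @param raster a \linkS4class{SpikeRaster}
#' @param nSample number of units to keep
#' @param seed RNG seed
#' @return a \linkS4class{SpikeRaster} with \code{nSample} rows
#' @export
sampleUnits <- function(raster, nSample = 100L, seed = 1L) {
  stopifnot(is(raster, "SpikeRaster"))
  n <- nUnits(raster)
  if (nSample > n) stop("cannot sample more units than available")
  keep <- sort(withr_seed(seed, sample.int(n, nSample)))
  SpikeRaster(raster@spikes[keep, , drop = FALSE],
              units = raster@units[keep], regions = raster@regions[keep],
              binMs = raster@binMs)
}

#' Control variants of the assembly model
#'
#' Returns the config with the Watts-Strogatz rewiring probability replaced:
#' 0 for the ring-lattice control, 1 for the random control. All other
#' fields are untouched.
#'
#' @param cfg an \linkS4class{AssemblyConfig}
#' @param kind "lattice" or "random"
#' @return a modified \linkS4class{AssemblyConfig}
#' @export
nullVariant <- function(cfg, kind = c("lattice", "random")) {
  kind <- match.arg(kind)
  cfg@wsP <- if (kind == "lattice") 0 else 1
  cfg
}
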