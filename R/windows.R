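#' Slice a recording into fixed-length overlapping windows
#'
#' Splits a \linkS4class{SpikeRaster} or \linkS4class{LFPSet} into
#' equal-length analysis windows. With overlap fraction f the window start
#' step is \code{round(lengthMs * (1 - f))} bins; only complete windows are
#' returned, in temporal order.
#'
#' @param x a \linkS4class{SpikeRaster} (1-ms bins) or \linkS4class{LFPSet}
#' @param lengthMs window length in ms (>= 2 bins)
#' @param overlap overlap fraction in [0, 1)
#' @return list of objects of the same class as \code{x}, one per window;
#'   each carries attribute \code{windowId}
#' @examples
#' r <- SpikeRaster(matrix(rbinom(4000, 1, 0.05), nrow = 4))
#' length(sliceWindows(r, 250, 0.5))   # 7 windows over 1000 ms
#' @export
sliceWindows <- function(x, lengthMs, overlap = 0.5) {
  stopifnot(overlap >= 0, overlap < 1)
  if (is(x, "SpikeRaster")) {
    total <- nBins(x); L <- as.integer(round(lengthMs / x@binMs))
  } else if (is(x, "LFPSet")) {
    total <- nrow(signalMatrix(x))
    L <- as.integer(round(lengthMs / 1000 * samplingRate(x)))
  } else stop("x must be a SpikeRaster or an LFPSet")
  if (L < 2) stop("window must span at least 2 bins")
  if (L > total) stop("window longer than the recording")
  step <- max(1L, as.integer(round(L * (1 - overlap))))
  starts <- seq.int(1L, total - L + 1L, by = step)
  lapply(seq_along(starts), function(i) {
    s <- starts[i]
    out <- if (is(x, "SpikeRaster")) {
      SpikeRaster(x@spikes[, s:(s + L - 1L), drop = FALSE],
                  units = x@units, regions = x@regions, binMs = x@binMs)
    } else {
      LFPSet(x@samples[s:(s + L - 1L), , drop = FALSE],
             samplingRate = x@samplingRate, channels = x@channels,
             regions = x@regions)
    }
    attr(out, "windowId") <- i
    out
  })
}

#' Binarize a weighted adjacency into a functional graph
#'
#' Asymmetric matrices (NCS) are symmetrized first by the elementwise
#' maximum, retaining the strongest dependency detected in either
#' direction. In \code{"percentile"} mode, theta is a percentile of the
#' off-diagonal weight distribution and the top \code{ceiling((1 -
#' theta/100) * nPairs)} unordered pairs become edges; ties at the cut are
#' broken deterministically by (weight descending, i ascending, j
#' ascending). In \code{"absolute"} mode an edge requires weight strictly
#' above theta (which must lie in [0, 1] for unit-range weights).
#'
#' Raising theta never adds an edge in either mode.
#'
#' @param adj a \linkS4class{FunctionalAdjacency}
#' @param mode "percentile" or "absolute"
#' @param theta threshold (percentile in [0, 100] or absolute weight)
#' @return a \linkS4class{FunctionalGraph}
#' @export
binarize <- function(adj, mode = c("percentile", "absolute"), theta = 90) {
  mode <- match.arg(mode)
  stopifnot(is(adj, "FunctionalAdjacency"))
  w <- adj@weights
  n <- nrow(w)
  ws <- pmax(w, t(w))              # symmetrize: elementwise max
  iu <- which(upper.tri(ws), arr.ind = TRUE)
  wt <- ws[upper.tri(ws)]
  ord <- order(-wt, iu[, 1], iu[, 2])   # weight desc, then i, then j
  keep <- integer(0)
  if (mode == "percentile") {
    if (theta < 0 || theta > 100) stop("percentile theta must be in [0, 100]")
    m <- ceiling((1 - theta / 100) * length(wt))
    if (m > 0) keep <- ord[seq_len(m)]
  } else {
    if (theta < 0 || theta > 1)
      stop("absolute theta must be in [0, 1] for unit-range weights")
    keep <- ord[wt[ord] > theta]
  }
  el <- iu[keep, , drop = FALSE]
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = adj@units)
  g <- igraph::set_vertex_attr(g, "region", value = adj@regions)
  if (nrow(el)) g <- igraph::add_edges(g, t(el))
  new("FunctionalGraph", graph = g, windowId = adj@windowId,
      theta = as.numeric(theta), mode = mode)
}

#' Admissibility screening of functional graphs
#'
#' Two-stage retention rule. Stage 1 drops graphs in which fewer than
#' \code{minConnected} (default 99\%) of nodes are connected; "connected"
#' means degree >= 1 (a giant-component reading is available via
#' \code{connectedRule = "component"}). Stage 2 drops size outliers: graphs
#' outside the [lower, upper] percentile band (default 5th-95th) of the
#' node-count, edge-count and density distributions over the remaining
#' list. A homogeneous list passes stage 2 untouched.
#'
#' @param graphs list of \linkS4class{FunctionalGraph}
#' @param minConnected minimum fraction of connected nodes
#' @param band two percentiles (0-100) bounding the outlier screen
#' @param connectedRule "degree" (degree >= 1) or "component" (membership in
#'   the largest component)
#' @return list with elements \code{kept} (the admissible graphs) and
#'   \code{log} (data.frame: windowId, stage, reason for every rejection)
#' @export
admissible <- function(graphs, minConnected = 0.99, band = c(5, 95),
                       connectedRule = c("degree", "component")) {
  connectedRule <- match.arg(connectedRule)
  stopifnot(length(graphs) >= 1)
  rej <- list()
  frac_conn <- vapply(graphs, function(fg) {
    g <- asIgraph(fg)
    if (connectedRule == "degree") {
      mean(igraph::degree(g) >= 1)
    } else {
      comp <- igraph::components(g)
      max(comp$csize) / igraph::vcount(g)
    }
  }, numeric(1))
  stage1 <- frac_conn >= minConnected
  for (i in which(!stage1))
    rej[[length(rej) + 1L]] <- data.frame(
      windowId = graphs[[i]]@windowId, stage = 1L,
      reason = sprintf("only %.1f%% of nodes connected", 100 * frac_conn[i]))
  g1 <- graphs[stage1]
  if (!length(g1))
    return(list(kept = list(), log = do.call(rbind, rej)))
  feats <- t(vapply(g1, function(fg) {
    g <- asIgraph(fg)
    n <- igraph::vcount(g); e <- igraph::ecount(g)
    c(nodes = n, edges = e, density = if (n > 1) 2 * e / (n * (n - 1)) else 0)
  }, numeric(3)))
  inband <- rep(TRUE, nrow(feats))
  for (k in seq_len(ncol(feats))) {
    qs <- quantile(feats[, k], band / 100, names = FALSE)
    inband <- inband & feats[, k] >= qs[1] & feats[, k] <= qs[2]
  }
  for (i in which(!inband))
    rej[[length(rej) + 1L]] <- data.frame(
      windowId = g1[[i]]@windowId, stage = 2L,
      reason = "size/density outlier")
  log <- if (length(rej)) do.call(rbind, rej) else
    data.frame(windowId = integer(0), stage = integer(0),
               reason = character(0))
  list(kept = g1[inband], log = log)
}
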