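#' Classify a recording as stimulus-responsive
#'
#' Responsive iff the evoked firing rate strictly exceeds the basal mean
#' plus \code{multiplier} times the basal standard deviation.
#'
#' @param evokedRate evoked firing rate (Hz)
#' @param basalMean,basalSd basal-rate mean and SD (Hz, SD >= 0)
#' @param multiplier SD multiplier (default 5)
#' @return "responsive" or "non_responsive"
#' @examples
#' classifyResponsive(20, 2, 3)   # 20 > 2 + 5*3 -> responsive
#' @export
classifyResponsive <- function(evokedRate, basalMean, basalSd,
                               multiplier = 5) {
  if (evokedRate < 0 || basalMean < 0 || basalSd < 0)
    stop("rates must be nonnegative")
  if (evokedRate > basalMean + multiplier * basalSd) "responsive"
  else "non_responsive"
}

#' Exclude units by firing rate
#'
#' Units firing below \code{low} or above \code{high} Hz over the whole
#' raster are dropped (silent or artifact-dominated channels).
#'
#' @param raster a \linkS4class{SpikeRaster}
#' @param low,high rate bounds in Hz
#' @return filtered \linkS4class{SpikeRaster}
#' @export
filterUnitsByRate <- function(raster, low = 0.5, high = 100) {
  stopifnot(is(raster, "SpikeRaster"))
  durS <- nBins(raster) * raster@binMs / 1000
  rate <- rowSums(spikeMatrix(raster)) / durS
  keep <- rate >= low & rate <= high
  if (!any(keep)) stop("no unit passes the firing-rate bounds")
  SpikeRaster(raster@spikes[keep, , drop = FALSE],
              units = raster@units[keep], regions = raster@regions[keep],
              binMs = raster@binMs)
}

#' Spike-train functional connectivity pipeline
#'
#' Slices the raster into windows, computes the NCS adjacency per window,
#' binarizes, applies the admissibility screen, and summarizes every
#' admissible graph with small-world statistics plus betweenness and
#' community summaries.
#'
#' @param raster a \linkS4class{SpikeRaster}
#' @param windowMs window length in ms
#' @param overlap window overlap fraction
#' @param mode,theta binarization mode and threshold
#' @param maxOrder PPM order; default half the window capped at 16
#' @param nNull null realizations for the small-world indices
#' @param iterationsPerEdge swap attempts per edge in null generation
#' @param seed RNG seed
#' @param maxWindows cap on the number of analyzed windows (NULL = all)
#' @param minConnected minimum connected-node fraction for admissibility
#'   (0 disables the connectivity screen)
#' @param band outlier percentile band for admissibility
#' @return list with \code{report} (data.frame: window, nodes, edges, win,
#'   theta, C, C_latt, C_rand, L, L_rand, S, omega, Q),
#'   \code{betweenness} (list per admissible graph),
#'   \code{rejections} (admissibility log)
#' @export
runSpikePipeline <- function(raster, windowMs = 1000, overlap = 0.5,
                             mode = "percentile", theta = 90,
                             maxOrder = NULL, nNull = 10L,
                             iterationsPerEdge = 10, seed = 1L,
                             maxWindows = NULL, minConnected = 0.99,
                             band = c(5, 95)) {
  stopifnot(is(raster, "SpikeRaster"))
  if (sum(spikeMatrix(raster)) == 0) stop("empty raster: no spikes")
  wins <- sliceWindows(raster, windowMs, overlap)
  if (!is.null(maxWindows) && length(wins) > maxWindows)
    wins <- wins[seq_len(maxWindows)]
  graphs <- lapply(wins, function(w) {
    adj <- ncsMatrix(w, maxOrder = maxOrder,
                     windowId = attr(w, "windowId"))
    binarize(adj, mode = mode, theta = theta)
  })
  adm <- admissible(graphs, minConnected = minConnected, band = band)
  if (!length(adm$kept)) {
    message("no admissible graphs; returning an empty report")
    return(list(report = data.frame(), betweenness = list(),
                rejections = adm$log))
  }
  rows <- lapply(seq_along(adm$kept), function(i) {
    fg <- adm$kept[[i]]
    swr <- smallWorldness(fg, nNull = nNull,
                          iterationsPerEdge = iterationsPerEdge,
                          seed = seed + 100L * i)
    cm <- detectCommunities(fg)
    cbind(data.frame(window = fg@windowId, win = windowMs,
                     theta = fg@theta), as.data.frame(swr),
          data.frame(Q = cm$Q))
  })
  btw <- lapply(adm$kept, betweennessCentrality)
  list(report = do.call(rbind, rows), betweenness = btw,
       rejections = adm$log)
}

#' LFP phase-synchrony pipeline
#'
#' Phase-synchrony graphs per window with intra- vs inter-region edge
#' counts and small-world statistics.
#'
#' @param lfp an \linkS4class{LFPSet} with region labels
#' @param windowMs window length in ms
#' @param overlap overlap fraction
#' @param mode,theta binarization mode and threshold
#' @param nNull,iterationsPerEdge,seed null-model settings
#' @param minConnected,band admissibility settings (see
#'   \code{\link{admissible}})
#' @return list with \code{report} (per admissible graph: window, win,
#'   theta, intraEdges, interEdges, totalEdges and small-world columns)
#'   and \code{rejections}
#' @export
runLfpPipeline <- function(lfp, windowMs = 1000, overlap = 0.5,
                           mode = "percentile", theta = 90, nNull = 10L,
                           iterationsPerEdge = 10, seed = 1L,
                           minConnected = 0.99, band = c(5, 95)) {
  stopifnot(is(lfp, "LFPSet"))
  if (length(unique(regionLabels(lfp))) < 2)
    warning("single region: inter-area edge counts will be zero")
  wins <- sliceWindows(lfp, windowMs, overlap)
  graphs <- lapply(wins, function(w) {
    adj <- plvMatrix(w, windowId = attr(w, "windowId"))
    binarize(adj, mode = mode, theta = theta)
  })
  adm <- admissible(graphs, minConnected = minConnected, band = band)
  rows <- lapply(seq_along(adm$kept), function(i) {
    fg <- adm$kept[[i]]
    g <- asIgraph(fg)
    reg <- igraph::V(g)$region
    el <- igraph::as_edgelist(g, names = FALSE)
    intra <- if (nrow(el)) sum(reg[el[, 1]] == reg[el[, 2]]) else 0L
    swr <- smallWorldness(fg, nNull = nNull,
                          iterationsPerEdge = iterationsPerEdge,
                          seed = seed + 100L * i)
    cbind(data.frame(window = fg@windowId, win = windowMs,
                     theta = fg@theta, intraEdges = intra,
                     interEdges = nrow(el) - intra,
                     totalEdges = nrow(el)),
          as.data.frame(swr))
  })
  list(report = if (length(rows)) do.call(rbind, rows) else data.frame(),
       rejections = adm$log)
}

#' Assembly-model simulation study
#'
#' For each assembly density on the grid and each structural variant
#' (small-world, random, lattice), builds the model, simulates, samples
#' units, runs the spike pipeline, and aggregates S and omega over seeds.
#' Reproduces the qualitative contrast that only the small-world variant
#' sustains S > 1 with omega near 0 in the sampled functional graphs.
#'
#' @param lambdaGrid assembly densities (default the published grid)
#' @param variants subset of c("swn", "random", "lattice")
#' @param nSeeds seeds per cell
#' @param baseConfig template \linkS4class{AssemblyConfig}; lambda, wsP and
#'   seed are overridden per cell
#' @param nSampleUnits units sampled per run
#' @param windowMs analysis window (100 ms in the published grid)
#' @param theta binarization percentile
#' @param nNull null realizations
#' @param maxWindows windows analyzed per run
#' @param seed base RNG seed
#' @param minConnected connectivity screen for admissibility; the model
#'   emits structurally silent units inside short windows by design, so the
#'   study defaults to no connectivity screen (0) to retain every window
#' @return data.frame with one row per (lambda, variant, seed) plus the
#'   mean S and omega of that run's admissible graphs
#' @export
runSimulationStudy <- function(lambdaGrid = c(0.01, 0.03, 0.05, 0.075,
                                              0.1, 0.25, 0.5),
                               variants = c("swn", "random", "lattice"),
                               nSeeds = 3L, baseConfig = NULL,
                               nSampleUnits = 100L, windowMs = 100,
                               theta = 90, nNull = 5L, maxWindows = 10L,
                               seed = 1L, minConnected = 0) {
  if (is.null(baseConfig))
    baseConfig <- assemblyConfig(nNodes = 2000L, durationMs = 2000L)
  rows <- list()
  for (lam in lambdaGrid) {
    for (v in variants) {
      for (s in seq_len(nSeeds)) {
        cfg <- baseConfig
        cfg@lambda <- lam
        cfg@seed <- as.integer(seed + 1000L * s)
        if (v != "swn") cfg <- nullVariant(cfg, ifelse(v == "random",
                                                       "random", "lattice"))
        model <- buildModel(cfg)
        raster <- simulateRaster(model)
        sub <- sampleUnits(raster, min(nSampleUnits, nUnits(raster)),
                           seed = cfg@seed + 7L)
        res <- tryCatch(
          runSpikePipeline(sub, windowMs = windowMs, overlap = 0,
                           theta = theta, nNull = nNull,
                           seed = cfg@seed + 13L, maxWindows = maxWindows,
                           minConnected = minConnected),
          error = function(e) NULL)
        rep <- if (is.null(res)) data.frame() else res$report
        rows[[length(rows) + 1L]] <- data.frame(
          lambda = lam, variant = v, seed = cfg@seed,
          nGraphs = nrow(rep),
          S = if (nrow(rep)) mean(rep$S) else NA_real_,
          omega = if (nrow(rep)) mean(rep$omega) else NA_real_,
          C = if (nrow(rep)) mean(rep$C) else NA_real_,
          L = if (nrow(rep)) mean(rep$L) else NA_real_)
      }
    }
  }
  do.call(rbind, rows)
}
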