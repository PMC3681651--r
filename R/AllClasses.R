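#' @import methods
#' @importFrom stats cor cor.test fft p.adjust pbinom quantile rbinom rnorm
#'   runif sd setNames ccf filter qnorm
#' @importFrom utils head write.table read.table
#' @useDynLib SpikeNets, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

setOldClass("igraph")

#' SpikeRaster: binary spike trains at 1-ms resolution
#'
#' Units in rows, time bins in columns, entries 0/1. Each unit carries an id
#' and a region label (e.g. cortical vs thalamic site).
#'
#' @slot spikes integer matrix of 0/1, units x bins
#' @slot units character vector of unit ids (rownames of \code{spikes})
#' @slot regions character vector of region labels, one per unit
#' @slot binMs numeric, bin width in milliseconds (1 throughout)
#' @exportClass SpikeRaster
setClass("SpikeRaster",
  representation(spikes = "matrix", units = "character",
                 regions = "character", binMs = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!all(object@spikes %in% c(0L, 1L)))
      msg <- c(msg, "spike matrix must be binary (0/1)")
    if (length(object@units) != nrow(object@spikes))
      msg <- c(msg, "one unit id per raster row required")
    if (length(object@regions) != nrow(object@spikes))
      msg <- c(msg, "one region label per raster row required")
    if (anyDuplicated(object@units))
      msg <- c(msg, "unit ids must be unique")
    if (length(object@binMs) != 1L || object@binMs <= 0)
      msg <- c(msg, "binMs must be a single positive number")
    if (length(msg)) msg else TRUE
  })

#' Construct a SpikeRaster
#'
#' @param spikes binary units x bins matrix
#' @param units unit ids; default u1..un
#' @param regions region labels; default "R1" for all units
#' @param binMs bin width in ms
#' @return a \linkS4class{SpikeRaster}
#' @examples
#' r <- SpikeRaster(matrix(rbinom(200, 1, 0.1), nrow = 4))
#' nUnits(r)
#' @export
SpikeRaster <- function(spikes, units = NULL, regions = NULL, binMs = 1) {
  spikes <- as.matrix(spikes)
  storage.mode(spikes) <- "integer"
  if (is.null(units)) units <- rownames(spikes)
  if (is.null(units)) units <- paste0("u", seq_len(nrow(spikes)))
  if (is.null(regions)) regions <- rep("R1", nrow(spikes))
  rownames(spikes) <- units
  new("SpikeRaster", spikes = spikes, units = as.character(units),
      regions = as.character(regions), binMs = binMs)
}

#' LFPSet: multichannel continuous signals
#'
#' Time in rows, channels in columns.
#'
#' @slot samples numeric matrix, samples x channels
#' @slot samplingRate sampling rate in Hz
#' @slot channels channel ids
#' @slot regions region label per channel
#' @exportClass LFPSet
setClass("LFPSet",
  representation(samples = "matrix", samplingRate = "numeric",
                 channels = "character", regions = "character"),
  validity = function(object) {
    msg <- character()
    if (!all(is.finite(object@samples)))
      msg <- c(msg, "samples must be finite")
    if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
      msg <- c(msg, "samplingRate must be a single positive number")
    if (length(object@channels) != ncol(object@samples))
      msg <- c(msg, "one channel id per column required")
    if (length(object@regions) != ncol(object@samples))
      msg <- c(msg, "one region label per channel required")
    if (length(msg)) msg else TRUE
  })

#' Construct an LFPSet
#'
#' @param samples numeric samples x channels matrix
#' @param samplingRate Hz
#' @param channels channel ids; default ch1..chn
#' @param regions per-channel region labels; default "R1"
#' @return an \linkS4class{LFPSet}
#' @export
LFPSet <- function(samples, samplingRate, channels = NULL, regions = NULL) {
  samples <- as.matrix(samples)
  if (is.null(channels)) channels <- colnames(samples)
  if (is.null(channels)) channels <- paste0("ch", seq_len(ncol(samples)))
  if (is.null(regions)) regions <- rep("R1", ncol(samples))
  colnames(samples) <- channels
  new("LFPSet", samples = samples, samplingRate = samplingRate,
      channels = as.character(channels), regions = as.character(regions))
}

#' FunctionalAdjacency: pairwise similarity weights for one analysis window
#'
#' Square weight matrix over units or channels; NCS matrices may be
#' asymmetric, phase-synchrony matrices are symmetric. Diagonal is zero.
#'
#' @slot weights numeric square matrix in [0, 1]
#' @slot units node ids
#' @slot regions node region labels
#' @slot windowId 1-based index of the source window
#' @slot method "ncs" or "plv"
#' @exportClass FunctionalAdjacency
setClass("FunctionalAdjacency",
  representation(weights = "matrix", units = "character",
                 regions = "character", windowId = "integer",
                 method = "character"),
  validity = function(object) {
    msg <- character()
    w <- object@weights
    if (nrow(w) != ncol(w)) msg <- c(msg, "weights must be square")
    if (any(diag(w) != 0)) msg <- c(msg, "diagonal must be zero")
    if (any(w < 0 | w > 1)) msg <- c(msg, "weights must lie in [0, 1]")
    if (length(object@units) != nrow(w))
      msg <- c(msg, "one unit id per row required")
    if (length(msg)) msg else TRUE
  })

#' FunctionalGraph: binarized undirected functional connection graph
#'
#' Wraps an igraph object together with the provenance of its construction
#' (window index, threshold, thresholding mode).
#'
#' @slot graph an undirected simple igraph with vertex attributes
#'   \code{name} and \code{region}
#' @slot windowId source window index
#' @slot theta threshold used at binarization
#' @slot mode "percentile" or "absolute"
#' @exportClass FunctionalGraph
setClass("FunctionalGraph",
  representation(graph = "igraph", windowId = "integer",
                 theta = "numeric", mode = "character"),
  validity = function(object) {
    g <- object@graph
    msg <- character()
    if (igraph::is_directed(g)) msg <- c(msg, "graph must be undirected")
    if (!igraph::is_simple(g)) msg <- c(msg, "graph must be simple")
    if (length(msg)) msg else TRUE
  })

#' SmallWorldReport: small-world statistics for one graph
#'
#' Holds the clustering coefficient C, characteristic path length L, their
#' null-model counterparts (randomized C_rand, L_rand; latticized C_latt),
#' and the two small-worldness indices
#' S = (C/C_rand)/(L/L_rand) and omega = L_rand/L - C/C_latt.
#'
#' @slot nodes,edges graph size
#' @slot C,L observed statistics
#' @slot Crand,Lrand means over randomized nulls
#' @slot Clatt mean over latticized nulls
#' @slot S,omega small-worldness indices
#' @slot nNull number of null realizations
#' @slot seed RNG seed used for the nulls
#' @exportClass SmallWorldReport
setClass("SmallWorldReport",
  representation(nodes = "integer", edges = "integer", C = "numeric",
                 L = "numeric", Crand = "numeric", Lrand = "numeric",
                 Clatt = "numeric", S = "numeric", omega = "numeric",
                 nNull = "integer", seed = "integer"))

#' SurrogateNull: shuffle-surrogate significance of one NCS value
#'
#' @slot observed observed NCS
#' @slot nullValues NCS under independent within-window spike-time shuffles
#'   of the second train
#' @slot pValue add-one permutation p-value
#'   (1 + #(null >= observed)) / (1 + n)
#' @slot nSurrogates number of surrogates
#' @exportClass SurrogateNull
setClass("SurrogateNull",
  representation(observed = "numeric", nullValues = "numeric",
                 pValue = "numeric", nSurrogates = "integer"),
  validity = function(object) {
    if (object@pValue < 0 || object@pValue > 1) "pValue outside [0, 1]" else TRUE
  })

#' AssemblyConfig: parameters of the cell-assembly generative model
#'
#' The model embeds round(lambda * nNodes) Watts-Strogatz subnetworks
#' ("assemblies") in a pool of nNodes neurons; assemblies fire inside 10-ms
#' execution windows in betweenness rank order.
#'
#' @slot nNodes neuron pool size
#' @slot lambda assembly density (small-world networks per node)
#' @slot wsK ring neighbors of the Watts-Strogatz generator
#' @slot wsP rewiring probability (0 = ring lattice, 1 = random)
#' @slot sizeLow,sizeHigh bounds of the discrete-uniform assembly size
#' @slot windowLen execution window length in timesteps
#' @slot fireProb probability an active assembly fires in a window
#' @slot maxConcurrent max simultaneously active assemblies per window
#' @slot delayLow,delayHigh propagation delay bounds (timesteps)
#' @slot durationMs simulated duration (1-ms timesteps)
#' @slot seed RNG seed
#' @exportClass AssemblyConfig
setClass("AssemblyConfig",
  representation(nNodes = "integer", lambda = "numeric", wsK = "integer",
                 wsP = "numeric", sizeLow = "integer", sizeHigh = "integer",
                 windowLen = "integer", fireProb = "numeric",
                 maxConcurrent = "integer", delayLow = "integer",
                 delayHigh = "integer", durationMs = "integer",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@lambda < 0) msg <- c(msg, "lambda must be >= 0")
    if (!(2L <= object@sizeLow && object@sizeLow <= object@sizeHigh &&
          object@sizeHigh <= object@nNodes))
      msg <- c(msg, "need 2 <= sizeLow <= sizeHigh <= nNodes")
    if (object@wsK >= object@sizeLow)
      msg <- c(msg, "wsK must be smaller than sizeLow")
    if (object@wsP < 0 || object@wsP > 1) msg <- c(msg, "wsP in [0, 1]")
    if (object@fireProb < 0 || object@fireProb > 1)
      msg <- c(msg, "fireProb in [0, 1]")
    if (object@delayLow > object@delayHigh)
      msg <- c(msg, "delayLow must be <= delayHigh")
    if (object@durationMs < object@windowLen)
      msg <- c(msg, "duration must cover at least one window")
    if (length(msg)) msg else TRUE
  })

#' AssemblyModel: the built multigraph of embedded assemblies
#'
#' @slot nNodes pool size
#' @slot assemblies list; each element has \code{nodes} (pool indices),
#'   \code{graph} (igraph over 1..size) and \code{offset} (intra-window
#'   firing offset per member, betweenness scaled into the window)
#' @slot config the \linkS4class{AssemblyConfig} used
#' @exportClass AssemblyModel
setClass("AssemblyModel",
  representation(nNodes = "integer", assemblies = "list",
                 config = "AssemblyConfig"))

setMethod("show", "SpikeRaster", function(object) {
  cat("SpikeRaster:", nrow(object@spikes), "units x", ncol(object@spikes),
      "bins (", object@binMs, "ms );",
      sum(object@spikes), "spikes;",
      length(unique(object@regions)), "region(s)\n")
})

setMethod("show", "LFPSet", function(object) {
  cat("LFPSet:", ncol(object@samples), "channels x", nrow(object@samples),
      "samples @", object@samplingRate, "Hz;",
      length(unique(object@regions)), "region(s)\n")
})

setMethod("show", "FunctionalAdjacency", function(object) {
  cat("FunctionalAdjacency (", object@method, "): ", nrow(object@weights),
      " nodes, window ", object@windowId, "\n", sep = "")
})

setMethod("show", "FunctionalGraph", function(object) {
  cat("FunctionalGraph: ", igraph::vcount(object@graph), " nodes, ",
      igraph::ecount(object@graph), " edges (window ", object@windowId,
      ", ", object@mode, " theta = ", object@theta, ")\n", sep = "")
})

setMethod("show", "SmallWorldReport", function(object) {
  cat(sprintf(
    "SmallWorldReport: %d nodes, %d edges\n  C = %.4f (rand %.4f, latt %.4f)  L = %.4f (rand %.4f)\n  S = %.3f  omega = %.3f  [%d nulls]\n",
    object@nodes, object@edges, object@C, object@Crand, object@Clatt,
    object@L, object@Lrand, object@S, object@omega, object@nNull))
})

setMethod("show", "SurrogateNull", function(object) {
  cat(sprintf("SurrogateNull: observed = %.4f, p = %.4f (%d surrogates)\n",
              object@observed, object@pValue, object@nSurrogates))
})

setMethod("show", "AssemblyModel", function(object) {
  sz <- vapply(object@assemblies, function(a) length(a$nodes), integer(1))
  cat("AssemblyModel:", object@nNodes, "nodes,",
      length(object@assemblies), "assemblies",
      if (length(sz)) sprintf("(sizes %d-%d)", min(sz), max(sz)) else "", "\n")
})
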