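#' Accessors for SpikeNets classes
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param object a SpikeNets S4 object
#' @return the requested component
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("spikeMatrix", function(object) standardGeneric("spikeMatrix"))
#' @rdname accessors
#' @export
setGeneric("unitIds", function(object) standardGeneric("unitIds"))
#' @rdname accessors
#' @export
setGeneric("regionLabels", function(object) standardGeneric("regionLabels"))
#' @rdname accessors
#' @export
setGeneric("nUnits", function(object) standardGeneric("nUnits"))
#' @rdname accessors
#' @export
setGeneric("nBins", function(object) standardGeneric("nBins"))
#' @rdname accessors
#' @export
setGeneric("signalMatrix", function(object) standardGeneric("signalMatrix"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("channelIds", function(object) standardGeneric("channelIds"))
#' @rdname accessors
#' @export
setGeneric("weightMatrix", function(object) standardGeneric("weightMatrix"))
#' @rdname accessors
#' @export
setGeneric("asIgraph", function(object) standardGeneric("asIgraph"))
#' @rdname accessors
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))
#' @rdname accessors
#' @export
setGeneric("nullValues", function(object) standardGeneric("nullValues"))

#' @rdname accessors
setMethod("spikeMatrix", "SpikeRaster", function(object) object@spikes)
#' @rdname accessors
setMethod("unitIds", "SpikeRaster", function(object) object@units)
#' @rdname accessors
setMethod("regionLabels", "SpikeRaster", function(object) object@regions)
#' @rdname accessors
setMethod("nUnits", "SpikeRaster", function(object) nrow(object@spikes))
#' @rdname accessors
setMethod("nBins", "SpikeRaster", function(object) ncol(object@spikes))

#' @rdname accessors
setMethod("signalMatrix", "LFPSet", function(object) object@samples)
#' @rdname accessors
setMethod("samplingRate", "LFPSet", function(object) object@samplingRate)
#' @rdname accessors
setMethod("channelIds", "LFPSet", function(object) object@channels)
#' @rdname accessors
setMethod("regionLabels", "LFPSet", function(object) object@regions)

#' @rdname accessors
setMethod("weightMatrix", "FunctionalAdjacency", function(object) {
  w <- object@weights
  dimnames(w) <- list(object@units, object@units)
  w
})
#' @rdname accessors
setMethod("unitIds", "FunctionalAdjacency", function(object) object@units)
#' @rdname accessors
setMethod("regionLabels", "FunctionalAdjacency", function(object) object@regions)

#' @rdname accessors
setMethod("asIgraph", "FunctionalGraph", function(object) object@graph)
#' @rdname accessors
setMethod("regionLabels", "FunctionalGraph",
          function(object) igraph::vertex_attr(object@graph, "region"))
#' @rdname accessors
setMethod("unitIds", "FunctionalGraph",
          function(object) igraph::vertex_attr(object@graph, "name"))

#' @rdname accessors
setMethod("pValue", "SurrogateNull", function(object) object@pValue)
#' @rdname accessors
setMethod("nullValues", "SurrogateNull", function(object) object@nullValues)

#' Coerce a SmallWorldReport to a one-row data.frame
#'
#' Column layout follows the report tables: nodes, edges, C, C_latt, C_rand,
#' L, L_rand, S, omega.
#'
#' @param x a \linkS4class{SmallWorldReport}
#' @param row.names,optional,... ignored (S3 signature)
#' @return one-row data.frame
#' @export
as.data.frame.SmallWorldReport <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  data.frame(nodes = x@nodes, edges = x@edges, C = x@C, C_latt = x@Clatt,
             C_rand = x@Crand, L = x@L, L_rand = x@Lrand, S = x@S,
             omega = x@omega, stringsAsFactors = FALSE)
}
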