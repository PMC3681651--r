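#' Normalized Compression Similarity between two spike trains
#'
#' NCS(x, y) = 1 - [C(x(+)y) - min(C(x), C(y))] / max(C(x), C(y)), where
#' C(.) is the PPM ideal code length (\code{\link{codeLength}}) and (+) is
#' sequence concatenation. This reverses the normalized compression
#' distance so that values near 1 mean strong similarity. Because the
#' concatenation order is x then y, the function is mildly asymmetric; that
#' asymmetry carries no causal meaning and downstream graph construction
#' symmetrizes. Raw values can leave [0, 1] by compressor overhead and are
#' clipped.
#'
#' Shared firing patterns are detected at any lag within the window: the
#' model trained while coding x reuses its contexts when coding y, so a
#' common pattern shortens C(x(+)y) regardless of alignment.
#'
#' @param x,y binary integer vectors (same alphabet), both nonempty
#' @param maxOrder maximum PPM context order
#' @param alphabetSize alphabet cardinality
#' @param clip clip the result to [0, 1]? The surrogate test ranks on raw
#'   values: clipping collapses the low tail to an atom at 0 and would
#'   destroy the rank information the permutation p-value relies on
#' @return similarity in [0, 1] (or the raw value when \code{clip = FALSE})
#' @examples
#' set.seed(1)
#' x <- rbinom(1000, 1, 0.5)
#' ncs(x, x, maxOrder = 8)   # close to 1
#' @export
ncs <- function(x, y, maxOrder, alphabetSize = 2L, clip = TRUE) {
  if (length(x) == 0L || length(y) == 0L)
    stop("NCS requires nonempty sequences")
  cx <- codeLength(x, maxOrder, alphabetSize)
  cy <- codeLength(y, maxOrder, alphabetSize)
  mx <- max(cx, cy)
  if (mx <= 0) stop("both sequences have zero code length")
  cxy <- codeLength(concatSequences(x, y, alphabetSize), maxOrder, alphabetSize)
  v <- 1 - (cxy - min(cx, cy)) / mx
  if (clip) min(1, max(0, v)) else v
}

#' Shuffle-surrogate significance of an NCS value
#'
#' Builds a null distribution by independently permuting the spike
#' positions of \code{y} within the window (spike count preserved),
#' recomputing NCS against the intact \code{x}, and returns the add-one
#' permutation p-value (1 + #\{null >= observed\}) / (1 + nSurrogates).
#' Shuffling destroys temporal patterning but keeps the firing rate, so the
#' null captures rate-matched independence.
#'
#' The observed and null similarities are kept on the raw (unclipped) NCS
#' scale: the permutation p-value depends only on ranks, and clipping
#' would collapse the low tail into ties at 0.
#'
#' If either train carries fewer than 1 spike the test is uninformative and
#' p = 1 is returned with a warning.
#'
#' @param x,y binary integer spike trains
#' @param maxOrder maximum PPM context order
#' @param nSurrogates number of shuffles (>= 19)
#' @param seed RNG seed for the shuffles
#' @return a \linkS4class{SurrogateNull}
#' @export
ncsSignificance <- function(x, y, maxOrder, nSurrogates = 99L, seed = 1L) {
  stopifnot(nSurrogates >= 19)
  x <- as.integer(x); y <- as.integer(y)
  if (sum(x) < 1L || sum(y) < 1L) {
    warning("fewer than 1 spike in a train; significance undefined, p = 1")
    return(new("SurrogateNull", observed = NA_real_, nullValues = numeric(0),
               pValue = 1, nSurrogates = as.integer(nSurrogates)))
  }
  obs <- ncs(x, y, maxOrder, clip = FALSE)
  null <- withr_seed(seed, {
    vapply(seq_len(nSurrogates),
           function(i) ncs(x, sample(y), maxOrder, clip = FALSE),
           numeric(1))
  })
  p <- (1 + sum(null >= obs)) / (1 + nSurrogates)
  new("SurrogateNull", observed = obs, nullValues = null, pValue = p,
      nSurrogates = as.integer(nSurrogates))
}

#' NCS adjacency matrix for one raster window
#'
#' Evaluates NCS over all ordered unit pairs of a window (diagonal fixed at
#' zero). The result may be asymmetric; symmetrization happens at
#' binarization time.
#'
#' @param raster a \linkS4class{SpikeRaster} (or binary units x bins matrix)
#'   holding one analysis window
#' @param maxOrder maximum PPM context order; default half the window length
#'   capped at 16 (\code{\link{defaultMaxOrder}})
#' @param windowId window index recorded as provenance
#' @return a \linkS4class{FunctionalAdjacency} with method "ncs"
#' @export
ncsMatrix <- function(raster, maxOrder = NULL, windowId = 1L) {
  if (is(raster, "SpikeRaster")) {
    m <- spikeMatrix(raster); units <- unitIds(raster)
    regions <- regionLabels(raster)
  } else {
    m <- as.matrix(raster); storage.mode(m) <- "integer"
    units <- rownames(m); if (is.null(units)) units <- paste0("u", seq_len(nrow(m)))
    regions <- rep("R1", nrow(m))
  }
  if (nrow(m) < 2) stop("need at least 2 units")
  if (ncol(m) < 2) stop("window shorter than 2 bins")
  if (is.null(maxOrder)) maxOrder <- defaultMaxOrder(ncol(m))
  w <- .ncs_matrix_binary(m, as.integer(maxOrder))
  new("FunctionalAdjacency", weights = w, units = units, regions = regions,
      windowId = as.integer(windowId), method = "ncs")
}

# evaluate expr under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
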