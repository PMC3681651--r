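#' Ideal PPM code length of a symbol sequence
#'
#' Codes the sequence online with a variable-order Markov model estimated by
#' Prediction by Partial Matching (escape method C, full symbol exclusion,
#' fallback to a uniform order -1 model) and returns the ideal arithmetic
#' code length: the accumulated -log2 of every predictive probability,
#' escape events included. No bitstream is emitted; the ideal length is the
#' quantity the compression-distance theory is stated in, and it avoids
#' byte-alignment and container artifacts.
#'
#' Deterministic: identical inputs and order always give bit-identical
#' results.
#'
#' @param x integer vector of symbols in 0..(alphabetSize-1); for spike
#'   trains, a 0/1 vector at 1-ms bins
#' @param maxOrder maximum context order (>= 0)
#' @param alphabetSize alphabet cardinality (2 for spike trains)
#' @return code length in bits (0 for an empty sequence)
#' @examples
#' codeLength(rep(0L, 1000), maxOrder = 8)           # highly compressible
#' codeLength(rbinom(1000, 1, 0.5), maxOrder = 8)    # near 1000 bits
#' @export
codeLength <- function(x, maxOrder, alphabetSize = 2L) {
  stopifnot(maxOrder >= 0, alphabetSize >= 1)
  x <- as.integer(x)
  if (anyNA(x) || (length(x) && (min(x) < 0L || max(x) >= alphabetSize)))
    stop("symbol outside the declared alphabet 0..", alphabetSize - 1L)
  .ppm_code_length(x, as.integer(alphabetSize), as.integer(maxOrder))
}

#' Concatenate two symbol sequences
#'
#' The concatenation x (+) y used inside the compression similarity: the
#' output has x as prefix and y as suffix. Both inputs must be over the same
#' declared alphabet.
#'
#' @param x,y integer symbol vectors
#' @param alphabetSize shared alphabet cardinality; both inputs are checked
#' @return the concatenated integer vector
#' @export
concatSequences <- function(x, y, alphabetSize = 2L) {
  x <- as.integer(x); y <- as.integer(y)
  chk <- function(v, nm) {
    if (anyNA(v) || (length(v) && (min(v) < 0L || max(v) >= alphabetSize)))
      stop("sequence ", nm, " contains symbols outside the shared alphabet")
  }
  chk(x, "x"); chk(y, "y")
  c(x, y)
}

#' Default maximum PPM order for a window length
#'
#' The model order is bounded by half the window length in bins; an
#' additional cap (default 16) keeps the binary context trie tractable for
#' second-long windows while remaining overridable.
#'
#' @param windowBins window length in bins
#' @param cap upper cap on the order; use \code{Inf} to honor the half-window
#'   bound exactly
#' @return integer order
#' @export
defaultMaxOrder <- function(windowBins, cap = 16L) {
  as.integer(min(floor(windowBins / 2), cap))
}
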