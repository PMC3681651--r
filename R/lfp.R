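#' Instantaneous phase via the analytic signal
#'
#' Subtracts the mean, forms the analytic signal by the FFT construction
#' (negative frequencies zeroed, positive doubled) and returns its argument,
#' wrapped to (-pi, pi], one phase per input sample.
#'
#' @param x numeric signal (length >= 4); a constant signal has no defined
#'   phase and is rejected
#' @return numeric phase series, same length as \code{x}
#' @examples
#' t <- seq(0, 1, by = 1e-3)
#' ph <- instantaneousPhase(sin(2 * pi * 10 * t))
#' @export
instantaneousPhase <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 4) stop("signal too short (length >= 4 required)")
  if (!all(is.finite(x))) stop("signal must be finite")
  x <- x - mean(x)
  if (all(abs(x) < .Machine$double.eps * 1e3))
    stop("constant signal: instantaneous phase undefined")
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  analytic <- fft(X * h, inverse = TRUE) / n
  Arg(analytic)
}

#' Phase synchrony between two signals
#'
#' gamma = | mean_t exp(i (phi_x(t) - phi_y(t))) |, the modulus of the mean
#' phase-difference phasor (phase-locking value): 1 for perfect locking,
#' near 0 for asynchronous signals (for independent phases it decays as
#' 1/sqrt(T)). To suppress analytic-signal edge transients, a fraction of
#' samples at each end (default 5\%) is dropped before averaging.
#'
#' @param x,y equal-length numeric signals
#' @param edgeFraction fraction of samples trimmed at each end
#' @return synchrony in [0, 1]
#' @export
phaseSynchrony <- function(x, y, edgeFraction = 0.05) {
  if (length(x) != length(y)) stop("signals must have equal length")
  px <- instantaneousPhase(x)
  py <- instantaneousPhase(y)
  n <- length(px)
  k <- floor(n * edgeFraction)
  idx <- (1 + k):(n - k)
  Mod(mean(exp(1i * (px[idx] - py[idx]))))
}

#' Phase-synchrony adjacency matrix over channels
#'
#' Evaluates \code{\link{phaseSynchrony}} for every unordered channel pair
#' of an \linkS4class{LFPSet} window. The matrix is symmetric with zero
#' diagonal by construction.
#'
#' @param lfp an \linkS4class{LFPSet}
#' @param windowId window index recorded as provenance
#' @param edgeFraction end-trimming fraction passed through
#' @return a \linkS4class{FunctionalAdjacency} with method "plv"
#' @export
plvMatrix <- function(lfp, windowId = 1L, edgeFraction = 0.05) {
  stopifnot(is(lfp, "LFPSet"))
  m <- signalMatrix(lfp)
  nc <- ncol(m)
  if (nc < 2) stop("need at least 2 channels")
  # phases once per channel, then pairwise phasor means
  ph <- apply(m, 2, instantaneousPhase)
  n <- nrow(ph); k <- floor(n * edgeFraction); idx <- (1 + k):(n - k)
  w <- matrix(0, nc, nc)
  for (i in seq_len(nc - 1)) {
    for (j in (i + 1):nc) {
      g <- Mod(mean(exp(1i * (ph[idx, i] - ph[idx, j]))))
      w[i, j] <- w[j, i] <- min(1, g)
    }
  }
  new("FunctionalAdjacency", weights = w, units = channelIds(lfp),
      regions = regionLabels(lfp), windowId = as.integer(windowId),
      method = "plv")
}

#' Zero-phase Butterworth band-pass helper
#'
#' Optional pre-filter for phase extraction on broadband signals. Phase
#' estimation itself runs on whatever the caller supplies; filtering of raw
#' recordings is deliberately left to the caller.
#'
#' @param x numeric signal
#' @param low,high band edges in Hz
#' @param rate sampling rate in Hz
#' @param order filter order
#' @return filtered signal
#' @export
bandpassFilter <- function(x, low, high, rate, order = 4L) {
  if (!requireNamespace("signal", quietly = TRUE))
    stop("the 'signal' package is required for bandpassFilter")
  ny <- rate / 2
  stopifnot(low > 0, high < ny, low < high)
  bf <- signal::butter(order, c(low, high) / ny, type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}
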