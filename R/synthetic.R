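#' Independent uniform binary train pairs
#'
#' The bias benchmark: pairs of i.i.d. uniform (density 0.5) binary
#' sequences with no dependence within or across pairs. On these, a
#' calibrated similarity test must reject at the nominal rate.
#'
#' @param nPairs number of pairs
#' @param length bins per train
#' @param seed RNG seed
#' @return list of \code{nPairs} elements, each \code{list(x, y)}
#' @export
genIndependentPairs <- function(nPairs = 100L, length = 1000L, seed = 1L) {
  stopifnot(length >= 2)
  withr_seed(seed, {
    lapply(seq_len(nPairs), function(i)
      list(x = rbinom(length, 1L, 0.5), y = rbinom(length, 1L, 0.5)))
  })
}

#' Drifting shared-pattern benchmark
#'
#' A fixed train carries a random binary pattern (default 100 bins,
#' density 0.5) centered in a 1000-bin window; each of \code{nDrifts}
#' comparison trains carries the identical pattern at equally spaced
#' offsets, from the window start (drift 1) to flush with the window end
#' (drift \code{nDrifts}). Background spikes with probability
#' \code{noiseRate} per bin are added outside the pattern span, so every
#' train holds exactly pattern spikes plus its noise spikes and the shared
#' pattern itself stays intact.
#'
#' @param window window length in bins
#' @param pattern pattern length in bins (< window)
#' @param nDrifts number of drift positions (>= 2)
#' @param noiseRate background spike probability per bin
#' @param seed RNG seed
#' @return list with \code{fixed} (binary vector), \code{drifts} (list of
#'   binary vectors), \code{offsets} (0-based pattern offsets),
#'   \code{patternBits}, and the generating parameters
#' @export
genDriftBenchmark <- function(window = 1000L, pattern = 100L, nDrifts = 47L,
                              noiseRate = 0.01, seed = 1L) {
  stopifnot(pattern < window, nDrifts >= 2)
  withr_seed(seed, {
    bits <- rbinom(pattern, 1L, 0.5)
    addNoise <- function(train, span) {
      out <- setdiff(seq_len(window), span)
      train[out] <- pmax(train[out], rbinom(length(out), 1L, noiseRate))
      train
    }
    off0 <- round((window - pattern) / 2)
    fixed <- integer(window); fixed[off0 + seq_len(pattern)] <- bits
    fixed <- addNoise(fixed, off0 + seq_len(pattern))
    offsets <- round((window - pattern) * (seq_len(nDrifts) - 1) / (nDrifts - 1))
    drifts <- lapply(offsets, function(o) {
      tr <- integer(window); tr[o + seq_len(pattern)] <- bits
      addNoise(tr, o + seq_len(pattern))
    })
    list(fixed = fixed, drifts = drifts, offsets = offsets,
         patternBits = bits, window = window, pattern = pattern,
         nDrifts = nDrifts, noiseRate = noiseRate, seed = seed,
         fixedOffset = off0)
  })
}

#' Run the drift benchmark with three detectors
#'
#' For every drift position, evaluates (i) NCS with shuffle-surrogate
#' significance, (ii) the Pearson correlation with its t-test, and (iii)
#' the maximum of the lagged cross-correlation with the same
#' shuffle-surrogate null as NCS. Significance flags use alpha = 0.05.
#'
#' @param bench output of \code{\link{genDriftBenchmark}}
#' @param maxOrder maximum PPM order (default \code{defaultMaxOrder} of the
#'   window)
#' @param nSurrogates shuffle surrogates per drift
#' @param seed RNG seed for the surrogates
#' @param alpha significance level
#' @return data.frame, one row per drift: drift index, offset, ncs,
#'   ncsP, pearsonR, pearsonP, maxXcorr, xcorrP plus logical *Sig columns
#' @export
runDriftExperiment <- function(bench, maxOrder = NULL, nSurrogates = 99L,
                               seed = 1L, alpha = 0.05) {
  if (is.null(maxOrder)) maxOrder <- defaultMaxOrder(bench$window)
  x <- bench$fixed
  rows <- lapply(seq_along(bench$drifts), function(i) {
    y <- bench$drifts[[i]]
    sn <- ncsSignificance(x, y, maxOrder, nSurrogates, seed = seed + i)
    ct <- suppressWarnings(cor.test(x, y))
    mx <- .maxLaggedXcorr(x, y)
    xnull <- withr_seed(seed + 10000L + i, {
      vapply(seq_len(nSurrogates),
             function(s) .maxLaggedXcorr(x, sample(y)), numeric(1))
    })
    xp <- (1 + sum(xnull >= mx)) / (1 + nSurrogates)
    data.frame(drift = i, offset = bench$offsets[i], ncs = sn@observed,
               ncsP = pValue(sn), pearsonR = unname(ct$estimate),
               pearsonP = ct$p.value, maxXcorr = mx, xcorrP = xp)
  })
  out <- do.call(rbind, rows)
  out$ncsSig <- out$ncsP <= alpha
  out$pearsonSig <- out$pearsonP <= alpha
  out$xcorrSig <- out$xcorrP <= alpha
  out
}

# maximum over lags of the normalized cross-correlation
.maxLaggedXcorr <- function(x, y, maxLag = NULL) {
  n <- length(x)
  if (is.null(maxLag)) maxLag <- n - 2L
  cc <- ccf(as.numeric(x), as.numeric(y), lag.max = maxLag, plot = FALSE,
            demean = TRUE)
  max(cc$acf)
}

#' First index of the longest contiguous significant run
#'
#' Helper for band summaries of the drift benchmark: isolated alpha-level
#' false positives far from alignment are ignored by taking the longest
#' run of consecutive significant drifts (the central detection band).
#'
#' @param sig logical vector of per-drift significance
#' @return list with \code{first} and \code{last} indices of the band
#'   (NA if no drift is significant)
#' @export
significanceBand <- function(sig) {
  r <- rle(as.logical(sig))
  if (!any(r$values)) return(list(first = NA_integer_, last = NA_integer_))
  ends <- cumsum(r$lengths)
  k <- which(r$values)
  k <- k[which.max(r$lengths[k])]
  list(first = ends[k] - r$lengths[k] + 1L, last = ends[k])
}

#' Phase-coupled signal pair with a target locking value
#'
#' Two sinusoidal carriers at the same frequency; the second receives a
#' slowly varying (low-pass filtered) Gaussian phase jitter scaled so that
#' the wrapped-normal mean resultant exp(-sigma^2/2) equals the target
#' locking. The jitter bandwidth is a tenth of the carrier so the signal
#' stays narrow-band and Hilbert phases track the injected phases. Targets
#' below 0.05 switch to white (unsmoothed) phase jitter: slowly varying
#' phases leave too few effectively independent samples for the empirical
#' locking of truly asynchronous pairs to fall to its 1/sqrt(T) floor.
#'
#' @param targetLocking desired phase-locking value in [0, 1]
#' @param freq carrier frequency (Hz)
#' @param duration seconds
#' @param rate sampling rate (Hz)
#' @param seed RNG seed
#' @return list with \code{x}, \code{y} (numeric signals), the target, and
#'   the jitter SD used
#' @export
genCoupledPair <- function(targetLocking, freq = 10, duration = 10,
                           rate = 1000, seed = 1L) {
  stopifnot(targetLocking >= 0, targetLocking <= 1)
  n <- round(duration * rate)
  tt <- (seq_len(n) - 1) / rate
  base <- 2 * pi * freq * tt
  sigma <- sqrt(-2 * log(max(targetLocking, 1e-4)))
  psi <- withr_seed(seed, {
    raw <- rnorm(n)
    if (targetLocking < 0.05) {
      raw * sigma                                  # white: asynchronous pair
    } else {
      w <- max(3L, round(rate / freq) * 5L)        # ~freq/10 bandwidth
      sm <- as.numeric(filter(c(rev(raw[seq_len(w)]), raw,
                                rev(raw[n + 1 - seq_len(w)])),
                              rep(1 / w, w), sides = 2))
      sm <- sm[(w + 1):(w + n)]
      if (sd(sm) > 0) sm / sd(sm) * sigma else sm
    }
  })
  if (targetLocking >= 1) psi <- numeric(n)
  list(x = cos(base), y = cos(base + psi), targetLocking = targetLocking,
       freq = freq, rate = rate, jitterSd = sigma, seed = seed)
}

#' Lagged shared-pattern train pair
#'
#' A shared random pattern sits at offset 0 in the first train and at
#' \code{lag} in the second; background noise is added outside the pattern
#' spans. Mirrors the situation of a polysynaptic functional link whose
#' common pattern appears at a long delay.
#'
#' @param length train length in bins
#' @param patternLen pattern length (lag + patternLen <= length)
#' @param lag pattern offset in the second train
#' @param noiseRate background spike probability per bin
#' @param seed RNG seed
#' @return list with \code{x}, \code{y}, \code{patternBits}, \code{lag}
#' @export
genLaggedPair <- function(length = 1000L, patternLen = 100L, lag = 400L,
                          noiseRate = 0.01, seed = 1L) {
  if (lag + patternLen > length) stop("lag + patternLen exceeds the train length")
  withr_seed(seed, {
    bits <- rbinom(patternLen, 1L, 0.5)
    addNoise <- function(train, span) {
      out <- setdiff(seq_len(length), span)
      train[out] <- pmax(train[out], rbinom(base::length(out), 1L, noiseRate))
      train
    }
    x <- integer(length); x[seq_len(patternLen)] <- bits
    x <- addNoise(x, seq_len(patternLen))
    y <- integer(length); y[lag + seq_len(patternLen)] <- bits
    y <- addNoise(y, lag + seq_len(patternLen))
    list(x = x, y = y, patternBits = bits, lag = lag, seed = seed)
  })
}
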