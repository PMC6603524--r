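# Phase-space reconstruction: delay embedding with the delay chosen at the
# first local minimum of the auto-mutual information and the dimension
# chosen by the false-nearest-neighbour criterion.

#' Auto-mutual information of a scalar series
#'
#' Plug-in (histogram) mutual information between the series and its
#' lagged copy, on a coarse equal-width amplitude partition (default 8
#' bins) averaged over a few shifted bin origins; natural logarithm. The
#' origin averaging suppresses the lattice artefacts that a single
#' histogram origin produces on strongly periodic signals, so the curve of
#' a tremor-band sinusoid attains its first local minimum near a quarter
#' period, as it should. `MI(0)` is the plug-in entropy of the binned
#' marginal (origin-averaged) and the estimate is non-negative at every
#' lag up to estimator tolerance. A constant (zero-entropy) series returns
#' all-zero values flagged as degenerate.
#'
#' @param x numeric series.
#' @param tauMax largest lag to evaluate.
#' @param bins number of marginal bins (default 8).
#' @param dither number of histogram-origin shifts averaged (default 4).
#' @return Numeric vector of `MI(tau)` for `tau = 0..tauMax` (nats), with
#'   attribute `degenerate` set to TRUE for a constant input.
#' @seealso [selectTau()]
#' @examples
#' mi <- autoMutualInformation(sin(2 * pi * (0:999) / 24), 20)
#' selectTau(mi)   # ~ period / 4
#' @export
autoMutualInformation <- function(x, tauMax, bins = 8, dither = 4) {
  N <- length(x)
  if (N <= tauMax + 10L) stop("series too short for tauMax = ", tauMax)
  if (stats::sd(x) == 0) {
    out <- numeric(tauMax + 1L)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  B <- as.integer(bins)
  K <- as.integer(dither)
  rg <- range(x)
  wd <- diff(rg) * (1 + 1e-9)
  out <- numeric(tauMax + 1L)
  for (k in 0:(K - 1L)) {
    off <- wd / B * k / K
    bin <- pmin(B, pmax(1L, 1L + floor((x - rg[1] + off) / wd * B)))
    for (tau in 0:tauMax) {
      a <- bin[1:(N - tau)]
      b <- bin[(1 + tau):N]
      M <- length(a)
      joint <- tabulate((a - 1L) * B + b, nbins = B * B) / M
      dim(joint) <- c(B, B)       # joint[b, a]
      pa <- colSums(joint)
      pb <- rowSums(joint)
      nz <- joint > 0
      pp <- outer(pb, pa)
      out[tau + 1L] <- out[tau + 1L] + sum(joint[nz] * log(joint[nz] / pp[nz]))
    }
  }
  out <- out / K
  attr(out, "degenerate") <- FALSE
  out
}

#' Select the embedding delay from an auto-mutual-information curve
#'
#' Returns the smallest lag `tau >= 1` that is a local minimum in the
#' ties-left sense: `MI(tau) <= MI(tau - 1)` and `MI(tau) < MI(tau + 1)`,
#' i.e. a flat run counts as one minimum located where the curve finally
#' rises. If the curve has no interior local minimum
#' (e.g. strictly decreasing throughout), the fallback is the first lag at
#' which MI drops below `MI(0)/e`, else the largest lag evaluated, with a
#' warning in either case.
#'
#' @param mi numeric vector of `MI(tau)` values for `tau = 0..tauMax`
#'   (at least 3 values).
#' @return Integer delay in samples.
#' @examples
#' selectTau(c(4, 3, 2, 2.5, 1))  # 2
#' @export
selectTau <- function(mi) {
  if (length(mi) < 3L) stop("need MI values at >= 3 lags")
  tauMax <- length(mi) - 1L
  for (tau in 1:(tauMax - 1L)) {
    if (mi[tau + 1L] <= mi[tau] && mi[tau + 1L] < mi[tau + 2L])
      return(as.integer(tau))
  }
  below <- which(mi < mi[1] / exp(1)) - 1L
  below <- below[below >= 1L]
  fb <- if (length(below)) min(below) else tauMax
  warning("no interior local minimum in MI; falling back to tau = ", fb)
  as.integer(fb)
}

#' False-nearest-neighbour fractions
#'
#' For each trial dimension `m = 1..mMax`, embeds the series at delay
#' `tau`, finds each point's Euclidean nearest neighbour, and marks the
#' pair false when adding the (m+1)-th delay coordinate either inflates
#' the neighbour distance by a factor above `rtol` or moves the pair
#' farther apart than `atol` times the series' standard deviation
#' (the two Kennel criteria). Points whose nearest neighbour is farther
#' than one standard deviation are excluded as unreliable ("lonely").
#'
#' @param x numeric series.
#' @param tau embedding delay (samples).
#' @param mMax largest dimension to test.
#' @param rtol,atol Kennel thresholds (defaults 10 and 2).
#' @return Numeric vector of false-neighbour fractions for `m = 1..mMax`
#'   (NA where too few embeddable points remain).
#' @seealso [selectM()]
#' @export
falseNearestNeighbours <- function(x, tau, mMax, rtol = 10, atol = 2) {
  stopifnot(tau >= 1, mMax >= 1)
  if (length(x) - mMax * tau < 2L)
    stop("series too short to embed at mMax = ", mMax)
  .cpp_fnn_fractions(as.numeric(x), as.integer(tau), as.integer(mMax),
                     rtol, atol)
}

#' Select the embedding dimension from FNN fractions
#'
#' The smallest dimension whose false-neighbour fraction is at or below
#' `threshold` (default 1%, "arbitrarily small" to absorb noise); if the
#' fraction never falls that low, the largest tested dimension is returned
#' with a warning.
#'
#' @param fnn numeric vector of fractions for `m = 1..mMax`.
#' @param threshold acceptance threshold on the fraction.
#' @return Integer embedding dimension.
#' @examples
#' selectM(c(0.9, 0.4, 0.005, 0.004))  # 3
#' @export
selectM <- function(fnn, threshold = 0.01) {
  ok <- which(!is.na(fnn) & fnn <= threshold)
  if (length(ok)) return(as.integer(ok[1]))
  warning("FNN fraction never fell below ", threshold,
          "; using mMax = ", length(fnn))
  as.integer(length(fnn))
}

#' Delay-embed a scalar series
#'
#' Builds the matrix of delay vectors
#' `x(n) = (u(n), u(n + tau), ..., u(n + (m-1) tau))`, one state vector per
#' row; `N - (m-1) tau` rows for a series of length `N`.
#'
#' @param x numeric series.
#' @param params an [EmbeddingParams-class] (or anything coercible via
#'   `embeddingParams(tau, m)`).
#' @return Numeric matrix of embedded state vectors with attribute
#'   `sourceIndices` giving each row's starting sample index (1-based).
#' @examples
#' embedSeries(1:5, embeddingParams(2, 2))
#' @export
embedSeries <- function(x, params) {
  stopifnot(is(params, "EmbeddingParams"))
  tau <- params@tau
  m <- params@m
  N <- length(x)
  npts <- N - (m - 1L) * tau
  if (npts < 1L) stop("series too short to embed (need N > (m-1) tau)")
  E <- matrix(0, nrow = npts, ncol = m)
  for (j in seq_len(m))
    E[, j] <- x[(1L + (j - 1L) * tau):(npts + (j - 1L) * tau)]
  attr(E, "sourceIndices") <- seq_len(npts)
  E
}

#' Select embedding parameters for a recording
#'
#' Estimates the delay (first local minimum of the auto-mutual
#' information) and the dimension (first FNN fraction at or below the
#' threshold) from a single stretch of signal, normally the initial
#' atremorous segment of a recording. The selected pair is then held fixed
#' across all analysis windows of that recording so the per-window networks
#' have comparable sizes; a per-window mode exists for robustness studies
#' via [measureTimecourse()]'s `params` argument.
#'
#' @param x numeric series (e.g. the first seconds of a filtered LFP), or a
#'   [Recording-class] from which the first `selectS` seconds are taken.
#' @param tauMax largest delay to consider (samples).
#' @param mMax largest dimension to consider.
#' @param fnnThreshold acceptance threshold for [selectM()].
#' @param selectS when `x` is a Recording: seconds of signal used.
#' @return An [EmbeddingParams-class] with attributes `mi` and `fnn`
#'   (the diagnostic curves).
#' @export
selectEmbedding <- function(x, tauMax = 25, mMax = 10, fnnThreshold = 0.01,
                            selectS = 10) {
  if (is(x, "Recording"))
    x <- x@samples[seq_len(min(length(x@samples),
                               as.integer(selectS * x@rate)))]
  mi <- autoMutualInformation(x, tauMax)
  tau <- suppressWarnings(selectTau(mi))
  fnn <- falseNearestNeighbours(x, tau, mMax)
  m <- suppressWarnings(selectM(fnn, fnnThreshold))
  p <- embeddingParams(tau, m)
  attr(p, "mi") <- mi
  attr(p, "fnn") <- fnn
  p
}
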