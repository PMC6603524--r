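# epsilon-recurrence networks at fixed recurrence rate, and their global
# measures: clustering, transitivity, degree assortativity.

#' Distance threshold for a target recurrence rate
#'
#' Chooses `epsilon` as the smallest pairwise maximum-norm distance `d`
#' such that the fraction of off-diagonal state pairs with distance `<= d`
#' is at least `rr` (a deterministic, tie-stable quantile convention).
#' Because boundary distances count as recurrent, the achieved rate is
#' always `>= rr`; apart from heavy distance ties it stays within 0.005 of
#' the request, and a tie flag is raised otherwise.
#'
#' @param points embedded state vectors (matrix, one vector per row), e.g.
#'   from [embedSeries()].
#' @param rr target recurrence rate in (0, 1).
#' @return The threshold `epsilon`, with attributes `achievedRR` and
#'   `tieFlag`.
#' @seealso [buildNetwork()]
#' @examples
#' pts <- embedSeries(sin(2 * pi * (0:499) / 25), embeddingParams(6, 3))
#' epsilonForRR(pts, 0.03)
#' @export
epsilonForRR <- function(points, rr = 0.03) {
  if (is.vector(points)) points <- matrix(points, ncol = 1)
  n <- nrow(points)
  if (n < 2L) stop("need at least 2 embedded points")
  if (rr <= 0 || rr >= 1) stop("rr must lie in (0, 1)")
  D <- .cpp_maxnorm_dist(points)
  d <- sort(D[upper.tri(D)])
  if (d[length(d)] == 0)
    stop("all state vectors identical: every pairwise distance is zero")
  M <- length(d)
  k <- ceiling(rr * M)
  eps <- d[k]
  ach <- sum(d <= eps) / M
  tie <- ach > rr + 0.005
  structure(eps, achievedRR = ach, tieFlag = tie)
}

#' Build an epsilon-recurrence network
#'
#' Links every pair of state vectors whose maximum-norm distance is at most
#' `epsilon` (boundary inclusive, i.e. the Heaviside step with
#' `Theta(0) = 1`); the adjacency matrix is the recurrence matrix minus its
#' diagonal. An optional Theiler window excludes pairs of temporally close
#' states (default 0: no exclusion).
#'
#' @param points embedded state vectors (matrix, one per row).
#' @param epsilon distance threshold; when missing it is derived from `rr`
#'   via [epsilonForRR()].
#' @param rr target recurrence rate used when `epsilon` is missing.
#' @param theiler temporal exclusion half-width in samples (pairs with
#'   index difference `<= theiler` are never linked).
#' @return A [RecurrenceNetwork-class].
#' @examples
#' pts <- matrix(c(0, 1, 2, 10), ncol = 1)
#' adjacency(buildNetwork(pts, epsilon = 1.5))
#' @export
buildNetwork <- function(points, epsilon = NULL, rr = 0.03, theiler = 0L) {
  if (is.vector(points)) points <- matrix(points, ncol = 1)
  n <- nrow(points)
  if (n < 2L) stop("need at least 2 embedded points")
  tieFlag <- FALSE
  if (is.null(epsilon)) {
    epsilon <- epsilonForRR(points, rr)
    tieFlag <- attr(epsilon, "tieFlag")
    epsilon <- as.numeric(epsilon)
  }
  D <- .cpp_maxnorm_dist(points)
  A <- (D <= epsilon) * 1L
  diag(A) <- 0L
  if (theiler > 0L) {
    idx <- seq_len(n)
    near <- abs(outer(idx, idx, "-")) <= theiler
    A[near] <- 0L
    diag(A) <- 0L
  }
  storage.mode(A) <- "integer"
  ach <- sum(A) / (n * (n - 1))
  new("RecurrenceNetwork", adjacency = A, epsilon = as.numeric(epsilon),
      achievedRR = ach, tieFlag = isTRUE(tieFlag))
}

.counts <- function(net) {
  if (is(net, "RecurrenceNetwork")) net <- net@adjacency
  storage.mode(net) <- "integer"
  .cpp_adjacency_counts(net)
}

#' Global clustering coefficient
#'
#' Mean over all vertices of the local clustering coefficient
#' `C_i = (# linked neighbour pairs of i) / (k_i (k_i - 1) / 2)`.
#' Vertices with degree below 2 contribute `C_i = 0` rather than being
#' dropped, so the average always runs over all `N` vertices (isolated
#' vertices deflate `C`, which is the documented behaviour on sparse
#' windows).
#'
#' @param net a [RecurrenceNetwork-class] or binary symmetric adjacency
#'   matrix.
#' @return Clustering coefficient in `[0, 1]`.
#' @seealso [globalTransitivity()], [degreeAssortativity()]
#' @export
globalClustering <- function(net) {
  ct <- .counts(net)
  k <- ct$degree
  ci <- ifelse(k >= 2, 2 * ct$tri / (k * (k - 1)), 0)
  mean(ci)
}

#' Transitivity of a network
#'
#' `T = 3 x (# triangles) / (# connected triples)`: the fraction of
#' "open" vertex triples that close into triangles, normalised over the
#' whole network (hence more robust than clustering to low-degree
#' vertices). Returns 0 for a network without any connected triple.
#'
#' @inheritParams globalClustering
#' @return Transitivity in `[0, 1]`.
#' @export
globalTransitivity <- function(net) {
  ct <- .counts(net)
  if (ct$triples == 0) return(0)
  ct$triangles3 / ct$triples
}

#' Degree assortativity of a network
#'
#' Newman's degree-degree Pearson correlation over the endpoints of every
#' edge (both orientations). Undefined — returned as `NA` with attribute
#' `undefined = TRUE` — when the endpoint-degree variance is zero, as on
#' regular graphs or empty edge sets.
#'
#' @inheritParams globalClustering
#' @return Assortativity in `[-1, 1]`, or `NA` (flagged) when undefined.
#' @export
degreeAssortativity <- function(net) {
  A <- if (is(net, "RecurrenceNetwork")) net@adjacency else net
  k <- rowSums(A)
  e <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
  if (nrow(e) == 0) return(structure(NA_real_, undefined = TRUE))
  ki <- k[e[, 1]]
  kj <- k[e[, 2]]
  # Pearson over both edge orientations, in its edge-sum form
  m1 <- mean(0.5 * (ki + kj))
  num <- mean(ki * kj) - m1^2
  den <- mean(0.5 * (ki^2 + kj^2)) - m1^2
  if (den <= .Machine$double.eps * max(1, mean(ki^2)))
    return(structure(NA_real_, undefined = TRUE))
  structure(num / den, undefined = FALSE)
}

#' All three global network measures
#'
#' @inheritParams globalClustering
#' @return Named list with `C` (clustering), `T` (transitivity), `A`
#'   (assortativity, NA when undefined) and `degrees`.
#' @examples
#' pts <- embedSeries(sin(2 * pi * (0:499) / 25), embeddingParams(6, 3))
#' net <- buildNetwork(pts, rr = 0.03)
#' networkMeasures(net)[c("C", "T", "A")]
#' @export
networkMeasures <- function(net) {
  ct <- .counts(net)
  k <- ct$degree
  ci <- ifelse(k >= 2, 2 * ct$tri / (k * (k - 1)), 0)
  Tval <- if (ct$triples == 0) 0 else ct$triangles3 / ct$triples
  list(C = mean(ci), T = Tval,
       A = as.numeric(degreeAssortativity(net)), degrees = k)
}
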