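# Brute-force oracles used to validate the network measures and the
# recurrence construction, deliberately naive (O(N^2)/O(N^3) loops) and
# independent of the package's implementation paths.

bruteMaxDist <- function(P) {
  n <- nrow(P)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    D[i, j] <- max(abs(P[i, ] - P[j, ]))
  D
}

bruteAdjacency <- function(P, eps) {
  n <- nrow(P)
  A <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && max(abs(P[i, ] - P[j, ])) <= eps) A[i, j] <- 1L
  A
}

bruteClustering <- function(A) {
  n <- nrow(A)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(A[i, ])
    if (k < 2) next
    num <- 0
    for (j in seq_len(n)) for (q in seq_len(n))
      num <- num + A[i, j] * A[j, q] * A[q, i]
    ci[i] <- num / (k * (k - 1))
  }
  mean(ci)
}

bruteTransitivity <- function(A) {
  n <- nrow(A)
  num <- den <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) for (q in seq_len(n)) {
    num <- num + A[i, j] * A[j, q] * A[q, i]
    if (j != q) den <- den + A[i, j] * A[i, q]
  }
  if (den == 0) return(0)
  num / den
}

bruteAssortativity <- function(A) {
  k <- rowSums(A)
  ii <- jj <- c()
  n <- nrow(A)
  for (i in seq_len(n)) for (j in seq_len(n)) if (A[i, j] == 1) {
    ii <- c(ii, i); jj <- c(jj, j)   # both orientations
  }
  if (!length(ii)) return(NA_real_)
  x <- k[ii]; y <- k[jj]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

randomGraph <- function(n, p) {
  A <- matrix(0L, n, n)
  up <- which(upper.tri(A))
  A[up] <- as.integer(stats::runif(length(up)) < p)
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  A
}

# star graph: vertex 1 is the hub
starGraph <- function(leaves) {
  A <- matrix(0L, leaves + 1, leaves + 1)
  A[1, -1] <- 1L
  A[-1, 1] <- 1L
  A
}

completeGraph <- function(n) {
  A <- matrix(1L, n, n)
  diag(A) <- 0L
  A
}

cycleGraph <- function(n) {
  A <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    j <- i %% n + 1
    A[i, j] <- A[j, i] <- 1L
  }
  A
}

pathGraph <- function(n) {
  A <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1L
  A
}
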