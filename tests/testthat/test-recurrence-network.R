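test_that("epsilonForRR picks the tie-stable quantile of max-norm distances", {
  pts <- matrix(0:9, ncol = 1)
  # 45 pairs; the 9 adjacent ones have distance 1: rr up to 9/45 keeps
  # only adjacent pairs and the network is a path
  eps <- epsilonForRR(pts, 0.15)
  expect_gte(as.numeric(eps), 1)
  expect_lt(as.numeric(eps), 2)
  net <- buildNetwork(pts, epsilon = as.numeric(eps))
  expect_equal(adjacency(net), pathGraph(10), ignore_attr = TRUE)
  # rr -> 1 gives the complete graph
  full <- buildNetwork(pts, rr = 0.999)
  expect_equal(sum(adjacency(full)), 10 * 9)
  expect_error(epsilonForRR(matrix(1, 5, 2), 0.1), "identical")
  # achieved rate is never below the request
  set.seed(4)
  for (i in 1:10) {
    P <- matrix(rnorm(60), ncol = 3)
    rr <- runif(1, 0.02, 0.3)
    e <- epsilonForRR(P, rr)
    expect_gte(attr(e, "achievedRR"), rr)
  }
})

test_that("epsilon is monotone in rr and edge sets are nested", {
  set.seed(9)
  P <- matrix(rnorm(200), ncol = 2)
  rrs <- c(0.02, 0.05, 0.1, 0.3)
  eps <- vapply(rrs, function(r) as.numeric(epsilonForRR(P, r)), numeric(1))
  expect_true(all(diff(eps) >= 0))
  nets <- lapply(eps, function(e) adjacency(buildNetwork(P, epsilon = e)))
  for (i in seq_len(length(nets) - 1))
    expect_true(all(nets[[i]] <= nets[[i + 1]]))
})

test_that("buildNetwork matches the naive double loop, boundary inclusive", {
  set.seed(21)
  P <- matrix(rnorm(90), ncol = 3)
  eps <- as.numeric(epsilonForRR(P, 0.1))
  net <- buildNetwork(P, epsilon = eps)
  expect_identical(adjacency(net), bruteAdjacency(P, eps))
  # three identical points: complete K3 for any positive epsilon
  same <- matrix(1, 3, 2)
  expect_equal(sum(adjacency(buildNetwork(same, epsilon = 0.5))), 6)
  # Theta(0) = 1: distance exactly epsilon is recurrent
  two <- matrix(c(0, 3), ncol = 1)
  expect_equal(sum(adjacency(buildNetwork(two, epsilon = 3))), 2)
  # far-apart 1-D points with small epsilon: empty graph
  expect_equal(sum(adjacency(buildNetwork(matrix(c(0, 10, 20), ncol = 1),
                                          epsilon = 5))), 0)
})

test_that("measures take their textbook values on canonical graphs", {
  expect_equal(globalClustering(completeGraph(4)), 1)
  expect_equal(globalTransitivity(completeGraph(4)), 1)
  star <- starGraph(4)
  expect_equal(globalClustering(star), 0)
  expect_equal(globalTransitivity(star), 0)
  expect_equal(as.numeric(degreeAssortativity(star)), -1)
  tri <- completeGraph(3)
  expect_equal(globalTransitivity(tri), 1)
  expect_equal(globalTransitivity(pathGraph(3)), 0)
  # regular graph: endpoint-degree variance is zero
  a <- degreeAssortativity(cycleGraph(6))
  expect_true(is.na(a))
  expect_true(attr(a, "undefined"))
  # empty graph: no triples, no edges
  empty <- matrix(0L, 5, 5)
  expect_equal(globalClustering(empty), 0)
  expect_equal(globalTransitivity(empty), 0)
  expect_true(is.na(degreeAssortativity(empty)))
})

test_that("measures equal brute-force enumeration on random graphs", {
  set.seed(33)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    A <- randomGraph(n, runif(1, 0.05, 0.6))
    expect_equal(globalClustering(A), bruteClustering(A), tolerance = 1e-12)
    expect_equal(globalTransitivity(A), bruteTransitivity(A),
                 tolerance = 1e-12)
    got <- as.numeric(degreeAssortativity(A))
    want <- bruteAssortativity(A)
    if (is.na(want)) expect_true(is.na(got))
    else expect_lt(abs(got - want), 1e-12)
  }
})

test_that("measures agree with igraph on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(44)
  for (i in 1:10) {
    A <- randomGraph(30, 0.25)
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    # igraph leaves degree<2 vertices NaN; the package scores them 0
    liG <- igraph::transitivity(g, type = "local")
    liG[is.nan(liG)] <- 0
    expect_equal(globalClustering(A), mean(liG), tolerance = 1e-12)
    expect_equal(globalTransitivity(A),
                 igraph::transitivity(g, type = "global"),
                 tolerance = 1e-12)
    expect_equal(as.numeric(degreeAssortativity(A)),
                 igraph::assortativity_degree(g), tolerance = 1e-12)
  }
})

test_that("measures are invariant under vertex relabelling", {
  set.seed(55)
  A <- randomGraph(25, 0.3)
  p <- sample(25)
  B <- A[p, p]
  expect_equal(globalClustering(A), globalClustering(B))
  expect_equal(globalTransitivity(A), globalTransitivity(B))
  expect_equal(as.numeric(degreeAssortativity(A)),
               as.numeric(degreeAssortativity(B)))
})

test_that("structured dynamics score higher transitivity than noise", {
  xs <- generateBenchmarkSignals("sine", 1000, period = 24)
  set.seed(6)
  xn <- rnorm(1000) * stats::sd(xs)
  p <- embeddingParams(6, 3)
  Ts <- globalTransitivity(buildNetwork(embedSeries(xs, p), rr = 0.03))
  Tn <- globalTransitivity(buildNetwork(embedSeries(xn, p), rr = 0.03))
  expect_gt(Ts, Tn)
})

test_that("a Theiler window removes temporal neighbours only", {
  set.seed(8)
  P <- embedSeries(rnorm(100), embeddingParams(1, 2))
  eps <- as.numeric(epsilonForRR(P, 0.2))
  a0 <- adjacency(buildNetwork(P, epsilon = eps))
  a2 <- adjacency(buildNetwork(P, epsilon = eps, theiler = 2))
  idx <- abs(outer(seq_len(nrow(P)), seq_len(nrow(P)), "-"))
  expect_true(all(a2[idx <= 2] == 0))
  expect_identical(a2[idx > 2], a0[idx > 2])
})
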