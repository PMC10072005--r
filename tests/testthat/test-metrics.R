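test_that("hand-derived metric values are reproduced exactly", {
  # triangle
  expect_equal(clusteringCoef(adjTriangle), 1)
  expect_equal(transitivityCoef(adjTriangle), 1)
  expect_equal(localEfficiency(adjTriangle), 1)
  # path P3
  expect_equal(clusteringCoef(adjPath3), 0)
  expect_equal(as.numeric(charPathLength(shortestPaths(adjPath3))), 4 / 3)
  expect_equal(globalEfficiency(shortestPaths(adjPath3)), 5 / 6)
  expect_equal(localEfficiency(adjPath3), 0)
  expect_equal(transitivityCoef(adjPath3), 0)
  # K4 minus one edge
  expect_equal(clusteringCoef(adjK4minus), 5 / 6)
  expect_equal(transitivityCoef(adjK4minus), 0.75)
  # star S4: no triangles anywhere
  expect_equal(localEfficiency(adjStar4), 0)
  # complete graph
  k5 <- 1 - diag(5)
  expect_equal(clusteringCoef(k5), 1)
  expect_equal(as.numeric(charPathLength(shortestPaths(k5))), 1)
  expect_equal(globalEfficiency(shortestPaths(k5)), 1)
  # empty graph
  e4 <- matrix(0, 4, 4)
  expect_equal(globalEfficiency(shortestPaths(e4)), 0)
  expect_warning(L <- charPathLength(shortestPaths(e4)), "no reachable")
  expect_true(is.na(L))
  # two disjoint edges: L over reachable pairs only, fraction reported
  d2 <- matrix(0, 4, 4); d2[1, 2] <- d2[2, 1] <- d2[3, 4] <- d2[4, 3] <- 1
  L2 <- charPathLength(shortestPaths(d2))
  expect_equal(as.numeric(L2), 1)
  expect_equal(attr(L2, "reachableFraction"), 4 / 12)
})

finEnc <- function(d) { d[!is.finite(d)] <- -1; d } # compare Inf patterns

test_that("metrics agree with brute-force oracles on every small graph", {
  worst <- 0
  for (n in 3:5) {
    pats <- allEdgePatterns(n)
    for (i in seq_len(nrow(pats))) {
      a <- adjFromBits(n, pats[i, ])
      if (!isConnected(a)) next
      d <- shortestPaths(a)
      worst <- max(worst,
                   abs(finEnc(unname(d)) - finEnc(unname(bruteDistances(a)))),
                   abs(clusteringCoef(a) - bruteClustering(a)),
                   abs(as.numeric(charPathLength(d)) - bruteCharPath(a)),
                   abs(globalEfficiency(d) - bruteGE(a)),
                   abs(localEfficiency(a) - bruteLE(a)),
                   abs(transitivityCoef(a) - bruteTransitivity(a)))
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("metrics agree with oracles and igraph on random 7-node graphs", {
  skipIg <- !requireNamespace("igraph", quietly = TRUE)
  worst <- 0
  worstIg <- 0
  for (s in 1:60) {
    a <- randomAdj(7, runif(1, 0.25, 0.8), seed = s)
    d <- shortestPaths(a)
    worst <- max(worst,
                 abs(finEnc(unname(d)) - finEnc(unname(bruteDistances(a)))),
                 abs(clusteringCoef(a) - bruteClustering(a)),
                 abs(globalEfficiency(d) - bruteGE(a)),
                 abs(localEfficiency(a) - bruteLE(a)),
                 abs(transitivityCoef(a) - bruteTransitivity(a)))
    if (!skipIg) {
      g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
      tIg <- igraph::transitivity(g, type = "global")
      worstIg <- max(worstIg,
                     abs(finEnc(unname(d)) - finEnc(unname(igraph::distances(g)))),
                     abs(transitivityCoef(a) - ifelse(is.nan(tIg), 0, tIg)),
                     abs(clusteringCoef(a) -
                           mean(igraph::transitivity(g, type = "local",
                                                     isolates = "zero"))))
    }
  }
  expect_lt(worst, 1e-12)
  if (!skipIg) expect_lt(worstIg, 1e-12)
})

test_that("metrics are invariant under node relabeling", {
  set.seed(21)
  a <- randomAdj(9, 0.4, seed = 3)
  p <- sample(9)
  b <- a[p, p]
  expect_equal(clusteringCoef(a), clusteringCoef(b))
  expect_equal(as.numeric(charPathLength(shortestPaths(a))),
               as.numeric(charPathLength(shortestPaths(b))))
  expect_equal(globalEfficiency(shortestPaths(a)),
               globalEfficiency(shortestPaths(b)))
  expect_equal(localEfficiency(a), localEfficiency(b))
  expect_equal(transitivityCoef(a), transitivityCoef(b))
})

test_that("metric bounds hold across a full sweep", {
  set.seed(31)
  zr <- matrix(rnorm(484), 22)
  nets <- thresholdSweep(ZMatrix(zr + t(zr)))
  for (net in nets[seq(1, 41, by = 8)]) {
    m <- smallWorldMetrics(net)
    expect_true(all(m[c("C", "GE", "LE", "T")] >= 0 &
                      m[c("C", "GE", "LE", "T")] <= 1))
    expect_gte(m[["L"]], 1)
  }
})

test_that("randomReference preserves degrees and destroys lattice clustering", {
  latt <- BinaryNetwork(makeGroupNetwork(22, 44 / 231, 0))
  rr <- randomReference(latt, seed = 1)
  expect_equal(sort(rowSums(adjacency(rr))), sort(rowSums(adjacency(latt))))
  expect_identical(adjacency(randomReference(latt, seed = 8)),
                   adjacency(randomReference(latt, seed = 8)))

  # randomization reduces the lattice's clustering on average
  cs <- vapply(1:20, function(s)
    clusteringCoef(randomReference(latt, seed = s)), numeric(1))
  expect_lt(mean(cs), clusteringCoef(latt))

  # ring of 4: degree sequence (2,2,2,2) preserved
  ring4 <- matrix(0, 4, 4)
  ring4[cbind(1:4, c(2, 3, 4, 1))] <- 1
  ring4 <- ring4 + t(ring4)
  rr4 <- randomReference(BinaryNetwork(ring4), seed = 2)
  expect_equal(sort(rowSums(adjacency(rr4))), rep(2, 4))

  # degenerate input: returned unchanged with a warning
  one <- matrix(0, 3, 3); one[1, 2] <- one[2, 1] <- 1
  expect_warning(same <- randomReference(BinaryNetwork(one)), "fewer than 2")
  expect_equal(adjacency(same), adjacency(BinaryNetwork(one)))
})

test_that("normalized small-world ratios behave as expected", {
  # an already-random graph self-normalizes to ~1
  gs <- t(vapply(1:20, function(s) {
    er <- BinaryNetwork(randomAdj(22, 0.5, seed = 100 + s))
    normalizedSmallWorld(er, nRandom = 15, seed = s)[c("gamma", "lambda")]
  }, numeric(2)))
  expect_true(all(gs[, 1] > 0.8 & gs[, 1] < 1.2))
  expect_true(all(gs[, 2] > 0.95 & gs[, 2] < 1.05))

  # a ring lattice is far more clustered than its random references
  latt <- BinaryNetwork(makeGroupNetwork(22, 44 / 231, 0))
  nl <- normalizedSmallWorld(latt, nRandom = 15, seed = 3)
  expect_gt(nl[["gamma"]], 2)

  # delta == gamma / lambda to machine precision; exact reproducibility
  n1 <- normalizedSmallWorld(latt, nRandom = 1, seed = 5)
  n2 <- normalizedSmallWorld(latt, nRandom = 1, seed = 5)
  expect_identical(n1, n2)
  expect_equal(n1[["delta"]], n1[["gamma"]] / n1[["lambda"]],
               tolerance = 1e-12)
})

test_that("metricAUC is the trapezoidal integral on the exact grid", {
  expect_equal(metricAUC(rep(2, 41), seq(0.3, 0.7, 0.01)), 0.4 * 2)
  expect_equal(metricAUC(seq(0, 1, length.out = 41), seq(0.3, 0.7, 0.01)),
               0.2)
  expect_equal(metricAUC(c(1, 3), c(0.3, 0.4)), 0.2)
  expect_error(metricAUC(1:3, c(0.3, 0.4)), "equal length")
  expect_error(metricAUC(c(1, 2), c(0.4, 0.3)), "increasing")
})

test_that("subjectProfile assembles curves and AUCs deterministically", {
  # high, distinct |z|: the densest network of the sweep is complete
  z <- distinctZ(6)
  z@z <- z@z + sign(z@z) * 2
  nets <- thresholdSweep(z, 0, 0.5, 0.25)
  prof <- subjectProfile(nets, nRandom = 3, seed = 4, subjectId = "s1")
  expect_equal(unname(metricCurves(prof)[1, c("C", "L", "GE", "T")]),
               rep(1, 4))
  expect_equal(dim(metricCurves(prof)), c(3L, 8L))
  expect_length(metricAUCs(prof), 8L)

  prof2 <- subjectProfile(nets, nRandom = 3, seed = 4, subjectId = "s1")
  expect_identical(metricCurves(prof), metricCurves(prof2))
  expect_identical(metricAUCs(prof), metricAUCs(prof2))
})
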