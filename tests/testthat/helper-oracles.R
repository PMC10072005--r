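# Brute-force graph-metric oracles: direct enumeration, independent of the
# package's implementations (no shared code paths, no BFS reuse).

bruteClustering <- function(a) {
  n <- nrow(a)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    e <- 0
    for (x in seq_along(nb)) for (y in seq_len(x - 1)) {
      if (a[nb[x], nb[y]] == 1) e <- e + 1
    }
    ci[i] <- 2 * e / (k * (k - 1))
  }
  mean(ci)
}

bruteDistances <- function(a) { # Floyd-Warshall
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[a == 1] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

bruteCharPath <- function(a) {
  d <- bruteDistances(a)
  off <- d[row(d) != col(d)]
  mean(off[is.finite(off)])
}

bruteGE <- function(a) {
  n <- nrow(a)
  if (n < 2) return(0)
  d <- bruteDistances(a)
  off <- d[row(d) != col(d)]
  sum(1 / off[is.finite(off)]) / (n * (n - 1))
}

bruteLE <- function(a) {
  n <- nrow(a)
  mean(vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] == 1)
    if (length(nb) < 2) return(0)
    bruteGE(a[nb, nb, drop = FALSE])
  }, numeric(1)))
}

bruteTransitivity <- function(a) {
  n <- nrow(a)
  tri <- 0
  trip <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (i < j && j < k) {
      e <- a[i, j] + a[i, k] + a[j, k]
      if (e == 3) tri <- tri + 1
    }
  }
  deg <- rowSums(a)
  trip <- sum(deg * (deg - 1) / 2)
  if (trip == 0) return(0)
  3 * tri / trip
}

# random undirected graph helpers
randomAdj <- function(n, p, seed) {
  set.seed(seed)
  a <- matrix(0L, n, n)
  ut <- upper.tri(a)
  a[ut] <- rbinom(sum(ut), 1, p)
  a[lower.tri(a)] <- t(a)[lower.tri(a)]
  a
}

isConnected <- function(a) all(is.finite(bruteDistances(a)))

# enumerate every labeled graph on n nodes from an integer bitmask
adjFromBits <- function(n, bits) {
  a <- matrix(0L, n, n)
  ut <- which(upper.tri(a))
  a[ut] <- bits
  a[lower.tri(a)] <- t(a)[lower.tri(a)]
  a
}

allEdgePatterns <- function(n) {
  m <- n * (n - 1) / 2
  if (m == 0) return(matrix(integer(0), 1, 0))
  as.matrix(expand.grid(rep(list(0:1), m)))
}

# small toy adjacencies used across tests
adjTriangle <- matrix(c(0,1,1, 1,0,1, 1,1,0), 3, 3)
adjPath3 <- matrix(c(0,1,0, 1,0,1, 0,1,0), 3, 3)
adjK4minus <- local({ a <- 1 - diag(4); a[1, 2] <- a[2, 1] <- 0; a })
adjStar4 <- local({ a <- matrix(0, 4, 4); a[1, 2:4] <- a[2:4, 1] <- 1; a })

# distinct-valued symmetric Z matrix on n nodes (off-diagonal 0.1, 0.2, ...)
distinctZ <- function(n) {
  z <- matrix(0, n, n)
  z[upper.tri(z)] <- seq_len(n * (n - 1) / 2) / 10
  ZMatrix(z + t(z))
}

# a small, fast synthetic cohort for unit tests
tinyCohort <- function(seed = 7, duration = 120)
  generateCohort(cohortConfig(n_healthy = 2, n_mild = 2, n_mts = 2,
                              duration = duration, seed = seed))
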