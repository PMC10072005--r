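# Accept a BinaryNetwork or a plain 0/1 matrix (handy for oracles).
.adj <- function(net) {
  if (is(net, "BinaryNetwork")) return(adjacency(net))
  a <- as.matrix(net)
  storage.mode(a) <- "integer"
  a
}

#' Network clustering coefficient
#'
#' Mean over nodes of the node clustering coefficient
#' \eqn{C_i = 2 e_i / (K_i (K_i - 1))}, where \eqn{e_i} counts edges among
#' node i's neighbors and \eqn{K_i} is the degree; \eqn{C_i := 0} for
#' nodes of degree < 2.
#'
#' @param net a \linkS4class{BinaryNetwork} (or 0/1 adjacency matrix).
#' @param nodewise also return the per-node table.
#' @return The scalar C, or (with \code{nodewise = TRUE}) a list with
#'   \code{C} and a data.frame of K, e and Ci per node.
#' @examples
#' clusteringCoef(BinaryNetwork(1 - diag(3))) # triangle: 1
#' @export
clusteringCoef <- function(net, nodewise = FALSE) {
  a <- .adj(net)
  k <- rowSums(a)
  e <- diag(a %*% a %*% a) / 2
  ci <- ifelse(k < 2, 0, 2 * e / (k * (k - 1)))
  C <- mean(ci)
  if (!nodewise) return(C)
  list(C = C, nodes = data.frame(K = k, e = e, Ci = ci))
}

#' All-pairs shortest path lengths
#'
#' Breadth-first-search distances in edge counts; unreachable pairs are
#' \code{Inf}, the diagonal 0.
#'
#' @param net a \linkS4class{BinaryNetwork} (or 0/1 adjacency matrix).
#' @return Numeric distance matrix.
#' @export
shortestPaths <- function(net) {
  a <- .adj(net)
  d <- bfs_all_pairs(a)
  dimnames(d) <- dimnames(a)
  d
}

#' Characteristic path length
#'
#' Mean shortest path length over ordered reachable pairs (i != j).
#' On fragmented graphs unreachable pairs are excluded from the average
#' and the reachable fraction is reported in the
#' \code{"reachableFraction"} attribute, keeping L finite across a
#' threshold sweep.
#'
#' @param dist distance matrix from \code{\link{shortestPaths}} (or a
#'   \linkS4class{BinaryNetwork}, for which distances are computed).
#' @return L with attribute \code{reachableFraction}; \code{NA} (with a
#'   warning) when no pair is reachable.
#' @export
charPathLength <- function(dist) {
  if (is(dist, "BinaryNetwork")) dist <- shortestPaths(dist)
  m <- nrow(dist)
  off <- dist[row(dist) != col(dist)]
  reach <- is.finite(off)
  frac <- mean(reach)
  if (!any(reach)) {
    warning("no reachable pair: L undefined")
    L <- NA_real_
  } else {
    L <- mean(off[reach])
  }
  attr(L, "reachableFraction") <- frac
  L
}

#' Global efficiency
#'
#' \eqn{GE = \frac{1}{m(m-1)} \sum_{i \ne j} 1 / d_{ij}} with
#' \eqn{1/\infty := 0}, so fragmentation lowers GE instead of breaking it.
#'
#' @param dist distance matrix from \code{\link{shortestPaths}} (or a
#'   \linkS4class{BinaryNetwork}).
#' @return GE in [0, 1]; 1 exactly for the complete graph.
#' @export
globalEfficiency <- function(dist) {
  if (is(dist, "BinaryNetwork")) dist <- shortestPaths(dist)
  m <- nrow(dist)
  if (m < 2) return(0)
  off <- dist[row(dist) != col(dist)]
  sum(1 / off[is.finite(off) & off > 0]) / (m * (m - 1))
}

#' Local efficiency
#'
#' Mean over nodes of the global efficiency of the subgraph induced by
#' each node's neighbors (0 for nodes with fewer than 2 neighbors).
#'
#' @param net a \linkS4class{BinaryNetwork} (or 0/1 adjacency matrix).
#' @return LE in [0, 1].
#' @export
localEfficiency <- function(net) {
  a <- .adj(net)
  m <- nrow(a)
  eloc <- vapply(seq_len(m), function(i) {
    nb <- which(a[i, ] == 1L)
    if (length(nb) < 2) return(0)
    sub <- a[nb, nb, drop = FALSE]
    globalEfficiency(bfs_all_pairs(sub))
  }, numeric(1))
  mean(eloc)
}

#' Transitivity
#'
#' Ratio of closed triples (3 x triangles) to connected triples
#' \eqn{\sum_i K_i (K_i - 1) / 2}; 0 when the network has no triples.
#'
#' @param net a \linkS4class{BinaryNetwork} (or 0/1 adjacency matrix).
#' @return T in [0, 1].
#' @export
transitivityCoef <- function(net) {
  a <- .adj(net)
  k <- rowSums(a)
  triples <- sum(k * (k - 1) / 2)
  if (triples == 0) return(0)
  triangles <- sum(diag(a %*% a %*% a)) / 6
  3 * triangles / triples
}

#' All five base small-world metrics of one binary network
#'
#' @param net a \linkS4class{BinaryNetwork} (or 0/1 adjacency matrix).
#' @return Named numeric vector C, L, GE, LE, T with attribute
#'   \code{reachableFraction}.
#' @export
smallWorldMetrics <- function(net) {
  a <- .adj(net)
  d <- bfs_all_pairs(a)
  L <- charPathLength(d)
  out <- c(C = clusteringCoef(a), L = as.numeric(L),
           GE = globalEfficiency(d), LE = localEfficiency(a),
           T = transitivityCoef(a))
  attr(out, "reachableFraction") <- attr(L, "reachableFraction")
  out
}

#' Degree-preserving random reference network
#'
#' Maslov-Sneppen randomization: repeated double-edge swaps (default 10
#' attempted swaps per edge) that preserve every node's degree exactly
#' while destroying topological structure. Proposals creating self-loops
#' or multi-edges are rejected.
#'
#' @param net a \linkS4class{BinaryNetwork} with at least 2 edges.
#' @param seed optional integer seed (deterministic output when given).
#' @param swapFactor attempted swaps per edge (default 10).
#' @return A rewired \linkS4class{BinaryNetwork} with identical degree
#'   sequence. If no swap could be performed the input is returned with a
#'   warning.
#' @export
randomReference <- function(net, seed = NULL, swapFactor = 10) {
  a <- .adj(net)
  pairs <- pairIndex(nrow(a))
  edges <- pairs[a[pairs] == 1L, , drop = FALSE]
  if (nrow(edges) < 2) {
    warning("fewer than 2 edges: returning the input unchanged")
    return(net)
  }
  res <- withSeed(seed, ms_rewire(edges, nrow(a), swapFactor * nrow(edges)))
  if (res$swaps == 0)
    warning("no valid swap found: returning the input unchanged")
  out <- matrix(0L, nrow(a), ncol(a), dimnames = dimnames(a))
  out[res$edges] <- 1L
  out[res$edges[, c(2, 1), drop = FALSE]] <- 1L
  thr <- if (is(net, "BinaryNetwork")) net@threshold else 0
  BinaryNetwork(out, threshold = thr)
}

# fast internal: C and L of a 0/1 adjacency (no S4, for the ensemble loop)
.fastCL <- function(a) {
  k <- rowSums(a)
  e <- diag(a %*% a %*% a) / 2
  C <- mean(ifelse(k < 2, 0, 2 * e / (k * (k - 1))))
  d <- bfs_all_pairs(a)
  off <- d[row(d) != col(d)]
  reach <- is.finite(off)
  L <- if (any(reach)) mean(off[reach]) else NA_real_
  c(C = C, L = L)
}

#' Normalized small-world ratios against a random ensemble
#'
#' Computes \eqn{\gamma = C / C_{rand}}, \eqn{\lambda = L / L_{rand}} and
#' the small-worldness \eqn{\delta = \gamma / \lambda}, where
#' \eqn{C_{rand}} and \eqn{L_{rand}} are means over \code{nRandom}
#' independent degree-matched Maslov-Sneppen references.
#'
#' @param net a \linkS4class{BinaryNetwork}.
#' @param nRandom ensemble size (default 100).
#' @param seed optional master seed; reference seeds are derived from it.
#' @param swapFactor attempted swaps per edge in each reference.
#' @return Named numeric vector gamma, lambda, delta, Crand, Lrand.
#'   Ratios are \code{NA} when the corresponding random mean is zero or
#'   undefined.
#' @export
normalizedSmallWorld <- function(net, nRandom = 100, seed = NULL,
                                 swapFactor = 10) {
  stopifnot2(nRandom >= 1, "nRandom must be at least 1")
  a <- .adj(net)
  base <- .fastCL(a)
  pairs <- pairIndex(nrow(a))
  edges <- pairs[a[pairs] == 1L, , drop = FALSE]
  m <- nrow(edges)
  cl <- matrix(NA_real_, nRandom, 2)
  for (r in seq_len(nRandom)) {
    res <- withSeed(if (is.null(seed)) NULL else deriveSeed(seed, 7, r),
                    ms_rewire(edges, nrow(a), swapFactor * m))
    ra <- matrix(0L, nrow(a), ncol(a))
    ra[res$edges] <- 1L
    ra[res$edges[, c(2, 1), drop = FALSE]] <- 1L
    cl[r, ] <- .fastCL(ra)
  }
  crand <- mean(cl[, 1], na.rm = TRUE)
  lrand <- mean(cl[, 2], na.rm = TRUE)
  gamma <- if (is.finite(crand) && crand > 0) base[["C"]] / crand else NA_real_
  lambda <- if (is.finite(lrand) && lrand > 0 && is.finite(base[["L"]]))
    base[["L"]] / lrand else NA_real_
  delta <- if (is.finite(gamma) && is.finite(lambda)) gamma / lambda
           else NA_real_
  c(gamma = gamma, lambda = lambda, delta = delta,
    Crand = crand, Lrand = lrand)
}

#' Trapezoidal area under a metric-versus-threshold curve
#'
#' @param values metric values on the grid.
#' @param grid strictly increasing threshold grid of the same length
#'   (>= 2).
#' @return The trapezoidal integral.
#' @examples
#' metricAUC(c(1, 3), c(0.3, 0.4)) # 0.2
#' @export
metricAUC <- function(values, grid) {
  if (length(values) != length(grid))
    stop("values and grid must have equal length", call. = FALSE)
  stopifnot2(length(grid) >= 2, "need at least 2 grid points")
  stopifnot2(all(diff(grid) > 0), "grid must be strictly increasing")
  n <- length(grid)
  sum(diff(grid) * (values[-1] + values[-n]) / 2)
}

#' Metric curves and AUC features for one subject's threshold sweep
#'
#' Evaluates all eight small-world metrics (C, L, GE, LE, T, gamma,
#' lambda, delta) on every network of a proportional-threshold sweep and
#' integrates each curve into its threshold-AUC scalar -- the subject's
#' feature vector.
#'
#' @param networks list of \linkS4class{BinaryNetwork} from
#'   \code{\link{thresholdSweep}}.
#' @param nRandom random-reference ensemble size per network
#'   (default 100).
#' @param seed optional master seed for the reference ensembles.
#' @param subjectId subject identifier stored in the profile.
#' @param swapFactor attempted swaps per edge for the references.
#' @return A \linkS4class{MetricProfile}.
#' @export
subjectProfile <- function(networks, nRandom = 100, seed = NULL,
                           subjectId = "subject", swapFactor = 10) {
  stopifnot2(length(networks) >= 2, "need a sweep of at least 2 networks")
  thresholds <- vapply(networks, function(n) n@threshold, numeric(1))
  stopifnot2(all(diff(thresholds) > 0),
             "networks must come from an increasing threshold sweep")
  curves <- matrix(NA_real_, length(networks), 8,
                   dimnames = list(format(thresholds),
                                   c("C", "L", "GE", "LE", "T",
                                     "gamma", "lambda", "delta")))
  for (i in seq_along(networks)) {
    base <- smallWorldMetrics(networks[[i]])
    norm <- normalizedSmallWorld(networks[[i]], nRandom = nRandom,
                                 seed = if (is.null(seed)) NULL
                                        else deriveSeed(seed, 11, i),
                                 swapFactor = swapFactor)
    curves[i, ] <- c(base[c("C", "L", "GE", "LE", "T")],
                     norm[c("gamma", "lambda", "delta")])
  }
  auc <- apply(curves, 2, metricAUC, grid = thresholds)
  names(auc) <- paste0(colnames(curves), "_AUC")
  new("MetricProfile", subjectId = as.character(subjectId),
      thresholds = thresholds, curves = curves, auc = auc)
}
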