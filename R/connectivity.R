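#' Between-channel Pearson correlation matrix
#'
#' @param recording a \linkS4class{HemodynamicRecording} with at least 3
#'   samples.
#' @return Symmetric correlation matrix with unit diagonal. Constant
#'   channels get zero correlations (with a warning) rather than NA.
#' @export
correlationMatrix <- function(recording) {
  x <- t(sigData(recording)) # samples x channels
  stopifnot2(nrow(x) >= 3, "need at least 3 samples")
  sds <- apply(x, 2, sd)
  bad <- which(sds == 0)
  r <- suppressWarnings(cor(x))
  if (length(bad)) {
    warning("constant channel(s) ", paste(bad, collapse = ", "),
            ": correlations set to 0")
    r[bad, ] <- 0
    r[, bad] <- 0
  }
  diag(r) <- 1
  r
}

#' Fisher Z transformation
#'
#' \code{z = atanh(r)}, with \code{r} first clipped to
#' \code{1 - 1e-7} in magnitude so the result stays finite.
#'
#' @param r correlation value(s) in [-1, 1].
#' @return Fisher-Z value(s) of the same shape.
#' @examples
#' fisherZ(0.5) # 0.549306
#' @export
fisherZ <- function(r) {
  if (any(abs(r) > 1, na.rm = TRUE))
    stop("correlations must lie in [-1, 1]", call. = FALSE)
  atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7))
}

#' Fisher-Z connectivity matrix of a recording
#'
#' Convenience composition of \code{\link{correlationMatrix}} and
#' \code{\link{fisherZ}} with the diagonal set to zero.
#'
#' @param recording a \linkS4class{HemodynamicRecording}.
#' @return A \linkS4class{ZMatrix}.
#' @export
connectivityMatrix <- function(recording) {
  z <- fisherZ(correlationMatrix(recording))
  diag(z) <- 0
  ZMatrix(z, labels = channelNames(recording))
}

#' Binarize a connectivity matrix by proportional thresholding
#'
#' The \code{round((1 - threshold) * n * (n - 1) / 2)} node pairs with the
#' largest absolute Z values receive an edge; all other pairs none. Ties
#' at the cut are broken deterministically by ascending (row, column)
#' index, which makes threshold sweeps reproducible and nested.
#'
#' @param zmat a \linkS4class{ZMatrix}.
#' @param threshold fraction in [0, 1) of weakest pairs to discard.
#' @return A \linkS4class{BinaryNetwork}.
#' @examples
#' z <- matrix(0, 5, 5); z[upper.tri(z)] <- seq(0.1, 1, 0.1)
#' net <- proportionalThreshold(ZMatrix(z + t(z)), 0.4)
#' edgeCount(net) # 6 of 10 pairs retained
#' @export
proportionalThreshold <- function(zmat, threshold) {
  stopifnot2(is(zmat, "ZMatrix"), "zmat must be a ZMatrix")
  stopifnot2(threshold >= 0 && threshold < 1, "threshold must be in [0, 1)")
  z <- zValues(zmat)
  n <- nrow(z)
  pairs <- pairIndex(n)
  absz <- abs(z[pairs])
  keep <- round((1 - threshold) * nrow(pairs))
  adj <- matrix(0L, n, n, dimnames = dimnames(z))
  if (keep > 0) {
    ord <- order(-absz, pairs[, 1], pairs[, 2])
    sel <- pairs[ord[seq_len(keep)], , drop = FALSE]
    adj[sel] <- 1L
    adj[sel[, c(2, 1), drop = FALSE]] <- 1L
  }
  BinaryNetwork(adj, threshold = threshold)
}

#' Binarize over a grid of proportional thresholds
#'
#' @param zmat a \linkS4class{ZMatrix}.
#' @param lo,hi,step threshold grid (defaults 0.3 to 0.7 by 0.01, i.e. 41
#'   networks, both endpoints included).
#' @return Named list of \linkS4class{BinaryNetwork}, one per grid point;
#'   edge sets are nested along the grid.
#' @export
thresholdSweep <- function(zmat, lo = 0.3, hi = 0.7, step = 0.01) {
  stopifnot2(lo <= hi && step > 0, "need lo <= hi and step > 0")
  grid <- round(seq(lo, hi, by = step), 10)
  nets <- lapply(grid, function(t) proportionalThreshold(zmat, t))
  names(nets) <- format(grid)
  nets
}
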