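#' @import methods
#' @importFrom stats cor mad median sd rnorm runif rbinom rpois lm anova
#'   update resid pt p.adjust predict coef smooth.spline quantile setNames
#'   complete.cases
#' @importFrom utils read.csv write.csv head tail
#' @useDynLib motornet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' One subject's multichannel hemodynamic recording
#'
#' Holds a channels x samples matrix of hemoglobin concentration changes
#' (conventionally \eqn{\Delta}[HbO2] or \eqn{\Delta}[Hb], in mM·mm)
#' together with the sampling rate. Channel labels live in the matrix
#' rownames (\code{Ch1}, \code{Ch2}, ...).
#'
#' @slot subjectId character scalar identifier.
#' @slot data numeric matrix, channels in rows, samples in columns; no
#'   missing values allowed.
#' @slot fs sampling rate in Hz, > 0.
#' @slot chromophore label, typically \code{"HbO2"} or \code{"Hb"}.
#'
#' @exportClass HemodynamicRecording
setClass("HemodynamicRecording",
  representation(
    subjectId = "character",
    data = "matrix",
    fs = "numeric",
    chromophore = "character"
  )
)

setValidity("HemodynamicRecording", function(object) {
  msg <- character(0)
  if (length(object@subjectId) != 1L)
    msg <- c(msg, "subjectId must be a single string")
  if (!is.numeric(object@data))
    msg <- c(msg, "data must be a numeric matrix")
  else if (anyNA(object@data) || any(!is.finite(object@data)))
    msg <- c(msg, "data must contain only finite values")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (length(object@chromophore) != 1L)
    msg <- c(msg, "chromophore must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct a HemodynamicRecording
#'
#' @param data channels x samples numeric matrix.
#' @param fs sampling rate in Hz.
#' @param subjectId subject identifier.
#' @param chromophore chromophore label (\code{"HbO2"} or \code{"Hb"}).
#' @return A \linkS4class{HemodynamicRecording}.
#' @examples
#' rec <- HemodynamicRecording(matrix(rnorm(40), 4, 10), fs = 10)
#' nChannels(rec)
#' @export
HemodynamicRecording <- function(data, fs, subjectId = "subject",
                                 chromophore = "HbO2") {
  data <- as.matrix(data)
  if (is.null(rownames(data)))
    rownames(data) <- paste0("Ch", seq_len(nrow(data)))
  new("HemodynamicRecording", subjectId = as.character(subjectId),
      data = data, fs = as.numeric(fs),
      chromophore = as.character(chromophore))
}

#' Per-sample motion-artifact mask
#'
#' @slot mask logical channels x samples matrix, TRUE inside an artifact.
#' @slot segments data.frame with columns channel, start, end (1-based
#'   inclusive sample indices).
#' @exportClass ArtifactMask
setClass("ArtifactMask",
  representation(mask = "matrix", segments = "data.frame")
)

setValidity("ArtifactMask", function(object) {
  msg <- character(0)
  if (!is.logical(object@mask))
    msg <- c(msg, "mask must be a logical matrix")
  seg <- object@segments
  need <- c("channel", "start", "end")
  if (!all(need %in% names(seg)))
    msg <- c(msg, "segments needs columns channel, start, end")
  else if (nrow(seg)) {
    if (any(seg$start < 1L) || any(seg$end > ncol(object@mask)) ||
        any(seg$start > seg$end) ||
        any(seg$channel < 1L) || any(seg$channel > nrow(object@mask)))
      msg <- c(msg, "segments out of recording bounds")
  }
  if (length(msg)) msg else TRUE
})

#' Fisher-Z functional connectivity matrix
#'
#' Symmetric matrix of Fisher-Z transformed Pearson correlations between
#' channels, with the diagonal fixed at zero.
#'
#' @slot z numeric symmetric matrix, zero diagonal, finite entries.
#' @slot labels channel labels.
#' @exportClass ZMatrix
setClass("ZMatrix", representation(z = "matrix", labels = "character"))

setValidity("ZMatrix", function(object) {
  z <- object@z
  msg <- character(0)
  if (nrow(z) != ncol(z)) msg <- c(msg, "z must be square")
  if (any(!is.finite(z))) msg <- c(msg, "z must be finite")
  else {
    if (max(abs(z - t(z))) > 1e-8) msg <- c(msg, "z must be symmetric")
    if (any(diag(z) != 0)) msg <- c(msg, "diagonal must be exactly zero")
  }
  if (length(object@labels) != nrow(z))
    msg <- c(msg, "labels length must match matrix dimension")
  if (length(msg)) msg else TRUE
})

#' Construct a ZMatrix
#' @param z symmetric numeric matrix of Fisher-Z values (diagonal is forced
#'   to zero).
#' @param labels optional channel labels.
#' @return A \linkS4class{ZMatrix}.
#' @export
ZMatrix <- function(z, labels = NULL) {
  z <- as.matrix(z)
  diag(z) <- 0
  if (is.null(labels))
    labels <- if (!is.null(rownames(z))) rownames(z)
              else paste0("Ch", seq_len(nrow(z)))
  dimnames(z) <- list(labels, labels)
  new("ZMatrix", z = z, labels = labels)
}

#' Binarized connectivity network at one proportional threshold
#'
#' @slot adjacency integer 0/1 symmetric matrix with zero diagonal.
#' @slot threshold proportional threshold the network was binarized at
#'   (fraction of weakest pairs removed).
#' @exportClass BinaryNetwork
setClass("BinaryNetwork",
  representation(adjacency = "matrix", threshold = "numeric")
)

setValidity("BinaryNetwork", function(object) {
  a <- object@adjacency
  msg <- character(0)
  if (nrow(a) != ncol(a)) msg <- c(msg, "adjacency must be square")
  if (!all(a %in% c(0L, 1L))) msg <- c(msg, "adjacency must be 0/1")
  else {
    if (any(a != t(a))) msg <- c(msg, "adjacency must be symmetric")
    if (any(diag(a) != 0)) msg <- c(msg, "diagonal must be zero")
  }
  if (length(object@threshold) != 1L || object@threshold < 0 ||
      object@threshold >= 1)
    msg <- c(msg, "threshold must be a single value in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Construct a BinaryNetwork
#' @param adjacency 0/1 symmetric matrix, zero diagonal.
#' @param threshold proportional threshold in [0, 1).
#' @return A \linkS4class{BinaryNetwork}.
#' @export
BinaryNetwork <- function(adjacency, threshold = 0) {
  a <- as.matrix(adjacency)
  storage.mode(a) <- "integer"
  new("BinaryNetwork", adjacency = a, threshold = as.numeric(threshold))
}

#' Small-world metric curves and threshold-AUC features for one subject
#'
#' @slot subjectId subject identifier.
#' @slot thresholds the proportional-threshold grid.
#' @slot curves matrix, length(thresholds) x 8, columns C, L, GE, LE, T,
#'   gamma, lambda, delta.
#' @slot auc named numeric vector of trapezoidal areas under each curve.
#' @exportClass MetricProfile
setClass("MetricProfile",
  representation(
    subjectId = "character",
    thresholds = "numeric",
    curves = "matrix",
    auc = "numeric"
  )
)

setValidity("MetricProfile", function(object) {
  msg <- character(0)
  if (nrow(object@curves) != length(object@thresholds))
    msg <- c(msg, "curves must have one row per threshold")
  if (length(object@auc) != ncol(object@curves))
    msg <- c(msg, "one AUC per metric column required")
  if (anyNA(object@auc) || any(!is.finite(object@auc)))
    msg <- c(msg, "AUC values must be finite")
  if (length(msg)) msg else TRUE
})

#' A synthetic or loaded cohort of recordings with metadata
#'
#' @slot recordings list of \linkS4class{HemodynamicRecording}.
#' @slot meta data.frame of per-subject metadata (subject_id, group, age,
#'   gender, FMA, ...).
#' @slot truth list of per-subject ground-truth descriptions (latent
#'   adjacency, rewiring probability, FMA) for synthetic cohorts; empty
#'   list otherwise.
#' @exportClass NirsCohort
setClass("NirsCohort",
  representation(recordings = "list", meta = "data.frame", truth = "list")
)

setValidity("NirsCohort", function(object) {
  msg <- character(0)
  if (nrow(object@meta) != length(object@recordings))
    msg <- c(msg, "meta must have one row per recording")
  if (!all(c("subject_id", "group") %in% names(object@meta)))
    msg <- c(msg, "meta needs subject_id and group columns")
  ok <- vapply(object@recordings, is, logical(1), "HemodynamicRecording")
  if (!all(ok)) msg <- c(msg, "recordings must be HemodynamicRecording objects")
  if (length(object@truth) &&
      length(object@truth) != length(object@recordings))
    msg <- c(msg, "truth, when present, must match recordings in length")
  if (length(msg)) msg else TRUE
})

#' Pooled nested cross-validation classification result
#'
#' @slot confusion pooled confusion matrix, rows = true class, columns =
#'   predicted class.
#' @slot accuracy overall accuracy (trace / total).
#' @slot perClass data.frame of per-class sensitivity, specificity and
#'   ROC area (one-versus-rest).
#' @slot roc named list of per-class ROC curves (each a list with points
#'   and auc).
#' @slot folds per-outer-fold log: chosen hyperparameter, retained
#'   features, scaler.
#' @slot ranking full-data RFE feature ranking with normalized importance
#'   weights.
#' @slot decisionValues pooled n x K matrix of one-versus-rest decision
#'   values for the held-out subjects.
#' @exportClass ClassificationResult
setClass("ClassificationResult",
  representation(
    confusion = "matrix",
    accuracy = "numeric",
    perClass = "data.frame",
    roc = "list",
    folds = "list",
    ranking = "data.frame",
    decisionValues = "matrix"
  )
)
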