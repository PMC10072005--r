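#' @rdname HemodynamicRecording-class
#' @param object,x a \linkS4class{HemodynamicRecording}.
#' @export
setGeneric("sigData", function(x) standardGeneric("sigData"))

#' @rdname HemodynamicRecording-class
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname HemodynamicRecording-class
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname HemodynamicRecording-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname HemodynamicRecording-class
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname HemodynamicRecording-class
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname ZMatrix-class
#' @param x object.
#' @export
setGeneric("zValues", function(x) standardGeneric("zValues"))

#' @rdname BinaryNetwork-class
#' @param x object.
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' @rdname BinaryNetwork-class
#' @export
setGeneric("edgeCount", function(x) standardGeneric("edgeCount"))

#' @rdname BinaryNetwork-class
#' @export
setGeneric("nodeCount", function(x) standardGeneric("nodeCount"))

#' @rdname MetricProfile-class
#' @param x object.
#' @export
setGeneric("metricCurves", function(x) standardGeneric("metricCurves"))

#' @rdname MetricProfile-class
#' @export
setGeneric("metricAUCs", function(x) standardGeneric("metricAUCs"))

#' @rdname NirsCohort-class
#' @param x object.
#' @export
setGeneric("cohortMeta", function(x) standardGeneric("cohortMeta"))

#' @rdname NirsCohort-class
#' @export
setGeneric("cohortTruth", function(x) standardGeneric("cohortTruth"))

setMethod("sigData", "HemodynamicRecording", function(x) x@data)
setMethod("samplingRate", "HemodynamicRecording", function(x) x@fs)
setMethod("nChannels", "HemodynamicRecording", function(x) nrow(x@data))
setMethod("nSamples", "HemodynamicRecording", function(x) ncol(x@data))
setMethod("channelNames", "HemodynamicRecording", function(x) rownames(x@data))
setMethod("subjectId", "HemodynamicRecording", function(x) x@subjectId)

#' Recording duration in seconds
#' @param x a \linkS4class{HemodynamicRecording}.
#' @return duration in seconds.
#' @export
recordingDuration <- function(x) nSamples(x) / samplingRate(x)

setMethod("zValues", "ZMatrix", function(x) x@z)
setMethod("adjacency", "BinaryNetwork", function(x) x@adjacency)
setMethod("edgeCount", "BinaryNetwork", function(x) sum(x@adjacency) %/% 2L)
setMethod("nodeCount", "BinaryNetwork", function(x) nrow(x@adjacency))
setMethod("metricCurves", "MetricProfile", function(x) x@curves)
setMethod("metricAUCs", "MetricProfile", function(x) x@auc)
setMethod("cohortMeta", "NirsCohort", function(x) x@meta)
setMethod("cohortTruth", "NirsCohort", function(x) x@truth)

#' @describeIn NirsCohort-class number of subjects
#' @export
setMethod("length", "NirsCohort", function(x) length(x@recordings))

#' @describeIn NirsCohort-class extract one subject's recording
#' @param i subject index.
#' @export
setMethod("[[", "NirsCohort", function(x, i) x@recordings[[i]])

setMethod("show", "HemodynamicRecording", function(object) {
  cat(sprintf(
    "HemodynamicRecording '%s' (%s): %d channels x %d samples @ %g Hz (%.1f s)\n",
    object@subjectId, object@chromophore, nrow(object@data),
    ncol(object@data), object@fs, ncol(object@data) / object@fs))
})

setMethod("show", "ZMatrix", function(object) {
  z <- object@z[upper.tri(object@z)]
  cat(sprintf("ZMatrix: %d channels; |z| range %.3f-%.3f\n",
              nrow(object@z), min(abs(z)), max(abs(z))))
})

setMethod("show", "BinaryNetwork", function(object) {
  cat(sprintf("BinaryNetwork: %d nodes, %d edges (threshold %.2f)\n",
              nrow(object@adjacency), sum(object@adjacency) %/% 2L,
              object@threshold))
})

setMethod("show", "MetricProfile", function(object) {
  cat(sprintf("MetricProfile '%s': %d thresholds (%.2f-%.2f)\n",
              object@subjectId, length(object@thresholds),
              min(object@thresholds), max(object@thresholds)))
  print(round(object@auc, 4))
})

setMethod("show", "NirsCohort", function(object) {
  tab <- table(object@meta$group)
  cat(sprintf("NirsCohort: %d subjects (%s)\n", length(object@recordings),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
})

setMethod("show", "ClassificationResult", function(object) {
  cat(sprintf("ClassificationResult: accuracy %.1f%% (n = %d)\n",
              100 * object@accuracy, sum(object@confusion)))
  print(object@confusion)
})
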