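#' @name cohort-accessors
#' @title Accessors for BoldCohort and ConnectivityMatrix objects
#' @description Standard accessors: number of subjects/ROIs/volumes, subject
#'   identifiers, diagnosis labels, ROI labels, the list of per-subject
#'   signal matrices, the matrix of association values and the metric tag.
#' @param x a [BoldCohort-class] or [ConnectivityMatrix-class] object.
#' @return The corresponding component.
#' @examples
#' ch <- generateCohort(cohortSpec(nPerGroup = 2, numRoi = 4, numVolume = 20))
#' nSubjects(ch); nRoi(ch); nVolumes(ch)
#' head(subjectIds(ch)); table(labels(ch))
NULL

#' @rdname cohort-accessors
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))
#' @rdname cohort-accessors
#' @export
setGeneric("nRoi", function(x) standardGeneric("nRoi"))
#' @rdname cohort-accessors
#' @export
setGeneric("nVolumes", function(x) standardGeneric("nVolumes"))
#' @rdname cohort-accessors
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))
#' @rdname cohort-accessors
#' @export
setGeneric("labels", function(object, ...) standardGeneric("labels"))
#' @rdname cohort-accessors
#' @export
setGeneric("roiLabels", function(x) standardGeneric("roiLabels"))
#' @rdname cohort-accessors
#' @export
setGeneric("signals", function(x) standardGeneric("signals"))
#' @rdname cohort-accessors
#' @export
setGeneric("connectivityValues", function(x) standardGeneric("connectivityValues"))
#' @rdname cohort-accessors
#' @export
setGeneric("metricName", function(x) standardGeneric("metricName"))

#' @rdname cohort-accessors
setMethod("nSubjects", "BoldCohort", function(x) length(x@signals))
#' @rdname cohort-accessors
setMethod("nRoi", "BoldCohort", function(x) nrow(x@signals[[1L]]))
#' @rdname cohort-accessors
setMethod("nVolumes", "BoldCohort", function(x) ncol(x@signals[[1L]]))
#' @rdname cohort-accessors
setMethod("subjectIds", "BoldCohort", function(x) x@subjectIds)
#' @rdname cohort-accessors
setMethod("labels", "BoldCohort", function(object, ...) object@labels)
#' @rdname cohort-accessors
setMethod("roiLabels", "BoldCohort", function(x) x@roiLabels)
#' @rdname cohort-accessors
setMethod("signals", "BoldCohort", function(x) x@signals)

#' @rdname cohort-accessors
setMethod("nRoi", "ConnectivityMatrix", function(x) nrow(x@values))
#' @rdname cohort-accessors
setMethod("roiLabels", "ConnectivityMatrix", function(x) x@roiLabels)
#' @rdname cohort-accessors
setMethod("connectivityValues", "ConnectivityMatrix", function(x) x@values)
#' @rdname cohort-accessors
setMethod("metricName", "ConnectivityMatrix", function(x) x@metric)

#' @name evaluation-accessors
#' @title Accessors for EvaluationResult objects
#' @param x an [EvaluationResult-class] object.
#' @return The corresponding component: performance metrics (named numeric
#'   with Acc, Sn, Sp), confusion counts (TP, FN, TN, FP), per-subject
#'   predictions, fused decision scores, or per-fold selected feature sets.
NULL

#' @rdname evaluation-accessors
#' @export
setGeneric("performance", function(x) standardGeneric("performance"))
#' @rdname evaluation-accessors
#' @export
setGeneric("confusionCounts", function(x) standardGeneric("confusionCounts"))
#' @rdname evaluation-accessors
#' @export
setGeneric("predictions", function(x) standardGeneric("predictions"))
#' @rdname evaluation-accessors
#' @export
setGeneric("decisionScores", function(x) standardGeneric("decisionScores"))
#' @rdname evaluation-accessors
#' @export
setGeneric("perFoldSelected", function(x) standardGeneric("perFoldSelected"))

#' @rdname evaluation-accessors
setMethod("performance", "EvaluationResult", function(x) x@metrics)
#' @rdname evaluation-accessors
setMethod("confusionCounts", "EvaluationResult", function(x) x@counts)
#' @rdname evaluation-accessors
setMethod("predictions", "EvaluationResult", function(x) x@predictions)
#' @rdname evaluation-accessors
setMethod("decisionScores", "EvaluationResult", function(x) x@scores)
#' @rdname evaluation-accessors
setMethod("perFoldSelected", "EvaluationResult", function(x) x@perFoldSelected)

setMethod("show", "BoldCohort", function(object) {
  cat(sprintf("BoldCohort: %d subjects (%d MCI / %d NC), %d ROIs x %d volumes\n",
              nSubjects(object),
              sum(object@labels == "MCI"), sum(object@labels == "NC"),
              nRoi(object), nVolumes(object)))
  if (length(object@groundTruth))
    cat(sprintf("  synthetic, %d planted edge(s), coupling '%s'\n",
                nrow(object@groundTruth$plantedEdges),
                object@groundTruth$spec$coupling))
  invisible(object)
})

setMethod("show", "ConnectivityMatrix", function(object) {
  cat(sprintf("ConnectivityMatrix (%s): %d x %d, range [%.3f, %.3f]\n",
              object@metric, nrow(object@values), ncol(object@values),
              min(object@values), max(object@values)))
  invisible(object)
})

setMethod("show", "EvaluationResult", function(object) {
  m <- object@metrics
  cat(sprintf("EvaluationResult: %d subjects | Acc %.4f, Sn %.4f, Sp %.4f\n",
              length(object@truth), m[["Acc"]], m[["Sn"]], m[["Sp"]]))
  cfg <- object@config
  if (!is.null(cfg$metrics))
    cat(sprintf("  metrics: %s | alpha: %s | filter: %s (p < %s)\n",
                paste(cfg$metrics, collapse = " & "),
                if (is.null(cfg$alpha)) "-" else format(cfg$alpha),
                if (is.null(cfg$filter)) "-" else cfg$filter,
                if (is.null(cfg$threshold)) "-" else format(cfg$threshold)))
  invisible(object)
})
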