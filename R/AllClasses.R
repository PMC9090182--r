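#' Supported pairwise association metrics
#'
#' Metric identifiers accepted throughout the package: `"PCC"` (Pearson),
#' `"SCC"` (Spearman), `"KCC"` (Kendall tau-b), `"CS"` (cosine similarity)
#' and `"MIC"` (maximal information coefficient).
#'
#' @return Character vector of the five metric names.
#' @export
#' @examples
#' connectivityMetrics()
connectivityMetrics <- function() c("PCC", "SCC", "KCC", "CS", "MIC")

#' BoldCohort: a labelled cohort of ROI x volume BOLD time series
#'
#' Container for a two-group rs-fMRI cohort at the stage the pipeline
#' consumes: one real-valued matrix per subject with `nRoi` rows (regions of
#' interest) and `nVolumes` columns (time points), a binary diagnosis label
#' per subject (`"MCI"` = positive class, `"NC"` = negative class), and
#' optional ground truth carried along by the synthetic generator.
#'
#' @slot signals list of numeric matrices, one per subject, all of identical
#'   dimension (nRoi x nVolumes), finite values only.
#' @slot subjectIds character vector of unique subject identifiers.
#' @slot labels factor with levels `c("NC", "MCI")`, one per subject.
#' @slot roiLabels character vector of unique ROI names (row names of every
#'   signal matrix).
#' @slot groundTruth list; for synthetic cohorts, the generator spec and the
#'   planted edge set (`plantedEdges`, a 2-column matrix of ROI index pairs).
#'   Empty for cohorts read from disk.
#'
#' @seealso [generateCohort()], [readCohort()], [cohortFeatures()]
#' @export
setClass("BoldCohort",
  representation(
    signals = "list",
    subjectIds = "character",
    labels = "factor",
    roiLabels = "character",
    groundTruth = "list"
  )
)

setValidity("BoldCohort", function(object) {
  msg <- character()
  n <- length(object@signals)
  if (n < 1L) msg <- c(msg, "cohort must contain at least one subject")
  if (length(object@subjectIds) != n)
    msg <- c(msg, "subjectIds length must match number of subjects")
  if (anyDuplicated(object@subjectIds))
    msg <- c(msg, "subjectIds must be unique")
  if (length(object@labels) != n)
    msg <- c(msg, "labels length must match number of subjects")
  if (!identical(levels(object@labels), c("NC", "MCI")))
    msg <- c(msg, "labels must be a factor with levels c(\"NC\", \"MCI\")")
  if (n >= 1L) {
    d <- dim(object@signals[[1L]])
    if (d[1L] < 2L) msg <- c(msg, "at least 2 ROIs are required")
    if (d[2L] < 3L) msg <- c(msg, "at least 3 volumes are required")
    for (i in seq_len(n)) {
      m <- object@signals[[i]]
      if (!is.matrix(m) || !is.numeric(m)) {
        msg <- c(msg, sprintf("signals[[%d]] is not a numeric matrix", i))
        next
      }
      if (!identical(dim(m), d))
        msg <- c(msg, sprintf("subject '%s' has dimensions %dx%d, expected %dx%d",
                              object@subjectIds[i], nrow(m), ncol(m), d[1L], d[2L]))
      if (!all(is.finite(m)))
        msg <- c(msg, sprintf("subject '%s' contains non-finite values",
                              object@subjectIds[i]))
    }
    if (length(object@roiLabels) != d[1L])
      msg <- c(msg, "roiLabels length must equal the number of ROIs")
    if (anyDuplicated(object@roiLabels))
      msg <- c(msg, "roiLabels must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' ConnectivityMatrix: one subject's BFCN correlation square
#'
#' A symmetric `nRoi x nRoi` matrix of pairwise association values between
#' ROI time series, tagged with the metric that produced it.  Entries lie in
#' `[-1, 1]` for PCC/SCC/KCC/CS and in `[0, 1]` for MIC; the diagonal is the
#' metric's self-association (1 on non-constant rows).
#'
#' @slot metric one of [connectivityMetrics()].
#' @slot values symmetric numeric matrix.
#' @slot roiLabels character vector naming rows/columns.
#'
#' @seealso [staticBFCN()], [dynamicBFCN()], [flattenConnectivity()]
#' @export
setClass("ConnectivityMatrix",
  representation(
    metric = "character",
    values = "matrix",
    roiLabels = "character"
  )
)

setValidity("ConnectivityMatrix", function(object) {
  msg <- character()
  v <- object@values
  if (length(object@metric) != 1L || !object@metric %in% connectivityMetrics())
    msg <- c(msg, "metric must be one of connectivityMetrics()")
  if (nrow(v) != ncol(v)) msg <- c(msg, "values must be square")
  if (!all(is.finite(v))) msg <- c(msg, "values must be finite")
  else {
    if (max(abs(v - t(v))) > 1e-8) msg <- c(msg, "values must be symmetric")
    rng <- range(v)
    if (length(object@metric) == 1L && object@metric == "MIC") {
      if (rng[1L] < -1e-8 || rng[2L] > 1 + 1e-8)
        msg <- c(msg, "MIC values must lie in [0, 1]")
    } else if (rng[1L] < -1 - 1e-8 || rng[2L] > 1 + 1e-8) {
      msg <- c(msg, "values must lie in [-1, 1]")
    }
  }
  if (length(object@roiLabels) != nrow(v))
    msg <- c(msg, "roiLabels length must equal matrix dimension")
  if (length(msg)) msg else TRUE
})

#' EvaluationResult: predictions and performance of one cross-validated model
#'
#' Holds everything one leave-one-out evaluation produced: the per-subject
#' held-out predictions and fused decision scores, the confusion counts, the
#' performance metrics (Acc, Sn, Sp), the per-fold selected feature index
#' sets (one list element per fold, itself a named list per metric), the
#' model configuration, and protocol diagnostics (e.g. the nested-CV leakage
#' audit log).
#'
#' @slot predictions integer vector (1 = MCI, 0 = NC), one per subject.
#' @slot truth integer vector of the same coding.
#' @slot scores numeric vector of fused decision scores.
#' @slot counts named integer vector with elements TP, FN, TN, FP.
#' @slot metrics named numeric vector with elements Acc, Sn, Sp.
#' @slot perFoldSelected list (one per fold) of named lists metric -> integer
#'   vector of selected feature indices.
#' @slot config list describing the model (metrics, alpha, window, filter).
#' @slot diagnostics list of protocol diagnostics.
#'
#' @seealso [loocv()], [nestedLoocv()], [alphaGrid()], [frequencyTable()]
#' @export
setClass("EvaluationResult",
  representation(
    predictions = "integer",
    truth = "integer",
    scores = "numeric",
    counts = "integer",
    metrics = "numeric",
    perFoldSelected = "list",
    config = "list",
    diagnostics = "list"
  )
)

setValidity("EvaluationResult", function(object) {
  msg <- character()
  n <- length(object@truth)
  if (length(object@predictions) != n)
    msg <- c(msg, "one prediction per subject is required")
  if (!identical(sort(names(object@counts)), sort(c("TP", "FN", "TN", "FP"))))
    msg <- c(msg, "counts must be named TP, FN, TN, FP")
  else {
    P <- sum(object@truth == 1L)
    N <- sum(object@truth == 0L)
    if (object@counts[["TP"]] + object@counts[["FN"]] != P)
      msg <- c(msg, "TP + FN must equal the number of positives")
    if (object@counts[["TN"]] + object@counts[["FP"]] != N)
      msg <- c(msg, "TN + FP must equal the number of negatives")
  }
  if (!all(c("Acc", "Sn", "Sp") %in% names(object@metrics)))
    msg <- c(msg, "metrics must contain Acc, Sn, Sp")
  if (length(msg)) msg else TRUE
})
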