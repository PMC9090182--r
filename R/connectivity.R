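#' Static BFCN: whole-series pairwise connectivity of one subject
#'
#' Computes the pairwise association `W[i, j] = metric(V_i, V_j)` between
#' every pair of ROI time series of one subject over the full scan, giving
#' the subject's BFCN correlation square.  Only the upper triangle is
#' computed and mirrored; the diagonal is the metric's self-association
#' (1 for all five metrics on non-constant rows).
#'
#' @param x a numeric matrix with ROIs as rows and volumes as columns, or a
#'   [BoldCohort-class] (then `subject` picks the subject).
#' @param metric one of [connectivityMetrics()].
#' @param params MIC search parameters, see [micParams()]; ignored for the
#'   other metrics.
#' @param subject subject index when `x` is a cohort.
#' @return A [ConnectivityMatrix-class].
#' @details An undefined pairwise value (constant ROI signal) is an error
#'   identifying the offending ROI pair, rather than a silent 0.
#' @seealso [dynamicBFCN()] for the sliding-window average.
#' @export
#' @examples
#' ts <- matrix(rnorm(4 * 30), nrow = 4)
#' staticBFCN(ts, "PCC")
staticBFCN <- function(x, metric = "PCC", params = NULL, subject = 1L) {
  if (is(x, "BoldCohort")) {
    labs <- roiLabels(x)
    x <- signals(x)[[subject]]
  } else {
    labs <- rownames(x)
  }
  if (!is.matrix(x) || !is.numeric(x))
    muscnetError("x must be a numeric ROI x volume matrix", "muscnet_input_error")
  r <- nrow(x)
  if (r < 2L || ncol(x) < 3L)
    muscnetError("at least 2 ROIs and 3 volumes are required", "muscnet_input_error")
  if (is.null(labs)) labs <- paste0("ROI", seq_len(r))
  metric <- match.arg(metric, connectivityMetrics())
  fn <- metricFunction(metric, params)
  w <- matrix(0, r, r, dimnames = list(labs, labs))
  diag(w) <- selfAssociation(x, metric)
  for (i in seq_len(r - 1L)) {
    for (j in (i + 1L):r) {
      v <- tryCatch(fn(x[i, ], x[j, ]), muscnet_undefined_metric = function(e) {
        muscnetError(
          sprintf("undefined %s value for ROI pair (%d, %d): %s",
                  metric, i, j, conditionMessage(e)),
          "muscnet_undefined_metric", roiPair = c(i, j))
      })
      w[i, j] <- v
      w[j, i] <- v
    }
  }
  new("ConnectivityMatrix", metric = metric, values = w, roiLabels = labs)
}

# diagonal entries: the metric's self-association, with constant rows surfaced
selfAssociation <- function(x, metric) {
  const <- apply(x, 1L, sd) == 0
  if (any(const)) {
    i <- which(const)[1L]
    muscnetError(
      sprintf("undefined %s value for ROI pair (%d, %d): constant signal",
              metric, i, i),
      "muscnet_undefined_metric", roiPair = c(i, i))
  }
  1
}

#' Write / read a ConnectivityMatrix as delimited text
#'
#' The square matrix is stored tab-separated with ROI labels as header row
#' and first column; the metric name goes to a JSON sidecar (`<path>.meta.json`).
#'
#' @param cm a [ConnectivityMatrix-class].
#' @param path output file.
#' @return `writeConnectivity` returns `path` invisibly; `readConnectivity`
#'   returns the reconstructed [ConnectivityMatrix-class].
#' @export
writeConnectivity <- function(cm, path) {
  stopifnot(is(cm, "ConnectivityMatrix"))
  df <- data.frame(ROI = cm@roiLabels, cm@values, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(metric = cm@metric),
                       paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeConnectivity
#' @export
readConnectivity <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".meta.json"))
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  labs <- as.character(df[[1L]])
  v <- as.matrix(df[, -1L, drop = FALSE])
  dimnames(v) <- list(labs, labs)
  new("ConnectivityMatrix", metric = meta$metric, values = v, roiLabels = labs)
}
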