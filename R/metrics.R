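## Pairwise association metrics between two BOLD signal vectors.
## PCC/SCC/KCC delegate to stats::cor (Kendall is tau-b under ties, verified
## against a pair-count oracle in the tests); CS and MIC are local.

muscnetError <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "muscnetError", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

checkPair <- function(x, y, minLen = 2L) {
  if (!is.numeric(x) || !is.numeric(y))
    muscnetError("x and y must be numeric vectors", "muscnet_input_error")
  if (length(x) != length(y))
    muscnetError(sprintf("length mismatch: %d vs %d", length(x), length(y)),
                 "muscnet_input_error")
  if (length(x) < minLen)
    muscnetError(sprintf("vectors must have length >= %d", minLen),
                 "muscnet_input_error")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    muscnetError("non-finite values in input", "muscnet_input_error")
  invisible(TRUE)
}

checkVariance <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0)
    muscnetError("zero-variance (constant) signal: correlation undefined",
                 "muscnet_undefined_metric")
  invisible(TRUE)
}

#' Pairwise association metrics between two signal vectors
#'
#' The five edge definitions used for BFCN construction:
#' `corPearson` (product-moment correlation), `corSpearman` (Pearson on
#' average ranks), `corKendall` (tau-b, tie-corrected), `corCosine`
#' (inner product over the product of Euclidean norms) and [mic()].
#' The first four return values in `[-1, 1]`; Pearson equals the cosine
#' similarity of the mean-centred vectors.
#'
#' @param x,y numeric vectors of equal length (>= 2), finite values.
#' @return A single numeric association value.
#' @details A constant (zero-variance) input makes the correlation
#'   undefined and raises an error of class `muscnet_undefined_metric`
#'   rather than silently returning 0; `corCosine` does the same for a
#'   zero-norm vector.
#' @export
#' @examples
#' corPearson(c(1, 2, 3, 4), c(1, 3, 2, 4))  # 0.8
#' corKendall(1:3, c(1, 3, 2))               # 1/3
corPearson <- function(x, y) {
  checkPair(x, y)
  checkVariance(x, y)
  cor(x, y, method = "pearson")
}

#' @rdname corPearson
#' @export
corSpearman <- function(x, y) {
  checkPair(x, y)
  checkVariance(x, y)
  cor(x, y, method = "spearman")
}

#' @rdname corPearson
#' @export
corKendall <- function(x, y) {
  checkPair(x, y)
  checkVariance(x, y)
  cor(x, y, method = "kendall")
}

#' @rdname corPearson
#' @export
corCosine <- function(x, y) {
  checkPair(x, y)
  nx <- sqrt(sum(x^2))
  ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0)
    muscnetError("zero-norm vector: cosine similarity undefined",
                 "muscnet_undefined_metric")
  sum(x * y) / (nx * ny)
}

#' Look up a metric function by name
#'
#' @param metric one of [connectivityMetrics()].
#' @param params parameters for the MIC search, see [micParams()].
#' @return A function of two numeric vectors.
#' @keywords internal
metricFunction <- function(metric, params = NULL) {
  metric <- match.arg(metric, connectivityMetrics())
  if (metric == "MIC") {
    p <- if (is.null(params)) micParams() else params
    return(function(x, y) mic(x, y, params = p))
  }
  switch(metric,
    PCC = corPearson,
    SCC = corSpearman,
    KCC = corKendall,
    CS  = corCosine
  )
}
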