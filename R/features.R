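#' Flatten a connectivity square into a feature vector
#'
#' Two layouts are supported.  `"upper_triangle"` (default) keeps each
#' undirected edge once, in row-major pair order (1,2), (1,3), ...,
#' (1,R), (2,3), ..., length `R * (R - 1) / 2`; it discards the constant
#' diagonal and the duplicated lower triangle, which carry no classifier
#' information and are degenerate under the filter tests.  `"full_square"`
#' is the literal row-major flatten of the whole square, length `R^2`.
#' Both mappings are inverted exactly by [indexToPair()].
#'
#' @param cm a [ConnectivityMatrix-class] or a plain symmetric matrix.
#' @param layout `"upper_triangle"` or `"full_square"`.
#' @return A numeric feature vector.
#' @export
#' @examples
#' m <- matrix(c(1, .2, .3, .2, 1, .4, .3, .4, 1), 3)
#' flattenConnectivity(m)                         # .2 .3 .4
#' flattenConnectivity(m, "full_square")[1:4]     # 1 .2 .3 .2
flattenConnectivity <- function(cm, layout = c("upper_triangle", "full_square")) {
  layout <- match.arg(layout)
  v <- if (is(cm, "ConnectivityMatrix")) cm@values else cm
  stopifnot(is.matrix(v), nrow(v) == ncol(v))
  if (layout == "full_square") {
    as.vector(t(v))                      # row-major
  } else {
    tv <- t(v)
    tv[lower.tri(tv)]                    # row-major upper-triangle pair order
  }
}

#' Rebuild a symmetric connectivity square from a flattened vector
#'
#' Exact inverse of [flattenConnectivity()]; for the `"upper_triangle"`
#' layout the diagonal is restored as `diagValue`.
#'
#' @param values flattened feature vector.
#' @param numRoi matrix dimension.
#' @inheritParams flattenConnectivity
#' @param diagValue diagonal entry for the upper-triangle layout.
#' @return A symmetric `numRoi x numRoi` matrix.
#' @export
unflattenConnectivity <- function(values, numRoi,
                                  layout = c("upper_triangle", "full_square"),
                                  diagValue = 1) {
  layout <- match.arg(layout)
  if (layout == "full_square") {
    stopifnot(length(values) == numRoi^2)
    return(t(matrix(values, numRoi, numRoi)))
  }
  stopifnot(length(values) == numRoi * (numRoi - 1) / 2)
  m <- diag(diagValue, numRoi)
  tm <- t(m)
  tm[lower.tri(tm)] <- values
  m <- t(tm)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

#' Per-subject connectivity feature matrix of a cohort
#'
#' Runs [dynamicBFCN()] (or [staticBFCN()] when `windowSize` is `NULL` or
#' equals the series length) for every subject under one metric and stacks
#' the flattened feature vectors into a subjects x features matrix.
#'
#' @param cohort a [BoldCohort-class].
#' @param metric one of [connectivityMetrics()].
#' @param windowSize,windowStep sliding-window parameters; `windowSize =
#'   NULL` uses the full series (static BFCN).
#' @inheritParams flattenConnectivity
#' @param params MIC search parameters, see [micParams()].
#' @return Numeric matrix, one row per subject (row names = subject ids),
#'   with attributes `metric`, `layout` and `numRoi`.
#' @export
cohortFeatures <- function(cohort, metric = "PCC",
                           windowSize = NULL, windowStep = 1L,
                           layout = c("upper_triangle", "full_square"),
                           params = NULL) {
  stopifnot(is(cohort, "BoldCohort"))
  layout <- match.arg(layout)
  if (is.null(windowSize)) {
    windowSize <- nVolumes(cohort)
    windowStep <- 1L
  }
  rows <- lapply(seq_len(nSubjects(cohort)), function(s) {
    cm <- dynamicBFCN(cohort, metric, windowSize, windowStep,
                      params = params, subject = s)
    flattenConnectivity(cm, layout)
  })
  X <- do.call(rbind, rows)
  rownames(X) <- subjectIds(cohort)
  attr(X, "metric") <- metric
  attr(X, "layout") <- layout
  attr(X, "numRoi") <- nRoi(cohort)
  X
}

labelsToBinary <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    bad <- setdiff(unique(y), c("MCI", "NC"))
    if (length(bad))
      muscnetError(sprintf("unknown label(s): %s", paste(bad, collapse = ", ")),
                   "muscnet_input_error")
    y <- ifelse(y == "MCI", 1L, 0L)
  }
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L)))
    muscnetError("labels must be MCI/NC or 1/0", "muscnet_input_error")
  y
}

# features with zero pooled variance (constant within both groups)
degenerateFeatures <- function(X, y) {
  y <- labelsToBinary(y)
  v1 <- apply(X[y == 1L, , drop = FALSE], 2L, var)
  v0 <- apply(X[y == 0L, , drop = FALSE], 2L, var)
  v1 == 0 & v0 == 0
}

#' Per-feature filter test p-values
#'
#' Univariate two-sided two-sample tests of each feature between the MCI
#' and NC groups: `ttestPvalues` (Student's t with pooled variance by
#' default, Welch optionally), `ranksumPvalues` (Wilcoxon rank-sum /
#' Mann-Whitney; exact null for small tie-free samples, tie-corrected
#' normal approximation otherwise) and `ksPvalues` (two-sample
#' Kolmogorov-Smirnov, asymptotic p-value on the maximal ECDF gap).
#' Features that are constant within both groups carry no information for
#' any of the tests; their p-value is set to 1 and they are flagged via the
#' `degenerate` attribute.
#'
#' @param X numeric subjects x features matrix.
#' @param y labels: `"MCI"`/`"NC"` or 1/0 (MCI = positive = 1).
#' @param welch logical; for `ttestPvalues`, use the Welch (unequal
#'   variance) statistic instead of the pooled-variance Student default.
#' @return Numeric vector of p-values in `[0, 1]`, one per feature, with a
#'   logical attribute `degenerate`.
#' @export
ttestPvalues <- function(X, y, welch = FALSE) {
  filterPvalues(X, y, function(a, b)
    t.test(a, b, var.equal = !welch)$p.value)
}

#' @rdname ttestPvalues
#' @export
ranksumPvalues <- function(X, y) {
  filterPvalues(X, y, function(a, b)
    suppressWarnings(wilcox.test(a, b)$p.value))
}

#' @rdname ttestPvalues
#' @export
ksPvalues <- function(X, y) {
  filterPvalues(X, y, function(a, b)
    suppressWarnings(ks.test(a, b, exact = FALSE)$p.value))
}

filterPvalues <- function(X, y, testFun) {
  y <- labelsToBinary(y)
  if (sum(y == 1L) < 2L || sum(y == 0L) < 2L)
    muscnetError("each class needs at least 2 samples", "muscnet_input_error")
  degen <- degenerateFeatures(X, y)
  a <- X[y == 1L, , drop = FALSE]
  b <- X[y == 0L, , drop = FALSE]
  p <- vapply(seq_len(ncol(X)), function(j) {
    if (degen[j]) return(1)
    out <- testFun(a[, j], b[, j])
    if (is.na(out)) 1 else out
  }, numeric(1L))
  attr(p, "degenerate") <- degen
  p
}

#' Filter-based feature selection
#'
#' Selects the features whose filter p-value is strictly smaller than the
#' threshold (matching a "p-values smaller than the threshold" rule);
#' degenerate features (zero pooled variance) are never selected.  The
#' selection is monotone in the threshold: a smaller threshold always
#' yields a subset.
#'
#' @inheritParams ttestPvalues
#' @param method `"Ttest"`, `"Wtest"` or `"KStest"`.
#' @param threshold p-value threshold in `(0, 1]`; the sweep used for
#'   tuning typically covers 0.01 through 0.2, with 0.05 the conventional
#'   default.
#' @param adjust `"none"` (default) thresholds the raw p-values, the
#'   classical filter rule; `"BH"` applies a Benjamini-Hochberg adjustment
#'   first.
#' @return A list of class `FilterResult`: `method`, `pvalues`,
#'   `threshold`, `selected` (integer indices) and `degenerate`.
#' @export
#' @examples
#' X <- matrix(rnorm(40 * 6), 40)
#' X[1:20, 1] <- X[1:20, 1] + 3   # planted group difference
#' y <- rep(c(1, 0), each = 20)
#' selectFeatures(X, y, "Ttest", 0.05)$selected
selectFeatures <- function(X, y, method = c("Ttest", "Wtest", "KStest"),
                           threshold = 0.05, adjust = c("none", "BH")) {
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  if (!(is.numeric(threshold) && length(threshold) == 1L &&
        threshold > 0 && threshold <= 1))
    muscnetError("threshold must lie in (0, 1]", "muscnet_input_error")
  p <- switch(method,
    Ttest = ttestPvalues(X, y),
    Wtest = ranksumPvalues(X, y),
    KStest = ksPvalues(X, y)
  )
  degen <- attr(p, "degenerate")
  if (adjust == "BH") p[] <- stats::p.adjust(p, method = "BH")
  structure(
    list(method = method,
         pvalues = as.numeric(p),
         threshold = threshold,
         selected = which(p < threshold & !degen),
         degenerate = degen),
    class = "FilterResult"
  )
}
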