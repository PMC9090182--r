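#' Parameters of the maximal information coefficient search
#'
#' @param alphaExponent exponent of the grid-resolution budget
#'   `B(n) = max(floor(n^alphaExponent), 4)`; default 0.6, the canonical
#'   choice.
#' @param clumpFactor positive integer multiplier bounding the number of
#'   candidate partitions examined on the optimized axis (at most
#'   `clumpFactor * maxBins` superclumps); default 15, the canonical choice.
#' @param exactMode logical; if `TRUE`, [mic()] enumerates every admissible
#'   grid exhaustively instead of running the approximate search.  Feasible
#'   only for small samples (n <= 50) and small budgets (B <= 16); intended
#'   as an oracle for validating the approximation.
#' @return A list of class `micParams`.
#' @export
#' @examples
#' micParams()
#' micParams(exactMode = TRUE)
micParams <- function(alphaExponent = 0.6, clumpFactor = 15L, exactMode = FALSE) {
  stopifnot(
    is.numeric(alphaExponent), length(alphaExponent) == 1L,
    alphaExponent > 0, alphaExponent <= 1,
    is.numeric(clumpFactor), length(clumpFactor) == 1L, clumpFactor >= 1,
    is.logical(exactMode), length(exactMode) == 1L
  )
  structure(
    list(alphaExponent = alphaExponent,
         clumpFactor = as.integer(clumpFactor),
         exactMode = exactMode),
    class = "micParams"
  )
}

#' Grid-resolution budget of the MIC search
#'
#' @param n sample size.
#' @param params a [micParams()] object.
#' @return `max(floor(n^alphaExponent), 4)`.
#' @export
micBudget <- function(n, params = micParams()) {
  max(floor(n^params$alphaExponent), 4L)
}

#' Maximal information coefficient
#'
#' The largest normalized mutual information achievable by binning the two
#' variables on a grid: over all grids with `rows * cols <= B(n)` (and at
#' least 2 bins per axis), the mutual information of the induced 2-D
#' histogram divided by `log2(min(rows, cols))`.  Captures linear and
#' nonlinear, including non-monotone, association; a noiseless functional
#' relationship saturates the statistic at 1.  The default search is the
#' equipartition-plus-dynamic-programming approximation (one axis
#' equipartitioned, the other optimized exactly over clump boundaries, both
#' orientations evaluated, element-wise maximum taken), which never exceeds
#' the exhaustive maximum; `exactMode` enumerates all admissible grids.
#'
#' @param x,y numeric vectors of equal length `n >= 8`, finite values.
#' @param params a [micParams()] object.
#' @return A value in `[0, 1]`, symmetric in `x` and `y`.  A constant input
#'   vector returns 0 with a warning (no grid carries information).
#' @export
#' @examples
#' x <- 0:99
#' mic(x, x)          # 1: identity
#' mic(x, (x - 50)^2) # ~1: noiseless non-monotone relationship
mic <- function(x, y, params = micParams()) {
  checkPair(x, y, minLen = 8L)
  if (!inherits(params, "micParams"))
    muscnetError("params must be created by micParams()", "muscnet_input_error")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant input vector: MIC is 0 by convention")
    return(0)
  }
  if (params$exactMode) {
    .micExactCpp(as.numeric(x), as.numeric(y), params$alphaExponent)
  } else {
    .micApproxCpp(as.numeric(x), as.numeric(y), params$alphaExponent,
                  params$clumpFactor)
  }
}

#' Normalized mutual information of one explicit grid
#'
#' Bins `x` and `y` by the given cut points, forms the 2-D histogram, and
#' returns its mutual information (bits) divided by
#' `log2(min(#x bins, #y bins))` -- the score the MIC search maximizes over
#' grids.  Bin counts are taken over the non-empty bins.
#'
#' @param x,y numeric vectors of equal length.
#' @param xEdges,yEdges strictly increasing interior cut points; values are
#'   assigned to bins by `findInterval`.
#' @return A list with `rowsX`, `colsY` (non-empty bin counts, each >= 2
#'   required) and `normalizedMi` in `[0, 1]`.
#' @seealso [miFromCounts()] for the same computation from a count table.
#' @export
#' @examples
#' x <- rep(c(0, 1), each = 5); y <- x
#' normalizedMiForGrid(x, y, xEdges = 0.5, yEdges = 0.5)$normalizedMi  # 1
normalizedMiForGrid <- function(x, y, xEdges, yEdges) {
  checkPair(x, y)
  bx <- findInterval(x, sort(xEdges)) + 1L
  by <- findInterval(y, sort(yEdges)) + 1L
  counts <- table(bx, by)
  counts <- counts[rowSums(counts) > 0, colSums(counts) > 0, drop = FALSE]
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    muscnetError("each axis must have at least 2 non-empty bins",
                 "muscnet_input_error")
  list(rowsX = nrow(counts), colsY = ncol(counts),
       normalizedMi = miFromCounts(unclass(counts)))
}

#' Normalized mutual information from a grid count table
#'
#' @param counts numeric matrix of cell counts (rows = x bins, cols = y
#'   bins), at least 2 x 2 after dropping empty marginals.
#' @return Mutual information in bits divided by `log2(min(dim(counts)))`.
#' @export
#' @examples
#' miFromCounts(rbind(c(5, 0), c(0, 5)))  # 1: perfect association
#' miFromCounts(rbind(c(3, 3), c(3, 3)))  # 0: independence
miFromCounts <- function(counts) {
  counts <- as.matrix(counts)
  counts <- counts[rowSums(counts) > 0, colSums(counts) > 0, drop = FALSE]
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    muscnetError("count table must be at least 2 x 2 with non-empty marginals",
                 "muscnet_input_error")
  n <- sum(counts)
  p <- counts / n
  px <- rowSums(p)
  py <- colSums(p)
  e <- outer(px, py)
  nz <- p > 0
  mi <- sum(p[nz] * log2(p[nz] / e[nz]))
  mi / log2(min(dim(counts)))
}
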