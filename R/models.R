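#' Train a linear-SVM base estimator
#'
#' Fits a linear-kernel support vector machine on the selected features and
#' returns it as an explicit linear decision rule: for a sample `x`,
#' `score = sum(weights * x[featureIndices]) + intercept`, with `score > 0`
#' meaning the positive (MCI) class.  Scores are raw (no scaling or
#' per-estimator normalization), so they can be fused linearly across
#' estimators.  The decision-value orientation of the underlying solver
#' depends on the order classes are first seen; it is normalized here so
#' positive always means MCI.
#'
#' @param X numeric subjects x features matrix (already subset to the
#'   selected features, or use `featureIndices`).
#' @param y labels, `"MCI"`/`"NC"` or 1/0.
#' @param regularization SVM cost parameter C (default 1).
#' @param featureIndices integer indices of `X`'s columns the estimator
#'   uses (default all); recorded in the estimator.
#' @param metric optional tag naming the source connectivity metric.
#' @param balancedWeights logical; weight the SVM classes inversely to
#'   their training-set sizes (default `TRUE`).  Leave-one-out folds of a
#'   balanced cohort are always one subject short in the held-out
#'   subject's own class; without reweighting, a model fit to
#'   uninformative features drifts toward the majority class of the fold,
#'   which is systematically the wrong one.
#' @return An object of class `LinearEstimator`: `weights`, `intercept`,
#'   `featureIndices`, `metric`, and `fallback` (`TRUE` when the selection
#'   was empty and a majority-class constant scorer was used instead).
#' @seealso [estimatorScores()], [fuseScores()], [loocv()]
#' @export
trainEstimator <- function(X, y, regularization = 1,
                           featureIndices = seq_len(ncol(X)),
                           metric = NA_character_, balancedWeights = TRUE) {
  y <- labelsToBinary(y)
  if (length(unique(y)) < 2L)
    muscnetError("both classes must be present for training",
                 "muscnet_input_error")
  featureIndices <- as.integer(featureIndices)
  if (length(featureIndices) == 0L) {
    # empty selection: majority-class constant scorer (ties score 0 -> NC)
    maj <- sum(y == 1L) - sum(y == 0L)
    return(structure(
      list(weights = numeric(0L), intercept = sign(maj),
           featureIndices = integer(0L), metric = metric, fallback = TRUE),
      class = "LinearEstimator"))
  }
  Xs <- X[, featureIndices, drop = FALSE]
  yf <- factor(y, levels = c(0L, 1L))
  cw <- NULL
  if (balancedWeights) {
    tab <- table(yf)
    cw <- stats::setNames(as.numeric(sum(tab) / (2 * tab)), names(tab))
  }
  fit <- e1071::svm(Xs, yf, kernel = "linear", cost = regularization,
                    scale = FALSE, class.weights = cw)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # decision values are positive for the class listed first in fit$labels
  if (levels(yf)[fit$labels[1L]] != "1") {
    w <- -w
    b <- -b
  }
  structure(
    list(weights = unname(w), intercept = unname(b),
         featureIndices = featureIndices, metric = metric, fallback = FALSE),
    class = "LinearEstimator")
}

#' Decision scores of a linear estimator
#'
#' @param est a `LinearEstimator` from [trainEstimator()].
#' @param X subjects x features matrix on the same full feature space the
#'   estimator's `featureIndices` refer to.
#' @return Numeric decision scores, positive = MCI.
#' @export
estimatorScores <- function(est, X) {
  stopifnot(inherits(est, "LinearEstimator"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (est$fallback) return(rep(est$intercept, nrow(X)))
  drop(X[, est$featureIndices, drop = FALSE] %*% est$weights) + est$intercept
}

#' Linear fusion of two decision scores
#'
#' The weighted-voting rule: `alpha * scoreA + (1 - alpha) * scoreB`.  A
#' fused score strictly above 0 predicts the positive (MCI) class; a tie
#' at exactly 0 predicts NC.
#'
#' @param scoreA,scoreB numeric decision scores.
#' @param alpha fusion weight in `[0, 1]`; sweeps use the grid 0.1, 0.2,
#'   ..., 0.9.
#' @return Fused numeric score(s).
#' @export
#' @examples
#' fuseScores(2, -1, 0.5)  #  0.5 -> MCI
#' fuseScores(2, -1, 0.1)  # -0.7 -> NC
fuseScores <- function(scoreA, scoreB, alpha) {
  if (!(is.numeric(alpha) && length(alpha) == 1L && alpha >= 0 && alpha <= 1))
    muscnetError("alpha must lie in [0, 1]", "muscnet_input_error")
  alpha * scoreA + (1 - alpha) * scoreB
}

#' Classification metrics from confusion counts
#'
#' `Acc = (TP + TN) / (P + N)`, `Sn = TP / P`, `Sp = TN / N`, with
#' `P = TP + FN` positives (MCI) and `N = TN + FP` negatives (NC).
#'
#' @param TP,FN,TN,FP non-negative integer confusion counts.
#' @return Named numeric vector with `Acc`, `Sn`, `Sp`.
#' @export
#' @examples
#' computeMetrics(63, 5, 63, 6)  # Acc 0.9197, Sn 0.9265, Sp 0.9130
computeMetrics <- function(TP, FN, TN, FP) {
  counts <- c(TP, FN, TN, FP)
  if (any(counts < 0) || any(counts != round(counts)))
    muscnetError("confusion counts must be non-negative integers",
                 "muscnet_input_error")
  P <- TP + FN
  N <- TN + FP
  if (P == 0 || N == 0)
    muscnetError("both classes must be represented (P > 0 and N > 0)",
                 "muscnet_undefined_metric")
  c(Acc = (TP + TN) / (P + N), Sn = TP / P, Sp = TN / N)
}

# normalize the `features` argument: a matrix or a list of 1-2 matrices,
# all with rownames (subject ids) and identical row order
normalizeFeatureList <- function(features) {
  if (is.matrix(features)) {
    nm <- attr(features, "metric")
    features <- stats::setNames(list(features),
                                if (is.null(nm)) "metric1" else nm)
  }
  if (!is.list(features) || !length(features) %in% c(1L, 2L))
    muscnetError("features must be one matrix or a list of 1-2 matrices",
                 "muscnet_input_error")
  if (is.null(names(features)))
    names(features) <- paste0("metric", seq_along(features))
  n <- nrow(features[[1L]])
  for (f in features)
    if (nrow(f) != n)
      muscnetError("all feature matrices must have the same subjects",
                   "muscnet_input_error")
  features
}

# Held-out decision scores for every subject and metric under LOOCV:
# feature filtering and SVM training are redone inside each fold on the
# training subjects only.  selectionHook, when given, is called with the
# subject ids visible to each fold's selection (leakage audit).
loocvScores <- function(features, y, filter = "Ttest", threshold = 0.05,
                        cost = 1, selectionHook = NULL,
                        normalizeScores = FALSE) {
  features <- normalizeFeatureList(features)
  y <- labelsToBinary(y)
  n <- length(y)
  if (nrow(features[[1L]]) != n)
    muscnetError("labels must match feature rows", "muscnet_input_error")
  if (sum(y == 1L) < 2L || sum(y == 0L) < 2L)
    muscnetError("at least 2 subjects per class are required",
                 "muscnet_input_error")
  scores <- matrix(NA_real_, n, length(features),
                   dimnames = list(NULL, names(features)))
  perFoldSelected <- vector("list", n)
  for (i in seq_len(n)) {
    train <- setdiff(seq_len(n), i)
    sel <- list()
    for (m in names(features)) {
      Xtr <- features[[m]][train, , drop = FALSE]
      if (!is.null(selectionHook)) selectionHook(rownames(Xtr), i)
      fr <- selectFeatures(Xtr, y[train], method = filter,
                           threshold = threshold)
      est <- trainEstimator(Xtr, y[train], regularization = cost,
                            featureIndices = fr$selected, metric = m)
      s <- estimatorScores(est, features[[m]][i, , drop = FALSE])
      if (normalizeScores && !est$fallback) {
        trSc <- estimatorScores(est, Xtr)
        if (sd(trSc) > 0) s <- (s - mean(trSc)) / sd(trSc)
      }
      scores[i, m] <- s
      sel[[m]] <- fr$selected
    }
    perFoldSelected[[i]] <- sel
  }
  list(scores = scores, perFoldSelected = perFoldSelected, y = y)
}

buildEvaluation <- function(fused, y, perFoldSelected, config,
                            diagnostics = list()) {
  pred <- as.integer(fused > 0)
  TP <- sum(pred == 1L & y == 1L)
  FN <- sum(pred == 0L & y == 1L)
  TN <- sum(pred == 0L & y == 0L)
  FP <- sum(pred == 1L & y == 0L)
  new("EvaluationResult",
      predictions = pred, truth = as.integer(y), scores = as.numeric(fused),
      counts = c(TP = TP, FN = FN, TN = TN, FP = FP),
      metrics = computeMetrics(TP, FN, TN, FP),
      perFoldSelected = perFoldSelected,
      config = config, diagnostics = diagnostics)
}

#' Leave-one-out cross-validated evaluation
#'
#' For each fold, one subject is held out; filter feature selection is
#' recomputed on the remaining subjects only, one linear-SVM estimator is
#' trained per metric on that fold's selection, the held-out subject's
#' decision scores are computed and (for a metric duet) linearly fused with
#' weight `alpha`, and the fused score is thresholded at 0 (positive =
#' MCI).  Every subject is predicted exactly once.
#'
#' @param features one subjects x features matrix, or a named list of two
#'   (one per metric of the duet), as produced by [cohortFeatures()].
#' @param y labels, `"MCI"`/`"NC"` or 1/0.
#' @param filter filter method, see [selectFeatures()].
#' @param threshold filter p-value threshold.
#' @param alpha fusion weight for a duet (weight of the first metric);
#'   ignored for a single metric.
#' @param cost SVM regularization constant.
#' @param normalizeScores logical; z-score each estimator's held-out
#'   decision score against its training-set score distribution before
#'   fusing.  Off by default: the weighted-voting rule fuses raw scores.
#' @return An [EvaluationResult-class].
#' @export
loocv <- function(features, y, filter = "Ttest", threshold = 0.05,
                  alpha = 0.5, cost = 1, normalizeScores = FALSE) {
  sc <- loocvScores(features, y, filter, threshold, cost,
                    normalizeScores = normalizeScores)
  fused <- if (ncol(sc$scores) == 2L)
    fuseScores(sc$scores[, 1L], sc$scores[, 2L], alpha)
  else sc$scores[, 1L]
  buildEvaluation(fused, sc$y, sc$perFoldSelected,
                  config = list(metrics = colnames(sc$scores), alpha = alpha,
                                filter = filter, threshold = threshold,
                                cost = cost, protocol = "loocv"))
}

#' LOOCV evaluation over the full fusion-weight grid
#'
#' Runs the leave-one-out protocol once (per-fold selection and estimator
#' training do not depend on `alpha`) and evaluates the fused predictions
#' at every `alpha` of the grid.  The full table is always reported next to
#' the argmax: the per-alpha best of a sweep is an optimistically selected
#' number, and collapsing the table to it silently would hide that.
#'
#' @inheritParams loocv
#' @param alphas fusion-weight grid (default 0.1 to 0.9 by 0.1).
#' @return A list with `table` (a data.frame of alpha, Acc, Sn, Sp),
#'   `results` (one [EvaluationResult-class] per alpha), and `best` (the
#'   result at the argmax accuracy; ties broken toward smaller alpha).
#' @export
alphaGrid <- function(features, y, filter = "Ttest", threshold = 0.05,
                      alphas = seq(0.1, 0.9, by = 0.1), cost = 1,
                      normalizeScores = FALSE) {
  sc <- loocvScores(features, y, filter, threshold, cost,
                    normalizeScores = normalizeScores)
  if (ncol(sc$scores) != 2L)
    muscnetError("alphaGrid requires a metric duet (two feature matrices)",
                 "muscnet_input_error")
  results <- lapply(alphas, function(a) {
    fused <- fuseScores(sc$scores[, 1L], sc$scores[, 2L], a)
    buildEvaluation(fused, sc$y, sc$perFoldSelected,
                    config = list(metrics = colnames(sc$scores), alpha = a,
                                  filter = filter, threshold = threshold,
                                  cost = cost, protocol = "loocv"))
  })
  tab <- data.frame(
    alpha = alphas,
    Acc = vapply(results, function(r) r@metrics[["Acc"]], numeric(1L)),
    Sn = vapply(results, function(r) r@metrics[["Sn"]], numeric(1L)),
    Sp = vapply(results, function(r) r@metrics[["Sp"]], numeric(1L))
  )
  list(table = tab, results = results,
       best = results[[which.max(tab$Acc)]])
}

#' Nested (two-level) leave-one-out cross-validation
#'
#' The honest protocol for tuning the free parameters: for each outer fold,
#' an inner LOOCV over the outer training subjects alone evaluates every
#' `(alpha, threshold)` candidate; the candidate with the best inner
#' accuracy (ties: smaller alpha, then smaller threshold) is used to
#' predict the outer held-out subject.  The held-out subject is never
#' visible to the inner selection; the audit log in `diagnostics`
#' records, per outer fold, the subject ids the inner selection actually
#' saw, captured from the matrices handed to the filter.
#'
#' @inheritParams alphaGrid
#' @param thresholds candidate filter thresholds.
#' @return An [EvaluationResult-class]; `@diagnostics$audit` holds the
#'   leakage audit log and `@diagnostics$innerChoice` the per-fold chosen
#'   parameters.
#' @export
nestedLoocv <- function(features, y, filter = "Ttest",
                        thresholds = 0.05,
                        alphas = seq(0.1, 0.9, by = 0.1), cost = 1) {
  features <- normalizeFeatureList(features)
  y <- labelsToBinary(y)
  n <- length(y)
  duet <- length(features) == 2L
  alphaCands <- if (duet) sort(alphas) else NA_real_
  ids <- rownames(features[[1L]])
  if (is.null(ids)) {
    ids <- paste0("S", seq_len(n))
    features <- lapply(features, function(f) { rownames(f) <- ids; f })
  }
  audit <- vector("list", n)
  innerChoice <- vector("list", n)
  fused <- numeric(n)
  perFoldSelected <- vector("list", n)
  for (i in seq_len(n)) {
    outerTrain <- setdiff(seq_len(n), i)
    trainFeat <- lapply(features, function(f) f[outerTrain, , drop = FALSE])
    seen <- character(0L)
    hook <- function(idsSeen, fold) seen <<- union(seen, idsSeen)
    # inner grid search: one inner LOOCV per threshold, all alphas read off it
    bestAcc <- -Inf; bestAlpha <- NA_real_; bestThr <- NA_real_
    for (thr in sort(thresholds)) {
      sc <- loocvScores(trainFeat, y[outerTrain], filter, thr, cost,
                        selectionHook = hook)
      for (a in alphaCands) {
        f <- if (duet) fuseScores(sc$scores[, 1L], sc$scores[, 2L], a)
             else sc$scores[, 1L]
        acc <- mean(as.integer(f > 0) == sc$y)
        better <- acc > bestAcc + 1e-12 ||
          (abs(acc - bestAcc) <= 1e-12 &&
             (isTRUE(a < bestAlpha) ||
                (identical(a, bestAlpha) && thr < bestThr)))
        if (better) { bestAcc <- acc; bestAlpha <- a; bestThr <- thr }
      }
    }
    audit[[i]] <- list(heldOut = ids[i], innerSeen = seen)
    innerChoice[[i]] <- list(alpha = bestAlpha, threshold = bestThr,
                             innerAcc = bestAcc)
    # refit on the full outer training set with the chosen parameters
    sel <- list()
    sOut <- numeric(length(features))
    for (k in seq_along(features)) {
      m <- names(features)[k]
      fr <- selectFeatures(trainFeat[[k]], y[outerTrain], method = filter,
                           threshold = bestThr)
      est <- trainEstimator(trainFeat[[k]], y[outerTrain],
                            regularization = cost,
                            featureIndices = fr$selected, metric = m)
      sOut[k] <- estimatorScores(est, features[[k]][i, , drop = FALSE])
      sel[[m]] <- fr$selected
    }
    perFoldSelected[[i]] <- sel
    fused[i] <- if (duet) fuseScores(sOut[1L], sOut[2L], bestAlpha) else sOut[1L]
  }
  buildEvaluation(fused, y, perFoldSelected,
                  config = list(metrics = names(features), alpha = NULL,
                                filter = filter,
                                threshold = NULL, cost = cost,
                                protocol = "nested_loocv",
                                thresholds = thresholds, alphas = alphas),
                  diagnostics = list(audit = audit, innerChoice = innerChoice))
}
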