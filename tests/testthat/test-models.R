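test_that("a separable toy problem is fit perfectly and symmetrically", {
  set.seed(1)
  X <- rbind(matrix(rnorm(20, mean = 2), 10),
             matrix(rnorm(20, mean = -2), 10))
  y <- rep(c(1, 0), each = 10)
  est <- trainEstimator(X, y)
  sc <- estimatorScores(est, X)
  expect_identical(as.integer(sc > 0), as.integer(y))
  # flipped labels negate the decision scores (up to solver tolerance)
  estFlip <- trainEstimator(X, 1 - y)
  expect_equal(estimatorScores(estFlip, X), -sc, tolerance = 1e-4)
})

test_that("decision scores agree with an independent SVM solver", {
  skip_if_not_installed("kernlab")
  set.seed(33)
  X <- matrix(rnorm(40 * 50), 40)
  y <- rep(c(1, 0), each = 20)
  est <- trainEstimator(X, y, balancedWeights = FALSE)
  mine <- estimatorScores(est, X)
  ref <- kernlab::ksvm(X, factor(y, levels = c(1, 0)),
                       kernel = "vanilladot", kpar = list(), C = 1,
                       scaled = FALSE, tol = 1e-6)
  refScores <- kernlab::predict(ref, X, type = "decision")[, 1]
  if (cor(mine, refScores) < 0) refScores <- -refScores
  expect_gt(cor(mine, refScores), 0.999)
  expect_equal(mine, refScores, tolerance = 0.02)
})

test_that("empty feature selections fall back to a flagged majority scorer", {
  X <- matrix(rnorm(20), 10, 2)
  y <- c(rep(1, 6), rep(0, 4))
  est <- trainEstimator(X, y, featureIndices = integer(0))
  expect_true(est$fallback)
  expect_true(all(estimatorScores(est, X) > 0))  # majority is MCI
})

test_that("score fusion follows the weighted-voting arithmetic", {
  expect_equal(fuseScores(2, -1, 0.5), 0.5)
  expect_equal(fuseScores(2, -1, 0.1), -0.7)
  # fusing an estimator with itself changes nothing, for every alpha
  s <- rnorm(10)
  for (a in seq(0.1, 0.9, by = 0.1))
    expect_identical(fuseScores(s, s, a) > 0, s > 0)
  expect_error(fuseScores(1, 1, 1.5), class = "muscnet_input_error")
})

test_that("confusion-count metrics reproduce their defining ratios", {
  expect_equal(computeMetrics(5, 0, 5, 0), c(Acc = 1, Sn = 1, Sp = 1))
  expect_equal(computeMetrics(0, 5, 0, 5), c(Acc = 0, Sn = 0, Sp = 0))
  m <- computeMetrics(63, 5, 63, 6)
  expect_equal(m[["Acc"]], 126 / 137)
  expect_equal(m[["Sn"]], 63 / 68)
  expect_equal(m[["Sp"]], 63 / 69)
  expect_error(computeMetrics(0, 0, 3, 2), class = "muscnet_undefined_metric")
})

test_that("LOOCV predicts every subject exactly once and satisfies Acc identity", {
  pf <- plantedFeatures(nPerGroup = 8, nFeatures = 15, shift = 2, seed = 3)
  ev <- loocv(pf$X, pf$y, "Ttest", 0.05)
  expect_length(predictions(ev), length(pf$y))
  expect_false(anyNA(predictions(ev)))
  cnt <- confusionCounts(ev)
  P <- sum(pf$y == 1); N <- sum(pf$y == 0)
  expect_identical(cnt[["TP"]] + cnt[["FN"]], P)
  expect_identical(cnt[["TN"]] + cnt[["FP"]], N)
  perf <- performance(ev)
  expect_equal(perf[["Acc"]],
               (perf[["Sn"]] * P + perf[["Sp"]] * N) / (P + N))
  # a huge planted effect is classified perfectly
  expect_equal(perf[["Acc"]], 1)
  # one selection record per fold
  expect_length(perFoldSelected(ev), length(pf$y))
})

test_that("score normalization preserves the evaluation contract", {
  pf <- plantedFeatures(nPerGroup = 6, nFeatures = 10, shift = 2, seed = 15)
  ev <- loocv(list(a = pf$X, b = pf$X), pf$y, "Ttest", 0.2,
              normalizeScores = TRUE)
  expect_length(predictions(ev), length(pf$y))
  expect_identical(sum(confusionCounts(ev)), length(pf$y))
})

test_that("LOOCV predictions are invariant to subject ordering", {
  pf <- plantedFeatures(nPerGroup = 7, nFeatures = 12, shift = 1, seed = 4)
  ev <- loocv(pf$X, pf$y, "Ttest", 0.2)
  set.seed(5)
  perm <- sample(length(pf$y))
  evPerm <- loocv(pf$X[perm, ], pf$y[perm], "Ttest", 0.2)
  expect_identical(predictions(evPerm), predictions(ev)[perm])
})

test_that("label permutation drives accuracy to the chance band", {
  set.seed(20)
  X <- matrix(rnorm(20 * 25), 20)
  rownames(X) <- paste0("S", 1:20)
  accs <- vapply(1:20, function(r) {
    set.seed(100 + r)
    y <- sample(rep(c(1, 0), each = 10))
    performance(loocv(X, y, "Ttest", 0.2))[["Acc"]]
  }, numeric(1))
  expect_gte(mean(accs), 0.3)
  expect_lte(mean(accs), 0.7)
})

test_that("the alpha sweep reports the full 9-row table with its argmax", {
  pf <- plantedFeatures(nPerGroup = 6, nFeatures = 10, shift = 1.5, seed = 6)
  ag <- alphaGrid(list(a = pf$X, b = pf$X), pf$y, "Ttest", 0.2)
  expect_identical(nrow(ag$table), 9L)
  expect_equal(ag$table$alpha, seq(0.1, 0.9, by = 0.1))
  # same metric twice: all rows identical
  expect_equal(length(unique(ag$table$Acc)), 1L)
  expect_gte(performance(ag$best)[["Acc"]], ag$table$Acc[ag$table$alpha == 0.5])
})

test_that("nested LOOCV with one candidate equals plain LOOCV", {
  pf <- plantedFeatures(nPerGroup = 6, nFeatures = 10, shift = 2, seed = 7)
  feats <- list(a = pf$X, b = pf$X + rnorm(length(pf$X), 0, 0.1))
  plain <- loocv(feats, pf$y, "Ttest", 0.05, alpha = 0.3)
  nested <- nestedLoocv(feats, pf$y, "Ttest", thresholds = 0.05, alphas = 0.3)
  expect_identical(predictions(nested), predictions(plain))
  expect_equal(performance(nested), performance(plain))
})

test_that("nested LOOCV stays close to the non-nested best alpha on strong effects", {
  pf <- plantedFeatures(nPerGroup = 8, nFeatures = 12, shift = 2.5, seed = 8)
  set.seed(88)
  feats <- list(a = pf$X, b = pf$X[, sample(ncol(pf$X))])
  ag <- alphaGrid(feats, pf$y, "Ttest", 0.05, alphas = c(0.3, 0.5, 0.7))
  nested <- nestedLoocv(feats, pf$y, "Ttest", thresholds = 0.05,
                        alphas = c(0.3, 0.5, 0.7))
  expect_lte(abs(performance(nested)[["Acc"]] -
                   max(ag$table$Acc)), 0.1)
})

test_that("the inner selection never sees the outer held-out subject", {
  pf <- plantedFeatures(nPerGroup = 5, nFeatures = 8, shift = 1, seed = 9)
  nested <- nestedLoocv(list(m = pf$X), pf$y, "Ttest",
                        thresholds = c(0.05, 0.2))
  audit <- nested@diagnostics$audit
  expect_length(audit, length(pf$y))
  for (fold in audit) {
    expect_gt(length(fold$innerSeen), 0)
    expect_false(fold$heldOut %in% fold$innerSeen)
  }
})
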