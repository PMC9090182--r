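test_that("index/pair maps match their declared conventions", {
  expect_equal(unname(indexToPair(1, 116, "full_square")[1, ]), c(1, 1))
  expect_equal(unname(indexToPair(118, 116, "full_square")[1, ]), c(2, 2))
  expect_equal(unname(indexToPair(4, 4, "upper_triangle")[1, ]), c(2, 3))
  expect_error(indexToPair(7, 4, "upper_triangle"),
               class = "muscnet_input_error")
})

test_that("index maps are exact inverses on all valid indices", {
  for (r in 3:10) {
    nUt <- r * (r - 1) / 2
    p <- indexToPair(seq_len(nUt), r, "upper_triangle")
    expect_true(all(p[, 1] < p[, 2]))
    expect_identical(pairToIndex(p[, 1], p[, 2], r, "upper_triangle"),
                     seq_len(nUt))
    pf <- indexToPair(seq_len(r^2), r, "full_square")
    expect_identical(pairToIndex(pf[, 1], pf[, 2], r, "full_square"),
                     seq_len(r^2))
    # flatten order consistency: feature k holds the (i, j) entry
    m <- matrix(0, r, r)
    for (i in 1:(r - 1)) for (j in (i + 1):r) {
      m[i, j] <- i * 100 + j
      m[j, i] <- i * 100 + j
    }
    fv <- flattenConnectivity(m, "upper_triangle")
    expect_equal(fv, p[, 1] * 100 + p[, 2])
  }
})

makeEval <- function(perFold, n = 4) {
  y <- rep(c(1L, 0L), n / 2)
  new("EvaluationResult",
      predictions = y, truth = y, scores = as.numeric(y) - 0.5,
      counts = c(TP = sum(y), FN = 0L, TN = sum(y == 0), FP = 0L),
      metrics = c(Acc = 1, Sn = 1, Sp = 1),
      perFoldSelected = perFold, config = list(), diagnostics = list())
}

test_that("frequency tables count folds and conserve ROI aggregation", {
  labs <- paste0("R", 1:4)
  # feature 1 = edge (1,2) selected in all 4 folds, feature 6 = (3,4) in 1
  perFold <- c(rep(list(list(m = c(1L, 6L))), 1),
               rep(list(list(m = 1L)), 3))
  ft <- frequencyTable(makeEval(perFold), labs, metric = "m")
  expect_equal(ft$features$count[ft$features$feature == 1], 4)
  expect_equal(ft$features$count[ft$features$feature == 6], 1)
  expect_equal(ft$nFolds, 4)
  # conservation: sum of ROI counts = 2 x sum of edge counts
  expect_equal(sum(ft$rois$count), 2 * sum(ft$features$count))
  # endpoints of (1,2) credited 4 each
  expect_equal(ft$rois$count[ft$rois$roi == 1], 4)
  expect_equal(ft$rois$count[ft$rois$roi == 2], 4)
  # empty selections give all-zero counts
  ft0 <- frequencyTable(makeEval(rep(list(list(m = integer(0))), 4)),
                        labs, metric = "m")
  expect_true(all(ft0$features$count == 0))
  expect_true(all(ft0$rois$count == 0))
  # frequency ties broken by ascending feature index
  expect_identical(ft0$features$feature, seq_len(6L))
})

test_that("top-k overlap reports shared and exclusive features", {
  labs <- paste0("R", 1:5)
  fA <- rep(list(list(m = c(1L, 2L, 3L))), 3)
  fB <- rep(list(list(m = c(1L, 2L, 3L))), 3)
  tA <- frequencyTable(makeEval(fA), labs, "m")
  tB <- frequencyTable(makeEval(fB), labs, "m")
  ovSame <- topKOverlap(tA, tB, 3)
  expect_equal(ovSame$overlap, 3)
  fC <- rep(list(list(m = c(8L, 9L, 10L))), 3)
  tC <- frequencyTable(makeEval(fC), labs, "m")
  ovDisj <- topKOverlap(tA, tC, 3)
  expect_equal(ovDisj$overlap, 0)
  expect_equal(nrow(ovDisj$onlyA), 3)
  # exclusive features carry their rank in the other table
  expect_true(all(ovDisj$onlyA$rankInOther > 3))
  expect_error(topKOverlap(tA, tB, 99), class = "muscnet_input_error")
})

test_that("frequency tables from a planted run rank planted edges on top", {
  ch <- smallCohort(nPerGroup = 6, numRoi = 6, numVolume = 60, delta = 0.7,
                    seed = 77)
  X <- cohortFeatures(ch, "PCC")
  ev <- loocv(X, labels(ch), "Ttest", 0.05)
  ft <- frequencyTable(ev, roiLabels(ch), metric = 1L)
  planted <- pairToIndex(c(1, 3), c(2, 4), 6)
  topRanks <- ft$features$rank[match(planted, ft$features$feature)]
  expect_true(all(topRanks <= 2 * length(planted)))
})
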