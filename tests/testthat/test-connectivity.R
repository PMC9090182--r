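test_that("metric values match hand-computed examples", {
  expect_equal(corPearson(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(corPearson(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(corPearson(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)

  expect_equal(corSpearman(c(1, 2, 3), c(1, 4, 9)), 1)
  expect_equal(corSpearman(c(1, 2, 3), c(9, 4, 1)), -1)
  # tie-free: ranks are the data themselves, so SCC = PCC here
  expect_equal(corSpearman(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)

  expect_equal(corKendall(1:3, 1:3), 1)
  expect_equal(corKendall(1:3, c(1, 3, 2)), 1 / 3)
  expect_equal(corKendall(1:4, 4:1), -1)

  expect_equal(corCosine(c(1, 0), c(0, 1)), 0)
  expect_equal(corCosine(c(1, 2), c(2, 4)), 1)
  expect_equal(corCosine(c(1, 1), c(1, -1)), 0)
})

test_that("Pearson equals the decentralized cosine similarity", {
  for (s in 1:10) {
    set.seed(s)
    x <- rnorm(60)
    y <- rnorm(60)
    expect_equal(corPearson(x, y),
                 corCosine(x - mean(x), y - mean(y)),
                 tolerance = 1e-12)
  }
})

test_that("Spearman equals Pearson on ranks; Kendall matches pair-count oracle", {
  for (s in 1:10) {
    set.seed(s)
    n <- sample(5:50, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    expect_identical(corSpearman(x, y), corPearson(rank(x), rank(y)))
    expect_equal(corKendall(x, y), kendallOracle(x, y), tolerance = 1e-12)
    # with ties
    xt <- round(x); yt <- round(y * 2) / 2
    if (sd(xt) > 0 && sd(yt) > 0)
      expect_equal(corKendall(xt, yt), kendallOracle(xt, yt),
                   tolerance = 1e-12)
  }
})

test_that("all metrics are symmetric in their arguments", {
  set.seed(7)
  x <- rnorm(64)
  y <- runif(64)
  for (m in connectivityMetrics()) {
    fn <- muscnet:::metricFunction(m)
    expect_equal(fn(x, y), fn(y, x), info = m)
  }
})

test_that("undefined metrics fail loudly, not silently", {
  expect_error(corPearson(rep(1, 10), rnorm(10)),
               class = "muscnet_undefined_metric")
  expect_error(corCosine(rep(0, 5), 1:5),
               class = "muscnet_undefined_metric")
  expect_error(corPearson(1:3, 1:4), class = "muscnet_input_error")
})

test_that("staticBFCN matches a double-loop oracle and its invariants", {
  set.seed(42)
  ts <- matrix(rnorm(4 * 50), nrow = 4)
  for (m in c("PCC", "SCC", "KCC", "CS")) {
    cm <- staticBFCN(ts, m)
    fn <- muscnet:::metricFunction(m)
    v <- connectivityValues(cm)
    for (i in 1:4) for (j in 1:4) {
      expected <- if (i == j) 1 else fn(ts[i, ], ts[j, ])
      expect_equal(v[i, j], expected, info = sprintf("%s (%d,%d)", m, i, j))
    }
    expect_identical(v, t(v))
  }
  # perfectly collinear 2-ROI subject
  cm <- staticBFCN(rbind(c(1, 2, 3), c(2, 4, 6)), "PCC")
  expect_equal(unname(connectivityValues(cm)),
               matrix(1, 2, 2))
})

test_that("staticBFCN names the offending pair for a constant ROI", {
  ts <- matrix(rnorm(3 * 20), nrow = 3)
  ts[2, ] <- 5
  err <- tryCatch(staticBFCN(ts, "PCC"), error = identity)
  expect_s3_class(err, "muscnet_undefined_metric")
  expect_match(conditionMessage(err), "\\(2, 2\\)|\\(1, 2\\)")
})

test_that("connectivity matrices round-trip through delimited text", {
  set.seed(3)
  cm <- staticBFCN(matrix(rnorm(5 * 30), nrow = 5,
                          dimnames = list(paste0("R", 1:5), NULL)), "SCC")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeConnectivity(cm, path)
  back <- readConnectivity(path)
  expect_equal(metricName(back), "SCC")
  expect_equal(connectivityValues(back), connectivityValues(cm),
               tolerance = 1e-12)
  expect_identical(roiLabels(back), roiLabels(cm))
})
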