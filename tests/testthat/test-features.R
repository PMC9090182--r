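test_that("flatten layouts and their inverses agree with the declared order", {
  a <- 0.2; b <- 0.3; cc <- 0.4
  m <- rbind(c(1, a, b), c(a, 1, cc), c(b, cc, 1))
  expect_equal(flattenConnectivity(m, "upper_triangle"), c(a, b, cc))
  fs <- flattenConnectivity(m, "full_square")
  expect_length(fs, 9)
  expect_equal(fs[1:5], c(1, a, b, a, 1))
  expect_equal(unflattenConnectivity(fs, 3, "full_square"), m)
  expect_equal(unflattenConnectivity(c(a, b, cc), 3, "upper_triangle"), m)
})

test_that("flatten round-trips random symmetric matrices in both layouts", {
  for (s in 1:5) {
    set.seed(s)
    r <- sample(3:12, 1)
    m <- matrix(rnorm(r * r), r)
    m <- (m + t(m)) / 2
    diag(m) <- 1
    expect_equal(unflattenConnectivity(
      flattenConnectivity(m, "full_square"), r, "full_square"), m)
    expect_equal(unflattenConnectivity(
      flattenConnectivity(m, "upper_triangle"), r, "upper_triangle"), m)
  }
})

test_that("t-test p-values match the textbook formula", {
  pf <- plantedFeatures(nPerGroup = 20, nFeatures = 20, seed = 5)
  p <- ttestPvalues(pf$X, pf$y)
  a <- pf$X[pf$y == 1, , drop = FALSE]
  b <- pf$X[pf$y == 0, , drop = FALSE]
  for (j in seq_len(ncol(pf$X)))
    expect_equal(p[[j]], tOracle(a[, j], b[, j]), tolerance = 1e-10)
  # planted features are overwhelmingly significant, null ones mostly not
  expect_true(all(p[1:5] < 1e-3))
})

test_that("identical groups give p near 1 and are never selected at 0.05", {
  set.seed(8)
  X <- matrix(rnorm(60 * 4), 60)
  X[31:60, ] <- X[1:30, ]  # exactly identical group values
  y <- rep(c(1, 0), each = 30)
  expect_true(all(ttestPvalues(X, y) > 0.99))
  expect_length(selectFeatures(X, y, "Ttest", 0.05)$selected, 0)
})

test_that("rank-sum p-values: exact null for separation, rank invariance", {
  X <- cbind(c(1:10, 11:20))
  y <- rep(c(0, 1), each = 10)
  # complete separation: p from the exact U-statistic null distribution
  expect_equal(ranksumPvalues(X, y)[[1]], 2 / choose(20, 10),
               tolerance = 1e-12)
  set.seed(2)
  Z <- matrix(rnorm(40 * 5), 40)
  yz <- rep(c(1, 0), 20)
  expect_equal(ranksumPvalues(exp(Z), yz), ranksumPvalues(Z, yz),
               tolerance = 1e-12)
})

test_that("KS statistic matches the brute-force ECDF scan", {
  set.seed(4)
  for (r in 1:5) {
    a <- rnorm(20)
    b <- rnorm(20, mean = r / 4)
    expect_equal(unname(ks.test(a, b, exact = FALSE)$statistic),
                 ksStatOracle(a, b), tolerance = 1e-12)
  }
  # disjoint supports: D = 1, tiny p
  X <- cbind(c(rnorm(10), rnorm(10) + 100))
  y <- rep(c(0, 1), each = 10)
  expect_lt(ksPvalues(X, y)[[1]], 1e-3)
})

test_that("fully degenerate features are flagged with p = 1 for all methods", {
  set.seed(6)
  X <- cbind(rep(3, 20), rnorm(20))
  y <- rep(c(1, 0), 10)
  for (m in c("Ttest", "Wtest", "KStest")) {
    fr <- selectFeatures(X, y, m, threshold = 1)
    expect_equal(fr$pvalues[1], 1)
    expect_true(fr$degenerate[1])
    expect_identical(fr$selected, 2L)  # threshold 1 selects all non-degenerate
  }
})

test_that("selection is monotone in the threshold and permutation-equivariant", {
  pf <- plantedFeatures(nPerGroup = 10, nFeatures = 25, shift = 1, seed = 9)
  set.seed(10)
  perm <- sample(ncol(pf$X))
  for (m in c("Ttest", "Wtest", "KStest")) {
    s005 <- selectFeatures(pf$X, pf$y, m, 0.05)$selected
    s02 <- selectFeatures(pf$X, pf$y, m, 0.2)$selected
    expect_true(all(s005 %in% s02), info = m)
    # permuted columns, selection mapped back, must coincide
    sPerm <- selectFeatures(pf$X[, perm], pf$y, m, 0.2)$selected
    expect_setequal(perm[sPerm], s02)
  }
})

test_that("BH adjustment only ever shrinks the raw-p selection", {
  pf <- plantedFeatures(nPerGroup = 12, nFeatures = 30, shift = 1.2, seed = 14)
  raw <- selectFeatures(pf$X, pf$y, "Ttest", 0.1)$selected
  bh <- selectFeatures(pf$X, pf$y, "Ttest", 0.1, adjust = "BH")$selected
  expect_true(all(bh %in% raw))
})

test_that("strongly planted features are recovered by the filter", {
  pf <- plantedFeatures(nPerGroup = 15, nFeatures = 40, shift = 2.5,
                        nInformative = 10, seed = 12)
  sel <- selectFeatures(pf$X, pf$y, "Ttest", 0.05)$selected
  expect_gte(length(intersect(sel, 1:10)), 8)
})
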