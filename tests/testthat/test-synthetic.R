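test_that("group covariances are valid correlation matrices, differing only when planted", {
  sp0 <- cohortSpec(nPerGroup = 4, numRoi = 12, numVolume = 50,
                    plantedEdges = rbind(c(2, 7)), effectDelta = 0,
                    seed = 1)
  expect_equal(buildGroupCovariance(sp0, "NC"),
               buildGroupCovariance(sp0, "MCI"))
  sp <- cohortSpec(nPerGroup = 4, numRoi = 12, numVolume = 50,
                   plantedEdges = rbind(c(2, 7)), effectDelta = 0.4,
                   seed = 1)
  Snc <- buildGroupCovariance(sp, "NC")
  Smci <- buildGroupCovariance(sp, "MCI")
  for (S in list(Snc, Smci)) {
    expect_equal(diag(S), rep(1, 12))
    expect_identical(S, t(S))
    expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
  # the difference is non-zero exactly at the planted edge
  d <- Smci - Snc
  expect_equal(d[2, 7], 0.4, tolerance = 1e-6)
  d[2, 7] <- 0; d[7, 2] <- 0
  expect_lt(max(abs(d)), 1e-8)
})

test_that("subject generation is deterministic under fixed seeds", {
  sp <- cohortSpec(nPerGroup = 2, numRoi = 5, numVolume = 30, seed = 3,
                   plantedEdges = rbind(c(1, 5)))
  expect_identical(generateSubject(sp, "MCI", 17),
                   generateSubject(sp, "MCI", 17))
  ch1 <- generateCohort(sp)
  ch2 <- generateCohort(sp)
  expect_identical(signals(ch1), signals(ch2))
})

test_that("long series converge to the group covariance entrywise", {
  sp <- cohortSpec(nPerGroup = 1, numRoi = 6, numVolume = 8000,
                   plantedEdges = rbind(c(1, 4)), effectDelta = 0.5,
                   seed = 5)
  m <- generateSubject(sp, "MCI", 501)
  emp <- cor(t(m))
  expect_lt(max(abs(emp - buildGroupCovariance(sp, "MCI"))), 0.03)
})

test_that("quadratic coupling hides from Pearson but not from MIC", {
  sp <- cohortSpec(nPerGroup = 1, numRoi = 4, numVolume = 500,
                   plantedEdges = rbind(c(1, 2)), coupling = "quadratic",
                   seed = 7)
  m <- generateSubject(sp, "MCI", 701)
  # sample PCC fluctuates around its true value of 0; MIC sees the coupling
  expect_lt(abs(corPearson(m[1, ], m[2, ])), 0.25)
  expect_gt(mic(m[1, ], m[2, ]), 0.3)
  expect_gt(mic(m[1, ], m[2, ]) - abs(corPearson(m[1, ], m[2, ])), 0.2)
})

test_that("cohorts have the declared shape, labels and ground truth", {
  sp <- cohortSpec(nPerGroup = 3, numRoi = 8, numVolume = 25, seed = 9,
                   plantedEdges = rbind(c(1, 2), c(3, 8)))
  ch <- generateCohort(sp)
  expect_identical(nSubjects(ch), 6L)
  expect_identical(nRoi(ch), 8L)
  expect_identical(nVolumes(ch), 25L)
  expect_identical(as.character(labels(ch)),
                   rep(c("MCI", "NC"), each = 3))
  expect_false(anyDuplicated(subjectIds(ch)) > 0)
  expect_identical(ch@groundTruth$plantedEdges, sp$plantedEdges)
})

test_that("classification accuracy is monotone in the planted effect size", {
  deltas <- c(0, 0.3, 0.6)
  accs <- vapply(deltas, function(d) {
    sp <- cohortSpec(nPerGroup = 8, numRoi = 8, numVolume = 137,
                     plantedEdges = rbind(c(1, 2), c(3, 4), c(5, 6)),
                     effectDelta = d, seed = 21)
    ch <- generateCohort(sp)
    performance(loocv(cohortFeatures(ch, "PCC"), labels(ch),
                      "Ttest", 0.05))[["Acc"]]
  }, numeric(1))
  n <- 16
  se <- sqrt(pmax(accs * (1 - accs), 0.25 / 4) / n)
  expect_gte(accs[2], accs[1] - se[1])
  expect_gte(accs[3], accs[2] - se[2])
})

test_that("invalid planted edges and scanner-margin trimming behave as declared", {
  expect_error(cohortSpec(plantedEdges = rbind(c(3, 3))),
               class = "muscnet_input_error")
  expect_error(cohortSpec(numRoi = 4, plantedEdges = rbind(c(1, 9))),
               class = "muscnet_input_error")
  x <- matrix(rnorm(2 * 140), 2)
  expect_identical(ncol(discardInitialVolumes(x)), 137L)
  expect_identical(discardInitialVolumes(x, 0), x)
})
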