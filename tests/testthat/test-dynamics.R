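test_that("window counts match the floor-division formula examples", {
  expect_identical(numWindows(137, 50, 8), 11L)
  expect_identical(numWindows(100, 100, 5), 1L)
  expect_identical(numWindows(137, 110, 10), 3L)
  expect_error(numWindows(100, 110, 5), class = "muscnet_input_error")
  expect_error(numWindows(100, 10, 20), class = "muscnet_input_error")
})

test_that("window count equals exhaustive enumeration of valid starts", {
  for (nv in c(3, 10, 57, 137, 200)) {
    for (size in unique(pmin(nv, c(1, 2, 5, 20, 50, nv)))) {
      for (step in unique(pmin(size, c(1, 2, 7, 20)))) {
        starts <- seq(1, nv, by = step)
        oracle <- sum(starts + size - 1 <= nv)
        expect_identical(numWindows(nv, size, step), as.integer(oracle),
                         info = sprintf("nv=%d size=%d step=%d", nv, size, step))
      }
    }
  }
})

test_that("extracted segments cover the declared index ranges", {
  x <- matrix(seq_len(2 * 137), nrow = 2)  # values encode column index
  segs <- extractWindows(x, 50, 8)
  expect_length(segs, 11)
  expect_identical(segs[[1]], x[, 1:50])
  expect_identical(segs[[11]], x[, 81:130])  # trailing volumes dropped
  expect_true(all(vapply(segs, ncol, integer(1)) == 50))

  one <- extractWindows(x, 137, 5)
  expect_identical(one[[1]], x)
})

test_that("dynamic BFCN is the mean of per-window static BFCNs", {
  set.seed(9)
  ts <- matrix(rnorm(5 * 90), nrow = 5)
  dyn <- dynamicBFCN(ts, "PCC", windowSize = 40, windowStep = 10)
  segs <- extractWindows(ts, 40, 10)
  perWin <- lapply(segs, function(s) connectivityValues(staticBFCN(s, "PCC")))
  oracle <- Reduce(`+`, perWin) / length(perWin)
  expect_equal(connectivityValues(dyn), oracle, tolerance = 1e-12)
  # mean property: entries within the per-window range
  lo <- Reduce(pmin, perWin); hi <- Reduce(pmax, perWin)
  expect_true(all(connectivityValues(dyn) >= lo - 1e-12))
  expect_true(all(connectivityValues(dyn) <= hi + 1e-12))
  # symmetry inherited
  v <- connectivityValues(dyn)
  expect_identical(v, t(v))
})

test_that("a full-length window reduces the dynamic BFCN to the static one", {
  set.seed(10)
  ts <- matrix(rnorm(4 * 60), nrow = 4)
  for (m in c("PCC", "KCC")) {
    expect_equal(connectivityValues(dynamicBFCN(ts, m, 60, 10)),
                 connectivityValues(staticBFCN(ts, m)),
                 tolerance = 1e-12, info = m)
  }
})

test_that("an undefined window correlation reports the window index", {
  ts <- matrix(rnorm(3 * 60), nrow = 3)
  ts[2, 31:60] <- 7  # constant only in the second half
  err <- tryCatch(dynamicBFCN(ts, "PCC", 30, 30), error = identity)
  expect_s3_class(err, "muscnet_undefined_metric")
  expect_match(conditionMessage(err), "window 2")
})
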