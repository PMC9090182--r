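# Shared fixtures and independent oracles used across the suite.

# Exhaustive O(n^2) concordant/discordant pair count with tie correction
# (tau-b); independent of stats::cor.
kendallOracle <- function(x, y) {
  n <- length(x)
  C <- 0L; D <- 0L
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
    if (s > 0) C <- C + 1L else if (s < 0) D <- D + 1L
  }
  n0 <- n * (n - 1) / 2
  tx <- sum(sapply(split(x, x), function(g) length(g) * (length(g) - 1) / 2))
  ty <- sum(sapply(split(y, y), function(g) length(g) * (length(g) - 1) / 2))
  (C - D) / sqrt((n0 - tx) * (n0 - ty))
}

# pooled-variance two-sample t-test p-value from the textbook formula
tOracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  2 * pt(-abs(tstat), df = na + nb - 2)
}

# brute-force two-sample KS statistic: max ECDF gap scanned at all points
ksStatOracle <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(p) mean(a <= p) - mean(b <= p), numeric(1))))
}

# tiny deterministic cohort for plumbing tests
smallCohort <- function(nPerGroup = 5, numRoi = 6, numVolume = 40,
                        delta = 0.6, seed = 101, coupling = "linear") {
  generateCohort(cohortSpec(
    nPerGroup = nPerGroup, numRoi = numRoi, numVolume = numVolume,
    plantedEdges = rbind(c(1, 2), c(3, 4)),
    effectDelta = delta, coupling = coupling, seed = seed))
}

# synthetic feature matrices with a planted mean shift on the first
# `nInformative` features; returns list(X, y)
plantedFeatures <- function(nPerGroup = 10, nFeatures = 30,
                            shift = 2, nInformative = 5, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(2 * nPerGroup * nFeatures), 2 * nPerGroup)
  y <- rep(c(1L, 0L), each = nPerGroup)
  X[y == 1L, seq_len(nInformative)] <-
    X[y == 1L, seq_len(nInformative)] + shift
  rownames(X) <- paste0("S", seq_len(nrow(X)))
  list(X = X, y = y)
}
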