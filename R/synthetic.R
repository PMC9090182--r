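#' Specification of a synthetic two-group BOLD cohort
#'
#' Describes a cohort of multivariate Gaussian ROI time series in two
#' diagnostic groups whose inter-ROI correlation structure differs on a
#' planted edge set -- the ground truth every downstream stage (filter
#' recovery, classification, frequency ranking) is validated against.
#'
#' The default scale mirrors a typical preprocessed rs-fMRI cohort in the
#' time dimension (137 retained volumes) while shrinking the spatial and
#' subject dimensions (20 ROIs, 20 subjects per group) to desk-test size;
#' `numRoi = 116` gives the full atlas-sized mode.
#'
#' @param nPerGroup subjects per group (MCI and NC).
#' @param numRoi number of ROIs.
#' @param numVolume volumes (time points) per subject.
#' @param plantedEdges 2-column matrix of distinct ROI index pairs (i < j)
#'   whose connectivity differs between groups; default: up to 10 disjoint
#'   random pairs derived from `seed`.
#' @param effectDelta correlation difference planted on those edges
#'   between the MCI and NC groups (linear coupling mode).
#' @param coupling `"linear"` (correlation shift by `effectDelta`) or
#'   `"quadratic"` (in the MCI group only, each planted edge's second ROI
#'   becomes a rescaled square of the first plus noise -- a relationship
#'   with near-zero Pearson correlation that MIC detects).
#' @param arCoefficient AR(1) temporal autocorrelation in `[0, 1)`; the
#'   innovation scaling keeps the stationary cross-ROI correlation equal
#'   to the group covariance.
#' @param noiseSd for quadratic coupling, the proportion of independent
#'   noise mixed into the driven ROI (in `[0, 1)`).
#' @param seed integer seed governing all randomness of the cohort.
#' @return A list of class `CohortSpec`.
#' @export
cohortSpec <- function(nPerGroup = 20L, numRoi = 20L, numVolume = 137L,
                       plantedEdges = NULL, effectDelta = 0.5,
                       coupling = c("linear", "quadratic"),
                       arCoefficient = 0.3, noiseSd = 0.3, seed = 42L) {
  coupling <- match.arg(coupling)
  stopifnot(nPerGroup >= 1, numRoi >= 2, numVolume >= 3,
            arCoefficient >= 0, arCoefficient < 1,
            noiseSd >= 0, noiseSd < 1)
  if (is.null(plantedEdges)) {
    # disjoint random pairs: no ROI participates in two planted edges
    nEdges <- min(10L, numRoi %/% 2L)
    old <- .Random.seed_save()
    set.seed(seed + 1L)
    perm <- sample(numRoi)
    .Random.seed_restore(old)
    a <- perm[seq(1L, 2L * nEdges, by = 2L)]
    b <- perm[seq(2L, 2L * nEdges, by = 2L)]
    plantedEdges <- cbind(pmin(a, b), pmax(a, b))
    plantedEdges <- plantedEdges[order(plantedEdges[, 1L]), , drop = FALSE]
  }
  plantedEdges <- as.matrix(plantedEdges)
  storage.mode(plantedEdges) <- "integer"
  if (ncol(plantedEdges) != 2L ||
      any(plantedEdges[, 1L] >= plantedEdges[, 2L]) ||
      any(plantedEdges < 1L) || any(plantedEdges > numRoi) ||
      anyDuplicated(plantedEdges))
    muscnetError("plantedEdges must be distinct valid pairs with i < j",
                 "muscnet_input_error")
  if (coupling == "quadratic" && any(table(c(plantedEdges)) > 1L))
    muscnetError(
      "quadratic coupling requires disjoint planted edges (each ROI at most once)",
      "muscnet_input_error")
  structure(
    list(nPerGroup = as.integer(nPerGroup), numRoi = as.integer(numRoi),
         numVolume = as.integer(numVolume), plantedEdges = plantedEdges,
         effectDelta = effectDelta, coupling = coupling,
         arCoefficient = arCoefficient, noiseSd = noiseSd,
         seed = as.integer(seed)),
    class = "CohortSpec"
  )
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Group correlation matrix with planted differential edges
#'
#' The NC baseline is block structured (blocks of 5 ROIs with within-block
#' correlation 0.2, a modest community structure typical of parcellated
#' connectomes); the MCI matrix is the same baseline with the planted
#' edges' correlations shifted by `effectDelta` (capped at 0.95 in
#' magnitude).  Both are repaired to positive definiteness by flooring
#' eigenvalues at 1e-6 and renormalizing to unit diagonal -- a
#' deterministic repair, since arbitrary planted deltas can leave the
#' matrix indefinite.
#'
#' @param spec a [cohortSpec()].
#' @param group `"NC"` or `"MCI"`.
#' @return A positive-definite correlation matrix with unit diagonal.
#' @export
buildGroupCovariance <- function(spec, group = c("NC", "MCI")) {
  group <- match.arg(group)
  r <- spec$numRoi
  S <- matrix(0, r, r)
  blocks <- split(seq_len(r), (seq_len(r) - 1L) %/% 5L)
  for (b in blocks) S[b, b] <- 0.2
  diag(S) <- 1
  if (spec$coupling == "quadratic") {
    # the driven ROI of each planted edge is decoupled from the baseline
    # blocks in BOTH groups, so every one of its Pearson edges is ~0 under
    # either diagnosis (cov(x^2, x_k) vanishes for jointly Gaussian
    # drivers) and the quadratic dependence is the only group difference
    driven <- spec$plantedEdges[, 2L]
    S[driven, ] <- 0
    S[, driven] <- 0
    diag(S) <- 1
  }
  if (group == "MCI" && spec$coupling == "linear") {
    for (k in seq_len(nrow(spec$plantedEdges))) {
      i <- spec$plantedEdges[k, 1L]
      j <- spec$plantedEdges[k, 2L]
      v <- max(-0.95, min(0.95, S[i, j] + spec$effectDelta))
      S[i, j] <- v
      S[j, i] <- v
    }
  }
  repairPD(S, delta = spec$effectDelta)
}

# eigenvalue flooring + renormalization to unit diagonal
repairPD <- function(S, floorAt = 1e-6, delta = NA) {
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) < floorAt) {
    v <- pmax(e$values, floorAt)
    S <- e$vectors %*% diag(v) %*% t(e$vectors)
    d <- sqrt(diag(S))
    S <- S / outer(d, d)
    S <- (S + t(S)) / 2
    diag(S) <- 1
    if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= 0)
      muscnetError(
        sprintf("covariance not repairable to positive definite (delta = %s)",
                format(delta)), "muscnet_input_error")
  }
  S
}

#' Generate one subject's synthetic BOLD time series
#'
#' Draws a `numRoi x numVolume` Gaussian series with the group's cross-ROI
#' correlation: i.i.d. multivariate normal innovations passed through an
#' AR(1) filter `x_t = a x_{t-1} + sqrt(1 - a^2) z_t` (burn-in 50
#' volumes), which leaves the stationary contemporaneous correlation equal
#' to the group matrix.  In quadratic coupling mode, for MCI subjects each
#' planted edge (i, j) replaces ROI j's series with the standardized
#' square of ROI i's series mixed with independent noise
#' (`sqrt(1 - noiseSd^2)` vs `noiseSd`), a dependence invisible to
#' Pearson correlation but visible to MIC.
#'
#' @param spec a [cohortSpec()].
#' @param group `"NC"` or `"MCI"`.
#' @param subjectSeed integer seed for this subject's draw.
#' @return A `numRoi x numVolume` matrix with ROI row names.
#' @export
generateSubject <- function(spec, group = c("NC", "MCI"), subjectSeed = 1L) {
  group <- match.arg(group)
  S <- buildGroupCovariance(spec, group)
  r <- spec$numRoi
  burn <- 50L
  tlen <- spec$numVolume + burn
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(subjectSeed))
  Z <- MASS::mvrnorm(tlen, mu = rep(0, r), Sigma = S)   # tlen x r
  a <- spec$arCoefficient
  if (a > 0) {
    sc <- sqrt(1 - a^2)
    X <- Z
    for (t in 2:tlen) X[t, ] <- a * X[t - 1L, ] + sc * Z[t, ]
  } else {
    X <- Z
  }
  X <- t(X[(burn + 1L):tlen, , drop = FALSE])           # r x numVolume
  if (group == "MCI" && spec$coupling == "quadratic") {
    for (k in seq_len(nrow(spec$plantedEdges))) {
      i <- spec$plantedEdges[k, 1L]
      j <- spec$plantedEdges[k, 2L]
      drv <- X[i, ]^2
      drv <- (drv - mean(drv)) / sd(drv)
      eps <- rnorm(spec$numVolume)
      X[j, ] <- sqrt(1 - spec$noiseSd^2) * drv + spec$noiseSd * eps
    }
  }
  rownames(X) <- paste0("ROI", seq_len(r))
  X
}

#' Generate a labelled two-group synthetic cohort
#'
#' `2 * nPerGroup` subjects (MCI first, then NC), fully reproducible from
#' `spec$seed`: subject `s` of the cohort is drawn with seed
#' `spec$seed * 1000 + s` (kept well below 2^31).  The ground truth
#' (spec and planted edge set) travels with the cohort for recovery
#' tests.
#'
#' @param spec a [cohortSpec()].
#' @return A [BoldCohort-class].
#' @export
#' @examples
#' ch <- generateCohort(cohortSpec(nPerGroup = 3, numRoi = 6, numVolume = 40))
#' ch
generateCohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  if (spec$seed * 1000L + 2L * spec$nPerGroup >= .Machine$integer.max)
    muscnetError("seed too large", "muscnet_input_error")
  groups <- rep(c("MCI", "NC"), each = spec$nPerGroup)
  sig <- vector("list", length(groups))
  ids <- character(length(groups))
  for (s in seq_along(groups)) {
    sig[[s]] <- unname(generateSubject(spec, groups[s],
                                       subjectSeed = spec$seed * 1000L + s))
    ids[s] <- sprintf("%s_%03d", tolower(groups[s]), s)
  }
  new("BoldCohort",
      signals = sig, subjectIds = ids,
      labels = factor(groups, levels = c("NC", "MCI")),
      roiLabels = paste0("ROI", seq_len(spec$numRoi)),
      groundTruth = list(spec = spec, plantedEdges = spec$plantedEdges))
}

#' Drop initial volumes from a time-series matrix
#'
#' Scanner runs conventionally discard the first few volumes so the
#' magnetization reaches equilibrium before analysis; e.g. 140 acquired
#' volumes minus the first 3 leave 137 retained.
#'
#' @param x ROI x volume matrix.
#' @param n number of leading volumes to discard (default 3).
#' @return The matrix without its first `n` columns.
#' @export
#' @examples
#' ncol(discardInitialVolumes(matrix(0, 2, 140)))  # 137
discardInitialVolumes <- function(x, n = 3L) {
  stopifnot(is.matrix(x), n >= 0, ncol(x) > n)
  if (n == 0L) return(x)
  x[, -seq_len(n), drop = FALSE]
}
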