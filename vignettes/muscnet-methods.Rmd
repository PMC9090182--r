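---
title: "Multi-metric connectivity networks and weighted-voting classification with muscnet"
author: "muscnet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-metric connectivity networks and weighted-voting classification with muscnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(muscnet)
```

## The problem and the model

A brain functional connectivity network (BFCN) represents each atlas region
of interest (ROI) as a node and the statistical association between two
ROIs' BOLD time series as a weighted edge.  Different association metrics
see different structure: Pearson's $r$ (PCC) captures linear coupling,
Spearman (SCC) and Kendall $\tau_b$ (KCC) capture monotone coupling, cosine
similarity (CS) is the uncentred analogue of PCC, and the maximal
information coefficient (MIC) captures arbitrary — including non-monotone —
functional relationships.  No single metric dominates, which motivates the
model this package implements: **MuscNet**, a weighted-voting fusion of two
base classifiers built from two different metrics' networks.

The pipeline, per subject $n$ with signal matrix $V \in
\mathbb{R}^{\text{numROI} \times \text{numVolume}}$:

1. **Connectivity.** $W_{ij} = \mathrm{corr}(V_i, V_j)$ for every ROI pair,
   giving a symmetric correlation square per subject.  For the *dynamic*
   variant, the series is cut into sliding windows of `windowSize` volumes
   advancing by `windowStep`, giving
   $\lfloor(\text{numVolume} - \text{windowSize})/\text{windowStep}\rfloor + 1$
   segments (137 volumes with size 50 and step 8 give 11), one temporal
   square per segment; the squares are averaged element-wise with no
   intermediate transformation.
2. **Features.** The square is flattened to a per-subject feature vector.
3. **Filtering.** Each feature is tested between the two diagnostic groups
   (two-sample t, Wilcoxon rank-sum, or Kolmogorov–Smirnov); features with
   $p$ strictly below the threshold are kept.
4. **Classification.** One linear-kernel SVM per metric; their decision
   scores $s_A, s_B$ are fused as $\alpha s_A + (1-\alpha) s_B$ with
   $\alpha \in \{0.1, \dots, 0.9\}$; a fused score $> 0$ predicts the
   positive class (MCI), a tie predicts NC.
5. **Evaluation.** Leave-one-out cross-validation (LOOCV) with the filter
   re-fit inside every fold; nested LOOCV when $\alpha$ or the threshold is
   tuned; accuracy, sensitivity and specificity from the confusion counts.
6. **Reporting.** Features are mapped back to ROI pairs and ranked by how
   often the per-fold filters selected them.

## The MIC implementation

MIC is defined over grids: bin $x$ into $k_x$ intervals and $y$ into $k_y$
intervals ($k_x k_y \le B(n)$, both $\ge 2$), compute the mutual
information of the induced 2-D histogram, normalize by
$\log_2 \min(k_x, k_y)$, and take the maximum over all grids.  The
resolution budget is $B(n) = \max(\lfloor n^{0.6} \rfloor, 4)$.  This
package implements the statistic from scratch (C++ core):

* **Search strategy.**  For each orientation and each bin count $q$ on one
  ("fixed") axis, the other axis is optimized *exactly* by a dynamic
  programme over clump boundaries — tied values and runs falling inside a
  single fixed-axis bin are never cut, and at most $15 \cdot
  \lfloor B/q \rfloor$ candidate superclumps are kept (the `clumpFactor`).
  The mutual information decomposes additively over the optimized axis's
  bins when the normalizer is the full sample size, which is what makes the
  interval DP exact given the fixed axis.
* **Fixed-axis handling.**  When enumerating *every* admissible $q$-bin
  partition of the fixed axis fits a deterministic work budget
  (about $5\times 10^7$ elementary operations), all of them are tried, so
  those grid sizes are searched exhaustively; this is always the case for
  the small samples where the exhaustive oracle can run at all, and for
  $q = 2$ even at typical scan lengths.  Beyond the budget the fixed axis
  is equipartitioned (ties kept together) and the DP solution seeds a
  coordinate-ascent refinement: the freshly optimized partition is frozen
  and the other axis re-optimized, alternating until no improvement (at
  most 6 rounds).
* **Guarantee.**  Every candidate the search evaluates is an admissible
  grid, so the reported value never exceeds the true maximum; `exactMode`
  (`micParams(exactMode = TRUE)`) enumerates all grids outright (feasible
  for $n \le 50$, $B \le 16$) and serves as the oracle in the test suite.
* **Conventions.**  Constant inputs return 0 with a warning (no grid
  carries information); both orientations are always evaluated, making the
  statistic exactly symmetric; the search depends on the data only through
  orderings, which yields exact invariance under strictly increasing
  transforms of either argument.

A note on normalization: a normalized-MI variant that divides by the
minimum marginal entropy rather than $\log_2 \min(k_x, k_y)$ circulates in
the applied literature.  This package implements the canonical grid-search
normalization, which is what the reference MINE implementations compute.

```{r mic-demo}
x <- 0:99
c(identity = mic(x, x), parabola = mic(x, (x - 50)^2))
```

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `windowSize`, `windowStep` | full series / 1 | sliding-window length and stride, in volumes; the conventional sweep is size $\in \{50,70,90,110\}$, step $\in \{1,2,4,8,10\}$ |
| filter `method` | `Ttest` | `Ttest` (pooled-variance Student; Welch by flag), `Wtest`, `KStest` |
| `threshold` | 0.05 | raw-p cut, strict `<`; sweeps typically cover 0.01–0.2; `adjust = "BH"` is available but off by default because the classical filter thresholds raw p-values |
| `alpha` | grid 0.1–0.9 | fusion weight of the first metric's score |
| `cost` | 1 | SVM regularization constant C |
| `alphaExponent`, `clumpFactor` | 0.6, 15 | MIC budget exponent and candidate-partition multiplier (canonical values) |

## Numerical and protocol choices

* **Zero-variance signals.**  A constant ROI makes every correlation with
  it undefined; the package raises a typed error naming the ROI pair (and
  the window, for dynamic networks) instead of silently writing 0, because
  silent constants later destabilize the filter tests.
* **Kendall and Spearman ties.**  $\tau_b$ (tie-corrected) and average
  ranks, the standard conventions.
* **Rank-sum p-values.**  Exact null for small tie-free samples,
  tie-corrected normal approximation otherwise (the `stats::wilcox.test`
  defaults).  Features constant in both groups get $p = 1$ and a
  `degenerate` flag; they are never selected.
* **Upper-triangle features by default.**  The literal full-square flatten
  duplicates every edge and carries a constant diagonal that is degenerate
  under every filter test; the upper triangle holds the identical
  classifier information.  `layout = "full_square"` remains available.
* **Class-balanced SVM weights.**  In LOOCV on a balanced cohort, every
  training fold is one subject short in the held-out subject's own class.
  An SVM fit to weakly informative features then drifts toward the fold's
  majority class — systematically the wrong one — which biases null-data
  accuracy far below chance.  Estimators therefore weight classes inversely
  to their training sizes by default (`balancedWeights = FALSE` restores
  the unweighted fit).  Decision scores are fused raw; a z-normalization
  flag exists and is off by default.
* **Ties.**  Fused score exactly 0 predicts NC (conservative toward
  controls); nested-CV parameter ties prefer the smaller $\alpha$, then the
  smaller threshold; frequency-ranking ties prefer the smaller feature
  index.
* **Sweep reporting.**  `alphaGrid()` always returns the full 9-row table
  next to its argmax: the per-grid best is an optimistically selected
  number, and `nestedLoocv()` is the honest protocol (its audit log
  records, per outer fold, exactly which subject identifiers the inner
  selection saw).

## The synthetic cohort generator

`generateCohort()` draws two groups of multivariate Gaussian ROI time
series whose correlation structure differs on a planted edge set — the
ground truth that recovery and classification tests are scored against.

* **Baseline.**  Block-structured correlation (blocks of 5 ROIs at
  $r = 0.2$), a modest community structure typical of parcellated
  connectomes; AR(1) temporal filtering (coefficient 0.3, innovations
  scaled by $\sqrt{1-a^2}$ so the stationary cross-ROI correlation equals
  the target; 50-volume burn-in).
* **Linear coupling.**  The MCI group's correlations on the planted edges
  are shifted by `effectDelta` (default 0.5).  Matrices are repaired to
  positive definiteness by flooring eigenvalues at $10^{-6}$ and
  renormalizing to unit diagonal — deterministic, and a no-op when the
  shift keeps the matrix valid.
* **Quadratic coupling.**  For MCI subjects each planted edge $(i, j)$
  replaces ROI $j$'s series with the standardized square of ROI $i$'s
  series plus independent noise.  ROI $j$ is decoupled from the baseline
  blocks in *both* groups, so all of its Pearson edges are near 0 under
  either diagnosis ($\mathrm{cov}(x^2, x_k) = 0$ for jointly Gaussian
  drivers): the quadratic dependence is the only group difference, visible
  to MIC and invisible to the linear metrics.  Planted edges are therefore
  required to be disjoint in this mode, and the default edge sampler draws
  disjoint pairs.
* **Scale.**  Defaults mirror a typical preprocessed rs-fMRI cohort in the
  time dimension (137 retained volumes, i.e. 140 acquired minus 3
  equilibration volumes) while shrinking the spatial and subject
  dimensions to desk size: 20 ROIs and 20 subjects per group, the problem
  size the test suite and the bundled evaluations use throughout (MIC over
  all ROI pairs is the cost hotspot; a full 116-ROI atlas mode is just
  `numRoi = 116`).
* **What it does not emulate.**  Hemodynamic response, scanner noise,
  motion artefacts, spatial smoothness, non-stationarity, site effects —
  so green tests demonstrate that the estimators, filters and protocols
  behave correctly on data with known structure, not that any particular
  accuracy will transfer to real cohorts.

## Worked example

```{r pipeline, eval = FALSE}
spec <- cohortSpec(seed = 42)          # 40 subjects, 20 ROIs, 137 volumes
cohort <- generateCohort(spec)
Xp <- cohortFeatures(cohort, "PCC")
ev <- loocv(Xp, labels(cohort), filter = "Ttest", threshold = 0.05)
performance(ev)
ft <- frequencyTable(ev, roiLabels(cohort))
head(ft$features)
```

(The chunk is not evaluated here because the MIC-bearing variants take
minutes; the README shows the printed output of this exact run.)

## Known limitations

* The coordinate-ascent branch of the MIC search is a heuristic; it is
  exhaustive on small instances and for 2-bin fixed axes, but for large
  $n$ and fine grids it can undershoot the true maximum (never overshoot).
* Fusion is pairwise only, matching the weighted-voting design; fusing
  three or more metrics is out of scope.
* The package starts from ROI-level time series; image preprocessing
  (registration, nuisance regression, parcellation, band-pass filtering)
  is upstream and out of scope.
* LOOCV is the protocol of record here for comparability; its variance is
  high at these cohort sizes, and the nested variant is the number to
  trust when any parameter was tuned.
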