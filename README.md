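# muscnet

Weighted-voting fusion of multi-metric brain functional connectivity
networks, for classifying subjects (mild cognitive impairment, MCI, vs
normal controls, NC) from region-of-interest BOLD time series.

## What it does

A brain functional connectivity network (BFCN) has atlas ROIs as nodes and
pairwise associations of their BOLD signals as weighted edges,
`W[i,j] = corr(V_i, V_j)`.  Different correlation metrics expose different
structure, so `muscnet` builds the network under five of them — Pearson
(PCC), Spearman (SCC), Kendall tau-b (KCC), cosine similarity (CS), and a
from-scratch maximal information coefficient (MIC, which also sees
non-monotone coupling) — and classifies by *weighted voting*: two
linear-kernel SVMs, one per metric, whose decision scores are fused as

    score = alpha * s_A + (1 - alpha) * s_B,   alpha in {0.1, ..., 0.9}

with `score > 0` predicting MCI.  Around that core the package provides:

* static and sliding-window *dynamic* networks
  (`floor((numVolume - windowSize)/windowStep) + 1` windows, averaged
  element-wise — 137 volumes, size 50, step 8 give 11 segments);
* filter feature selection on the flattened edge features (two-sample
  t-test, Wilcoxon rank-sum, Kolmogorov–Smirnov; strict `p < threshold`);
* leave-one-out cross-validation with in-fold filtering, the full
  alpha-sweep table, and honest nested LOOCV with a leakage audit log;
* selection-frequency reporting of edges and ROIs across folds;
* a synthetic two-group BOLD cohort generator with planted (linear or
  quadratic) differential connectivity, so the whole pipeline is testable
  against known ground truth;
* TSV/JSON readers and writers and a CLI
  (`inst/cli/muscnet.R`: `simulate`, `connectome`, `evaluate`, `sweep`,
  `report`).

See the methods vignette (`vignettes/muscnet-methods.Rmd`) for the MIC
search algorithm, protocol conventions and generator design.

## Worked example

Forty synthetic subjects (20 MCI / 20 NC), 20 ROIs x 137 volumes, ten
planted edges whose correlation is 0.5 higher in the MCI group:

```r
library(muscnet)
spec   <- cohortSpec(seed = 42)
cohort <- generateCohort(spec)
cohort
#> BoldCohort: 40 subjects (20 MCI / 20 NC), 20 ROIs x 137 volumes
#>   synthetic, 10 planted edge(s), coupling 'linear'

X  <- cohortFeatures(cohort, "PCC")              # 40 x 190 edge features
ev <- loocv(X, labels(cohort), filter = "Ttest", threshold = 0.05)
ev
#> EvaluationResult: 40 subjects | Acc 1.0000, Sn 1.0000, Sp 1.0000
#>   metrics: PCC | alpha: 0.5 | filter: Ttest (p < 0.05)
confusionCounts(ev)
#> TP FN TN FP
#> 20  0 20  0
```

With this effect size every fold classifies its held-out subject
correctly (Acc = Sn = Sp = 1).  The planted edges are exactly the ones the
in-fold filters keep selecting:

```r
ft <- frequencyTable(ev, roiLabels(cohort))
head(ft$features, 5)
#>  feature roiI roiJ labelI labelJ count rank
#>       11    1   12   ROI1  ROI12    40    1
#>       12    1   13   ROI1  ROI13    40    2
#>       21    2    4   ROI2   ROI4    40    3
#>       50    3   16   ROI3  ROI16    40    4
#>       75    5   10   ROI5  ROI10    40    5
```

`count` is the number of LOOCV folds (of 40) whose filter selected the
edge; all ten planted edges (here (1,13), (2,4), (3,16), (5,10), ...) are
selected in every fold.  A quadratic-coupling cohort
(`cohortSpec(coupling = "quadratic", seed = 42)`) makes the planted
dependence invisible to Pearson but not to MIC — on it, the MIC-based
model reaches Acc 1.00 while the PCC-based model stays at chance (0.45),
and fusing the two loses nothing: the complementarity argument for
weighted voting, demonstrated on ground truth.

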