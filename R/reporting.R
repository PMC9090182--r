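#' Map a flattened feature index back to its ROI pair
#'
#' Exact inverse of [flattenConnectivity()].  Indices are 1-based; for the
#' `"upper_triangle"` layout features enumerate the pairs (1,2), (1,3),
#' ..., (1,R), (2,3), ... in row-major order; for `"full_square"` feature
#' `k` maps to row `ceiling(k / R)`, column `(k - 1) %% R + 1`.
#'
#' @param flatIndex 1-based feature index (vectorized).
#' @param numRoi number of ROIs.
#' @inheritParams flattenConnectivity
#' @return A 2-column integer matrix of (i, j) ROI indices with `i <= j`
#'   for the upper-triangle layout.
#' @export
#' @examples
#' indexToPair(4, numRoi = 4)                   # (2, 3)
#' indexToPair(118, 116, "full_square")         # (2, 2)
indexToPair <- function(flatIndex, numRoi,
                        layout = c("upper_triangle", "full_square")) {
  layout <- match.arg(layout)
  flatIndex <- as.integer(flatIndex)
  maxLen <- if (layout == "full_square") numRoi^2 else numRoi * (numRoi - 1) / 2
  if (any(flatIndex < 1L) || any(flatIndex > maxLen))
    muscnetError(sprintf("feature index out of range 1..%d", maxLen),
                 "muscnet_input_error")
  if (layout == "full_square") {
    i <- (flatIndex - 1L) %/% numRoi + 1L
    j <- (flatIndex - 1L) %% numRoi + 1L
  } else {
    # row i (1-based) starts after (i-1)*numRoi - i*(i+1)/2 pairs
    k <- flatIndex
    i <- integer(length(k))
    j <- integer(length(k))
    for (u in seq_along(k)) {
      ii <- 1L
      offset <- 0L
      while (k[u] > offset + (numRoi - ii)) {
        offset <- offset + (numRoi - ii)
        ii <- ii + 1L
      }
      i[u] <- ii
      j[u] <- ii + (k[u] - offset)
    }
  }
  cbind(i = i, j = j)
}

#' Flattened feature index of an ROI pair
#'
#' Inverse of [indexToPair()] (for the upper-triangle layout the pair is
#' sorted so `i < j` first).
#'
#' @param i,j ROI indices (vectorized).
#' @inheritParams indexToPair
#' @return Integer feature indices.
#' @export
pairToIndex <- function(i, j, numRoi,
                        layout = c("upper_triangle", "full_square")) {
  layout <- match.arg(layout)
  if (layout == "full_square") return(as.integer((i - 1L) * numRoi + j))
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  if (any(lo == hi))
    muscnetError("upper-triangle features have i != j", "muscnet_input_error")
  as.integer((lo - 1L) * numRoi - (lo * (lo + 1L)) %/% 2L + hi)
}

#' Selection-frequency table of features and ROIs across LOOCV folds
#'
#' Counts, for one metric's per-fold selections of an evaluation, how often
#' each feature (edge) was selected across the folds, and aggregates
#' counts to ROIs by crediting both endpoints of each selected edge, the
#' declared convention for ranking ROIs by selection frequency.  Feature
#' ranks break frequency ties by ascending feature index.
#'
#' @param eval an [EvaluationResult-class].
#' @param roiLabels character vector of ROI names.
#' @param metric which metric's selections to count (name or index into
#'   the per-fold selection lists; default the first).
#' @param layout feature layout used when the features were built.
#' @return A list of class `FrequencyTable`: `features` (data.frame with
#'   feature index, ROI indices and labels, count, rank), `rois`
#'   (data.frame with ROI index, label, aggregate count), `nFolds`,
#'   `layout`, `metric`.
#' @export
frequencyTable <- function(eval, roiLabels, metric = 1L,
                           layout = c("upper_triangle", "full_square")) {
  stopifnot(is(eval, "EvaluationResult"))
  layout <- match.arg(layout)
  numRoi <- length(roiLabels)
  nFeat <- if (layout == "full_square") numRoi^2 else numRoi * (numRoi - 1) / 2
  folds <- eval@perFoldSelected
  counts <- integer(nFeat)
  for (f in folds) {
    sel <- f[[metric]]
    counts[sel] <- counts[sel] + 1L
  }
  pairs <- indexToPair(seq_len(nFeat), numRoi, layout)
  roiCounts <- integer(numRoi)
  for (k in which(counts > 0L)) {
    roiCounts[pairs[k, 1L]] <- roiCounts[pairs[k, 1L]] + counts[k]
    roiCounts[pairs[k, 2L]] <- roiCounts[pairs[k, 2L]] + counts[k]
  }
  featDf <- data.frame(
    feature = seq_len(nFeat),
    roiI = pairs[, 1L], roiJ = pairs[, 2L],
    labelI = roiLabels[pairs[, 1L]], labelJ = roiLabels[pairs[, 2L]],
    count = counts
  )
  featDf <- featDf[order(-featDf$count, featDf$feature), ]
  featDf$rank <- seq_len(nrow(featDf))
  roiDf <- data.frame(roi = seq_len(numRoi), label = roiLabels,
                      count = roiCounts)
  roiDf <- roiDf[order(-roiDf$count, roiDf$roi), ]
  structure(
    list(features = featDf, rois = roiDf, nFolds = length(folds),
         layout = layout,
         metric = if (is.numeric(metric)) names(folds[[1L]])[metric] else metric),
    class = "FrequencyTable"
  )
}

#' Compare the top-k most frequently selected features of two models
#'
#' Partitions each model's top-k features (by selection frequency, ties by
#' ascending index) into the shared set and each side's exclusive set, and
#' annotates every exclusive feature with its rank in the other model's
#' table -- the shared / also-in-other / only-in-this three-way view.
#'
#' @param tableA,tableB `FrequencyTable` objects over the same feature
#'   space.
#' @param k number of top features to compare (must not exceed the feature
#'   count).
#' @return A list of class `TopKOverlap`: `k`, `shared` (feature indices in
#'   both top-k sets), `onlyA`, `onlyB` (data.frames of exclusive features
#'   with their rank in the other table), `overlap` (size of `shared`).
#' @export
topKOverlap <- function(tableA, tableB, k) {
  stopifnot(inherits(tableA, "FrequencyTable"),
            inherits(tableB, "FrequencyTable"))
  nFeat <- nrow(tableA$features)
  if (k > nFeat)
    muscnetError(sprintf("k = %d exceeds the %d available features", k, nFeat),
                 "muscnet_input_error")
  topA <- tableA$features$feature[seq_len(k)]
  topB <- tableB$features$feature[seq_len(k)]
  shared <- intersect(topA, topB)
  rankIn <- function(feat, tab)
    tab$features$rank[match(feat, tab$features$feature)]
  onlyA <- setdiff(topA, topB)
  onlyB <- setdiff(topB, topA)
  structure(
    list(k = k, shared = shared, overlap = length(shared),
         onlyA = data.frame(feature = onlyA, rankInOther = rankIn(onlyA, tableB)),
         onlyB = data.frame(feature = onlyB, rankInOther = rankIn(onlyB, tableA))),
    class = "TopKOverlap"
  )
}

#' Bar chart of a model's top-k features against another model's top-k
#'
#' Mirrors the three-colour comparison view: red bars are the model's own
#' top-k features, drawn blue when the feature is also in the other
#' model's top-k and green when it is not.
#'
#' @inheritParams topKOverlap
#' @param main plot title.
#' @return Invisibly, the plotted data.frame.
#' @export
plotTopFeatures <- function(tableA, tableB, k = 10, main = NULL) {
  ov <- topKOverlap(tableA, tableB, k)
  top <- tableA$features[seq_len(k), ]
  col <- ifelse(top$feature %in% ov$shared, "steelblue", "seagreen")
  graphics::barplot(top$count,
                    names.arg = paste0(top$labelI, "-", top$labelJ),
                    col = col, las = 2, cex.names = 0.7,
                    ylab = "selection frequency",
                    main = if (is.null(main)) tableA$metric else main)
  graphics::legend("topright", fill = c("steelblue", "seagreen"),
                   legend = c("shared top-k", "exclusive"), bty = "n")
  invisible(top)
}

#' Write a frequency table as delimited text plus a JSON summary
#'
#' @param table a `FrequencyTable`.
#' @param path base output path; writes `<path>.tsv` (feature table) and
#'   `<path>.json` (ROI aggregate + metadata).
#' @return The TSV path, invisibly.
#' @export
writeFrequencyTable <- function(table, path) {
  tsv <- paste0(path, ".tsv")
  write.table(table$features, tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(
    list(metric = table$metric, nFolds = table$nFolds, layout = table$layout,
         rois = table$rois),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(tsv)
}
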