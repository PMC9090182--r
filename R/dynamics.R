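#' Sliding-window segment count
#'
#' Number of full-length sliding windows of `windowSize` volumes advancing
#' by `windowStep` over a series of `numVolume` volumes:
#' `floor((numVolume - windowSize) / windowStep) + 1`.  Trailing volumes
#' that do not fill a window are dropped, never padded.
#'
#' @param numVolume total number of volumes.
#' @param windowSize window length in volumes.
#' @param windowStep distance between successive window starts, in volumes;
#'   `1 <= windowStep <= windowSize <= numVolume`.
#' @return Integer number of windows (>= 1).
#' @export
#' @examples
#' numWindows(137, 50, 8)  # 11
numWindows <- function(numVolume, windowSize, windowStep) {
  checkWindowConfig(numVolume, windowSize, windowStep)
  as.integer((numVolume - windowSize) %/% windowStep + 1L)
}

checkWindowConfig <- function(numVolume, windowSize, windowStep) {
  if (!(windowStep >= 1 && windowStep <= windowSize))
    muscnetError("window step must satisfy 1 <= step <= size",
                 "muscnet_input_error")
  if (windowSize > numVolume)
    muscnetError(sprintf("window size %d exceeds the %d available volumes",
                         windowSize, numVolume), "muscnet_input_error")
  invisible(TRUE)
}

#' Extract sliding-window segments from a subject's time series
#'
#' Window `k` (1-based) covers the half-open volume range
#' `[(k - 1) * windowStep + 1, (k - 1) * windowStep + windowSize]` in
#' 1-based column indices; exactly [numWindows()] segments are returned.
#'
#' @param x numeric ROI x volume matrix.
#' @inheritParams numWindows
#' @return A list of ROI x `windowSize` matrices.
#' @export
extractWindows <- function(x, windowSize, windowStep) {
  stopifnot(is.matrix(x))
  k <- numWindows(ncol(x), windowSize, windowStep)
  lapply(seq_len(k), function(w) {
    start <- (w - 1L) * windowStep + 1L
    x[, start:(start + windowSize - 1L), drop = FALSE]
  })
}

#' Dynamic BFCN: sliding-window averaged connectivity
#'
#' Computes one [staticBFCN()] per sliding-window segment and returns their
#' element-wise arithmetic mean (averaging the temporal correlation squares
#' directly, with no transformation in between).  With
#' `windowSize = nVolumes` this reduces exactly to the static BFCN.
#'
#' @inheritParams staticBFCN
#' @inheritParams numWindows
#' @return A [ConnectivityMatrix-class].
#' @details An undefined correlation inside any window is an error naming
#'   the window index and ROI pair.
#' @export
#' @examples
#' ts <- matrix(rnorm(4 * 60), nrow = 4)
#' dynamicBFCN(ts, "PCC", windowSize = 30, windowStep = 10)
dynamicBFCN <- function(x, metric = "PCC", windowSize, windowStep,
                        params = NULL, subject = 1L) {
  if (is(x, "BoldCohort")) {
    labs <- roiLabels(x)
    x <- signals(x)[[subject]]
    rownames(x) <- labs
  }
  segs <- extractWindows(x, windowSize, windowStep)
  acc <- NULL
  cmLast <- NULL
  for (w in seq_along(segs)) {
    cmLast <- tryCatch(
      staticBFCN(segs[[w]], metric, params = params),
      muscnet_undefined_metric = function(e) {
        muscnetError(sprintf("window %d: %s", w, conditionMessage(e)),
                     "muscnet_undefined_metric", window = w)
      })
    acc <- if (is.null(acc)) cmLast@values else acc + cmLast@values
  }
  new("ConnectivityMatrix", metric = metric,
      values = acc / length(segs), roiLabels = cmLast@roiLabels)
}
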