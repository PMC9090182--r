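## Delimited-text readers/writers and the pipeline orchestrator.
## Time-series dialect: tab-separated, ROIs as rows, volumes as columns,
## first column = ROI label, no header.  Manifest: TSV with columns
## subject_id, path, label, preceded by a format-version comment line.

manifestVersion <- "1"

#' Write one subject's time series as tab-separated text
#'
#' @param x ROI x volume numeric matrix (row names used as ROI labels).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTimeSeries <- function(x, path) {
  stopifnot(is.matrix(x), is.numeric(x))
  labs <- rownames(x)
  if (is.null(labs)) labs <- paste0("ROI", seq_len(nrow(x)))
  # 17 significant digits: doubles survive the text round trip exactly
  chr <- matrix(sprintf("%.17g", x), nrow(x))
  write.table(cbind(labs, chr), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeTimeSeries
#' @export
readTimeSeries <- function(path) {
  if (!file.exists(path))
    muscnetError(sprintf("time-series file not found: %s", path),
                 "muscnet_io_error")
  df <- tryCatch(
    read.table(path, sep = "\t", header = FALSE, colClasses = NA,
               stringsAsFactors = FALSE),
    error = function(e)
      muscnetError(sprintf("ragged or unreadable time-series file %s: %s",
                           path, conditionMessage(e)), "muscnet_io_error"))
  labelled <- is.character(df[[1L]])
  labs <- if (labelled) df[[1L]] else paste0("ROI", seq_len(nrow(df)))
  num <- if (labelled) df[, -1L, drop = FALSE] else df
  if (!all(vapply(num, is.numeric, logical(1L))))
    muscnetError(sprintf("non-numeric cell in time-series file %s", path),
                 "muscnet_io_error")
  m <- as.matrix(num)
  dimnames(m) <- list(labs, NULL)
  m
}

#' Write a cohort to per-subject files plus a manifest
#'
#' Each subject goes to `<dir>/<subject_id>.tsv` via [writeTimeSeries()];
#' the manifest `<dir>/manifest.tsv` lists subject_id, path (relative to
#' the manifest) and label, under a format-version header line.
#'
#' @param cohort a [BoldCohort-class].
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "BoldCohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- subjectIds(cohort)
  sig <- signals(cohort)
  for (s in seq_along(ids)) {
    m <- sig[[s]]
    rownames(m) <- roiLabels(cohort)
    writeTimeSeries(m, file.path(dir, paste0(ids[s], ".tsv")))
  }
  manifest <- file.path(dir, "manifest.tsv")
  con <- file(manifest, "w")
  writeLines(sprintf("# muscnet_manifest_version=%s", manifestVersion), con)
  df <- data.frame(subject_id = ids, path = paste0(ids, ".tsv"),
                   label = as.character(labels(cohort)))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(manifest)
}

#' Read a cohort from a manifest of per-subject time-series files
#'
#' All subjects must share an identical ROI x volume shape and identical
#' ROI labels; violations are rejected naming the offending subject.
#'
#' @param manifest path to a manifest written by [writeCohort()] (or of
#'   the same dialect).
#' @return A [BoldCohort-class].
#' @export
readCohort <- function(manifest) {
  if (!file.exists(manifest))
    muscnetError(sprintf("manifest not found: %s", manifest),
                 "muscnet_io_error")
  lines <- readLines(manifest)
  body <- lines[!startsWith(lines, "#")]
  df <- read.table(text = body, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  need <- c("subject_id", "path", "label")
  if (!all(need %in% names(df)))
    muscnetError("manifest must have columns subject_id, path, label",
                 "muscnet_io_error")
  if (anyDuplicated(df$subject_id))
    muscnetError("duplicate subject_id in manifest", "muscnet_io_error")
  bad <- setdiff(unique(df$label), c("MCI", "NC"))
  if (length(bad))
    muscnetError(sprintf("unknown label(s) in manifest: %s",
                         paste(bad, collapse = ", ")), "muscnet_io_error")
  base <- dirname(manifest)
  sig <- vector("list", nrow(df))
  refDim <- NULL
  refLabs <- NULL
  for (s in seq_len(nrow(df))) {
    p <- file.path(base, df$path[s])
    if (!file.exists(p)) p <- df$path[s]
    m <- readTimeSeries(p)
    if (is.null(refDim)) {
      refDim <- dim(m)
      refLabs <- rownames(m)
    } else if (!identical(dim(m), refDim)) {
      muscnetError(
        sprintf("subject '%s' has shape %dx%d, expected %dx%d",
                df$subject_id[s], nrow(m), ncol(m), refDim[1L], refDim[2L]),
        "muscnet_io_error")
    } else if (!identical(rownames(m), refLabs)) {
      muscnetError(sprintf("subject '%s' has mismatching ROI labels",
                           df$subject_id[s]), "muscnet_io_error")
    }
    sig[[s]] <- unname(m)
  }
  new("BoldCohort",
      signals = sig, subjectIds = df$subject_id,
      labels = factor(df$label, levels = c("NC", "MCI")),
      roiLabels = refLabs, groundTruth = list())
}

#' Serialize an EvaluationResult to a JSON-ready list
#'
#' @param eval an [EvaluationResult-class].
#' @param alphaTable optional data.frame from [alphaGrid()] to embed.
#' @return A list matching the shipped evaluation schema
#'   (`system.file("schema", "evaluation.schema.json", package =
#'   "muscnet")`).
#' @export
evaluationToJson <- function(eval, alphaTable = NULL) {
  stopifnot(is(eval, "EvaluationResult"))
  out <- list(
    config = eval@config,
    counts = as.list(eval@counts),
    metrics = as.list(eval@metrics),
    predictions = eval@predictions,
    truth = eval@truth,
    scores = eval@scores,
    perFoldSelected = lapply(eval@perFoldSelected,
                             function(f) lapply(f, as.integer))
  )
  if (!is.null(alphaTable)) out$alphaTable <- alphaTable
  out
}

#' Validate an evaluation JSON document against the shipped schema
#'
#' Checks the required top-level keys and elementary types declared in the
#' schema shipped with the package.
#'
#' @param x a list (parsed JSON) or a path to a JSON file.
#' @return `TRUE` invisibly, or an error describing the first violation.
#' @export
validateEvaluationJson <- function(x) {
  if (is.character(x)) x <- jsonlite::read_json(x, simplifyVector = FALSE)
  schema <- jsonlite::read_json(
    system.file("schema", "evaluation.schema.json", package = "muscnet"),
    simplifyVector = FALSE)
  for (key in unlist(schema$required)) {
    if (is.null(x[[key]]))
      muscnetError(sprintf("evaluation JSON misses required key '%s'", key),
                   "muscnet_io_error")
  }
  for (key in c("TP", "FN", "TN", "FP")) {
    if (is.null(x$counts[[key]]))
      muscnetError(sprintf("counts misses '%s'", key), "muscnet_io_error")
  }
  for (key in c("Acc", "Sn", "Sp")) {
    v <- x$metrics[[key]]
    if (is.null(v) || !is.numeric(v) || v < 0 || v > 1)
      muscnetError(sprintf("metrics.%s must be a number in [0, 1]", key),
                   "muscnet_io_error")
  }
  invisible(TRUE)
}

#' Read a pipeline run configuration
#'
#' YAML with the keys `cohort` (either `manifest: <path>` or `simulate:`
#' with [cohortSpec()] fields), `metrics` (1-2 metric names, or more to
#' sweep all duets), `window` (`size`, `step`; omit for static), `filter`
#' (`method`, `threshold`), `alpha` (fixed weight; omit for the 0.1-0.9
#' sweep), `protocol` (`"loocv"` or `"nested"`), `nested` (`thresholds`,
#' `alphas`), `cost`, `layout`, `mic` (`alphaExponent`, `clumpFactor`).
#'
#' @param path YAML file.
#' @return The configuration list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  validateRunConfig(cfg)
}

validateRunConfig <- function(cfg) {
  if (is.null(cfg$cohort) ||
      (is.null(cfg$cohort$manifest) && is.null(cfg$cohort$simulate)))
    muscnetError("config needs cohort$manifest or cohort$simulate",
                 "muscnet_config_error")
  cfg$metrics <- if (is.null(cfg$metrics)) c("PCC", "MIC")
                 else unlist(cfg$metrics)
  bad <- setdiff(cfg$metrics, connectivityMetrics())
  if (length(bad))
    muscnetError(sprintf("unknown metric(s): %s", paste(bad, collapse = ", ")),
                 "muscnet_config_error")
  if (is.null(cfg$filter)) cfg$filter <- list(method = "Ttest", threshold = 0.05)
  cfg$filter$method <- match.arg(cfg$filter$method, c("Ttest", "Wtest", "KStest"))
  if (is.null(cfg$filter$threshold)) cfg$filter$threshold <- 0.05
  if (is.null(cfg$cost)) cfg$cost <- 1
  if (is.null(cfg$layout)) cfg$layout <- "upper_triangle"
  if (is.null(cfg$protocol)) cfg$protocol <- "loocv"
  cfg$protocol <- match.arg(cfg$protocol, c("loocv", "nested"))
  cfg
}

#' Run the full pipeline from a configuration
#'
#' Loads or simulates the cohort, validates the window configuration
#' before any heavy compute, builds per-metric dynamic (or static) BFCN
#' feature matrices, evaluates every metric duet (or the single metric)
#' under the requested protocol, and -- when `outputDir` is given --
#' writes one evaluation JSON per duet plus a provenance record (config
#' hash, seed, package and R versions).
#'
#' @param config a configuration list (see [readRunConfig()]) or a path
#'   to a YAML file.
#' @param outputDir optional directory for JSON artifacts.
#' @return A list with one element per evaluated model: for duets under
#'   `protocol = "loocv"`, the [alphaGrid()] sweep (`table`, `results`,
#'   `best`); otherwise a single [EvaluationResult-class].
#' @export
runPipeline <- function(config, outputDir = NULL) {
  if (is.character(config)) config <- readRunConfig(config)
  else config <- validateRunConfig(config)
  cohort <- if (!is.null(config$cohort$manifest)) {
    readCohort(config$cohort$manifest)
  } else {
    generateCohort(do.call(cohortSpec, config$cohort$simulate))
  }
  if (!is.null(config$window)) {
    checkWindowConfig(nVolumes(cohort), config$window$size,
                      config$window$step)
  }
  micP <- if (is.null(config$mic)) micParams()
          else do.call(micParams, config$mic)
  feats <- lapply(stats::setNames(config$metrics, config$metrics), function(m)
    cohortFeatures(cohort, m,
                   windowSize = config$window$size,
                   windowStep = if (is.null(config$window$step)) 1L
                                else config$window$step,
                   layout = config$layout, params = micP))
  y <- labels(cohort)
  duets <- if (length(config$metrics) == 1L) {
    list(config$metrics)
  } else {
    pairs <- utils::combn(config$metrics, 2L, simplify = FALSE)
    pairs
  }
  out <- list()
  for (d in duets) {
    key <- paste(d, collapse = "&")
    fl <- feats[d]
    res <- if (config$protocol == "nested") {
      nestedLoocv(fl, y, filter = config$filter$method,
                  thresholds = if (is.null(config$nested$thresholds))
                    config$filter$threshold else unlist(config$nested$thresholds),
                  alphas = if (is.null(config$nested$alphas))
                    seq(0.1, 0.9, by = 0.1) else unlist(config$nested$alphas),
                  cost = config$cost)
    } else if (length(d) == 2L && is.null(config$alpha)) {
      alphaGrid(fl, y, filter = config$filter$method,
                threshold = config$filter$threshold, cost = config$cost)
    } else {
      loocv(fl, y, filter = config$filter$method,
            threshold = config$filter$threshold,
            alpha = if (is.null(config$alpha)) 0.5 else config$alpha,
            cost = config$cost)
    }
    out[[key]] <- res
    if (!is.null(outputDir)) {
      dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
      doc <- if (is(res, "EvaluationResult")) evaluationToJson(res)
             else evaluationToJson(res$best, alphaTable = res$table)
      doc$provenance <- provenanceRecord(config)
      jsonlite::write_json(
        doc, file.path(outputDir, paste0(gsub("&", "_", key), ".json")),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  }
  out
}

provenanceRecord <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  list(configHash = unname(tools::md5sum(tmp)),
       seed = config$cohort$simulate$seed,
       package = as.character(utils::packageVersion("muscnet")),
       rVersion = as.character(getRversion()),
       timestampUtc = format(Sys.time(), tz = "UTC",
                             "%Y-%m-%dT%H:%M:%SZ"))
}
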