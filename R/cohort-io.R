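# Flat-table and CSV interchange for cohort objects, plus show methods.

#' @describeIn cohortTable flatten an `FTDCohort`.
#' @export
setMethod("cohortTable", "FTDCohort", function(x) {
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  vals <- t(SummarizedExperiment::assay(x, "values"))
  out <- cbind(cd, as.data.frame(vals))
  rownames(out) <- NULL
  out
})

#' Write a cohort to CSV
#'
#' One row per subject-visit; missing values are written as empty fields.
#'
#' @param cohort an [FTDCohort-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeCohortCsv <- function(cohort, path) {
  utils::write.csv(cohortTable(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a cohort CSV back into an FTDCohort
#'
#' Columns are split into the demographic/clinical schema and biomarker
#' columns using the marker manifest; unknown numeric columns are treated as
#' additional biomarkers with direction/transform taken from `markers` when
#' available.
#'
#' @param path CSV file written by [writeCohortCsv()] (or any file with the
#'   same schema).
#' @param markers manifest giving `name`, `direction`, `transform` per
#'   biomarker; defaults to [markerManifest()].
#' @return an [FTDCohort-class].
#' @export
readCohortCsv <- function(path, markers = markerManifest()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  missing_cols <- setdiff(DEMOGRAPHIC_COLS, colnames(df))
  if (length(missing_cols)) {
    ftdStop("ftdSchemaError", sprintf(
      "input is missing required columns: %s", paste(missing_cols, collapse = ", ")
    ))
  }
  marker_cols <- intersect(markers$name, colnames(df))
  if (!length(marker_cols)) ftdStop("ftdSchemaError", "no biomarker columns found")
  meta_cols <- setdiff(colnames(df), marker_cols)
  vals <- t(as.matrix(df[, marker_cols, drop = FALSE]))
  mk <- markers[match(marker_cols, markers$name), ]
  rd <- S4Vectors::DataFrame(
    direction = mk$direction, transform = mk$transform, row.names = marker_cols
  )
  cd <- S4Vectors::DataFrame(df[, meta_cols, drop = FALSE])
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(values = vals), colData = cd, rowData = rd
  )
  visit <- ave(df$visit_time, df$subject_id, FUN = function(t) rank(t, ties.method = "first") - 1)
  colnames(se) <- sprintf("%s_v%d", df$subject_id, as.integer(visit))
  methods::new("FTDCohort", se)
}

setMethod("show", "FTDCohort", function(object) {
  cd <- SummarizedExperiment::colData(object)
  nsubj <- length(unique(cd$subject_id))
  cat(sprintf(
    "FTDCohort: %d biomarkers x %d subject-visits (%d subjects)\n",
    nrow(object), ncol(object), nsubj
  ))
  tab <- table(cd$genotype[cd$visit_time == 0], cd$status[cd$visit_time == 0])
  print(tab)
  gt <- S4Vectors::metadata(object)$groundTruth
  if (!is.null(gt)) {
    cat("ground truth:", paste(gt, collapse = " > "), "\n")
  }
  invisible(NULL)
})

setMethod("show", "NormativeModel", function(object) {
  cat(sprintf(
    "NormativeModel (%s): log10(WMH) = %.4f + %.4f*age + %.4f*male  [sd %.4f, n=%d controls]\n",
    object@region, object@intercept, object@ageCoefficient,
    object@sexCoefficient, object@residualSd, object@nControls
  ))
  invisible(NULL)
})

setMethod("show", "BiomarkerGMM", function(object) {
  cat(sprintf(
    "BiomarkerGMM '%s' (%s): normal N(%.3f, %.3f), abnormal N(%.3f, %.3f)\n",
    object@marker, object@direction, object@normalMean, object@normalSd,
    object@abnormalMean, object@abnormalSd
  ))
  cat(sprintf(
    "  mixing: %s | mse %.2e | screen p %.3g | %s%s\n",
    paste(sprintf("%s=%.2f", names(object@mixing), object@mixing), collapse = " "),
    object@mse, object@screenP,
    if (object@admitted) "admitted" else "not admitted",
    if (!object@admitted && nzchar(object@reason)) paste0(" (", object@reason, ")") else ""
  ))
  invisible(NULL)
})

setMethod("show", "EventOrdering", function(object) {
  cat(sprintf("EventOrdering (%s):\n  %s\n", object@method,
              paste(object@ordering, collapse = " > ")))
  if (!is.na(object@cost)) cat(sprintf("  cost: %.4f\n", object@cost))
  invisible(NULL)
})

setMethod("show", "PositionalVariance", function(object) {
  cat(sprintf("PositionalVariance: %d biomarkers, B = %d bootstrap replicates\n",
              nrow(object@counts), object@B))
  print(object@counts)
  invisible(NULL)
})

setMethod("show", "DEBMFit", function(object) {
  cat("DEBMFit\n")
  cat(sprintf("  admitted biomarkers: %d of %d screened\n",
              ncol(object@probabilities), length(object@fits)))
  cat("  ordering:", paste(object@ordering@ordering, collapse = " > "), "\n")
  if (length(object@auc)) {
    cat(sprintf("  staging AUC (10-fold CV): %.3f +/- %.3f\n",
                object@auc[["mean"]], object@auc[["sd"]]))
  }
  invisible(NULL)
})

#' @describeIn eventSequence sequence of an ordering.
#' @export
setMethod("eventSequence", "EventOrdering", function(x) x@ordering)

#' @describeIn eventSequence central ordering of a positional-variance
#'   diagram.
#' @export
setMethod("eventSequence", "PositionalVariance", function(x) x@ordering)

#' @describeIn eventSequence central ordering of a fitted model.
#' @export
setMethod("eventSequence", "DEBMFit", function(x) x@ordering@ordering)

#' @describeIn positionCounts counts of a positional-variance diagram.
#' @export
setMethod("positionCounts", "PositionalVariance", function(x) x@counts)

#' @describeIn positionCounts counts stored in a fitted model.
#' @export
setMethod("positionCounts", "DEBMFit", function(x) {
  if (is.null(x@positional)) NULL else x@positional@counts
})

#' @describeIn admittedMarkers admitted biomarkers of a fitted model.
#' @export
setMethod("admittedMarkers", "DEBMFit", function(x) colnames(x@probabilities))

#' @describeIn stageTable stage table of a fitted model.
#' @export
setMethod("stageTable", "DEBMFit", function(x) x@stages)
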