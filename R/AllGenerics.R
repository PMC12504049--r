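#' Extract the event sequence from an ordering-like object
#'
#' @param x an [EventOrdering-class], [PositionalVariance-class] or
#'   [DEBMFit-class] object.
#' @return character vector of biomarker names, earliest event first.
#' @export
setGeneric("eventSequence", function(x) standardGeneric("eventSequence"))

#' Bootstrap position counts
#'
#' @param x a [PositionalVariance-class] or [DEBMFit-class] object.
#' @return K x K count matrix; rows follow the central ordering, columns are
#'   sequence positions.
#' @export
setGeneric("positionCounts", function(x) standardGeneric("positionCounts"))

#' Names of biomarkers admitted to the event-based model
#'
#' @param x a [DEBMFit-class] object.
#' @export
setGeneric("admittedMarkers", function(x) standardGeneric("admittedMarkers"))

#' Per-subject stage table
#'
#' @param x a [DEBMFit-class] object.
#' @return data frame with `subject_id`, discrete `stage` in 0..K and
#'   `continuous_stage` in \[0, 1\].
#' @export
setGeneric("stageTable", function(x) standardGeneric("stageTable"))

#' Ground-truth event ordering of a simulated cohort
#'
#' @param x a cohort configuration (from [cohortConfig()]) or a simulated
#'   [FTDCohort-class].
#' @return an [EventOrdering-class] with method `"ground_truth"`.
#' @export
setGeneric("groundTruthOrdering", function(x) standardGeneric("groundTruthOrdering"))

#' Flatten a cohort to one row per subject-visit
#'
#' @param x an [FTDCohort-class].
#' @return data.frame with demographics, clinical scores, latent stage (if
#'   simulated) and one column per biomarker. This is the CSV interchange
#'   schema used by [writeCohortCsv()].
#' @export
setGeneric("cohortTable", function(x) standardGeneric("cohortTable"))
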