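#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

GENOTYPES <- c("noncarrier", "C9orf72", "GRN", "MAPT")
STATUSES <- c("control", "presymptomatic", "symptomatic")
SEXES <- c("male", "female")

DEMOGRAPHIC_COLS <- c(
  "subject_id", "genotype", "status", "age", "sex", "education", "visit_time"
)

CLINICAL_SCORES <- c(
  "cdr_sob", "mmse", "tmt_b", "boston_naming", "digit_symbol", "verbal_fluency"
)

#' Cohort container for subject-visit biomarker data
#'
#' `FTDCohort` extends [SummarizedExperiment::SummarizedExperiment]: the assay
#' holds one biomarker per row and one subject-visit per column, `colData`
#' carries demographics, clinical scores and (for simulated cohorts) the
#' latent disease stage, and `rowData` carries each biomarker's abnormality
#' direction and transform. Simulated cohorts additionally store the
#' generating configuration and the ground-truth event ordering in
#' `metadata()`.
#'
#' @seealso [simulateCohort()], [cohortTable()], [readCohortCsv()]
#' @export
setClass("FTDCohort", contains = "SummarizedExperiment")

setValidity("FTDCohort", function(object) {
  cd <- SummarizedExperiment::colData(object)
  msgs <- character(0)
  need <- setdiff(DEMOGRAPHIC_COLS, colnames(cd))
  if (length(need)) {
    return(paste("missing colData columns:", paste(need, collapse = ", ")))
  }
  if (!all(cd$genotype %in% GENOTYPES)) msgs <- c(msgs, "unknown genotype label")
  if (!all(cd$status %in% STATUSES)) msgs <- c(msgs, "unknown status label")
  bad <- cd$genotype == "noncarrier" & cd$status != "control"
  if (any(bad)) msgs <- c(msgs, "noncarriers must have status 'control'")
  if (any(cd$visit_time < 0, na.rm = TRUE)) msgs <- c(msgs, "visit_time must be >= 0")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("direction", "transform") %in% colnames(rd))) {
    msgs <- c(msgs, "rowData must declare 'direction' and 'transform'")
  } else {
    if (!all(rd$direction %in% c("increase", "decrease"))) {
      msgs <- c(msgs, "direction must be 'increase' or 'decrease'")
    }
    if (!all(rd$transform %in% c("log10", "identity"))) {
      msgs <- c(msgs, "transform must be 'log10' or 'identity'")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Normative regression of log lesion volume on demographics
#'
#' Ordinary least squares fit of log10 WMH volume on age and sex, estimated on
#' healthy controls only. Adjusted WMH values are observed minus predicted.
#'
#' @slot intercept,ageCoefficient,sexCoefficient OLS coefficients; the sex
#'   coefficient is the male-vs-female contrast (0 when only one sex is
#'   present in the controls).
#' @slot residualSd residual standard deviation.
#' @slot nControls number of complete control records used.
#' @slot region region label the model was fitted for.
#' @export
setClass("NormativeModel", representation(
  intercept = "numeric",
  ageCoefficient = "numeric",
  sexCoefficient = "numeric",
  residualSd = "numeric",
  nControls = "integer",
  region = "character"
))

setValidity("NormativeModel", function(object) {
  if (length(object@residualSd) && object@residualSd < 0) "residualSd must be >= 0" else TRUE
})

#' Two-component biomarker mixture fit
#'
#' Constrained Gaussian mixture describing the normal and abnormal state of a
#' single biomarker, with per-diagnosis mixing fractions and a fit-quality
#' mean squared error against the empirical distribution.
#'
#' @slot marker biomarker name.
#' @slot direction `"increase"` or `"decrease"`: which side is abnormal.
#' @slot normalMean,normalSd,abnormalMean,abnormalSd component parameters.
#' @slot mixing named abnormal-component fraction per diagnosis label.
#' @slot mse mean squared error between mixture and empirical bin masses
#'   (50 bins).
#' @slot screenStatistic,screenP Mann-Whitney U comparison of symptomatic
#'   carriers versus controls.
#' @slot significant,admitted,converged logical flags; `admitted` requires a
#'   significant screen and `mse` below the admission threshold.
#' @slot logLik final observed-data log-likelihood.
#' @slot reason why a biomarker failed admission (empty when admitted).
#' @export
setClass("BiomarkerGMM", representation(
  marker = "character",
  direction = "character",
  normalMean = "numeric",
  normalSd = "numeric",
  abnormalMean = "numeric",
  abnormalSd = "numeric",
  mixing = "numeric",
  mse = "numeric",
  screenStatistic = "numeric",
  screenP = "numeric",
  significant = "logical",
  admitted = "logical",
  converged = "logical",
  logLik = "numeric",
  reason = "character"
))

setValidity("BiomarkerGMM", function(object) {
  msgs <- character(0)
  if (any(c(object@normalSd, object@abnormalSd) <= 0)) msgs <- c(msgs, "sds must be > 0")
  if (length(object@mixing) && any(object@mixing < 0 | object@mixing > 1)) {
    msgs <- c(msgs, "mixing fractions must lie in [0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' Central event ordering
#'
#' A permutation of the admitted biomarkers, together with the
#' probability-weighted Kendall cost it attains (sum over subjects of
#' `|P_ik - P_il|` across pairs discordant with the subject's posterior-sorted
#' ranking).
#'
#' @slot ordering biomarker names, earliest event first.
#' @slot cost aggregation cost of the ordering (NA for ground-truth objects).
#' @slot method `"exhaustive"`, `"greedy"` or `"ground_truth"`.
#' @export
setClass("EventOrdering", representation(
  ordering = "character",
  cost = "numeric",
  method = "character"
))

setValidity("EventOrdering", function(object) {
  if (anyDuplicated(object@ordering)) return("ordering must not contain duplicates")
  if (length(object@cost) && !is.na(object@cost) && object@cost < 0) return("cost must be >= 0")
  TRUE
})

#' Bootstrap positional-variance diagram
#'
#' Count matrix whose entry (k, j) is the number of bootstrap replicates that
#' placed biomarker k at position j of the estimated ordering. Every row and
#' every column sums to the number of replicates B.
#'
#' @slot counts K x K integer matrix, rows ordered by the central ordering.
#' @slot B number of bootstrap replicates.
#' @slot ordering the central ordering the rows follow.
#' @export
setClass("PositionalVariance", representation(
  counts = "matrix",
  B = "integer",
  ordering = "character"
))

setValidity("PositionalVariance", function(object) {
  cnt <- object@counts
  if (nrow(cnt) != ncol(cnt)) return("counts must be square")
  if (any(rowSums(cnt) != object@B) || any(colSums(cnt) != object@B)) {
    return("every row and column of counts must sum to B")
  }
  TRUE
})

#' Fitted discriminative event-based model
#'
#' Aggregate result of [runDEBM()]: per-biomarker mixture fits, the posterior
#' abnormality matrix, the central ordering, the bootstrap positional-variance
#' diagram, per-subject stages, and validation metrics.
#'
#' @slot fits named list of [BiomarkerGMM-class] objects (all screened
#'   biomarkers, admitted or not).
#' @slot probabilities subjects x K posterior abnormality matrix over the
#'   admitted biomarkers (NA where the biomarker is missing).
#' @slot ordering the central [EventOrdering-class].
#' @slot positional the bootstrap [PositionalVariance-class] (or NULL when
#'   `bootstrap = 0`).
#' @slot stages data frame of per-subject discrete and continuous stages.
#' @slot auc named numeric: mean and sd of the cross-validated staging AUC.
#' @slot clinical data frame of Spearman correlations between stage and
#'   clinical scores.
#' @slot excludedSubjects subjects dropped from ordering estimation because
#'   fewer than two biomarkers were observed.
#' @export
setClass("DEBMFit", representation(
  fits = "list",
  probabilities = "matrix",
  ordering = "EventOrdering",
  positional = "ANY",
  stages = "data.frame",
  auc = "numeric",
  clinical = "data.frame",
  excludedSubjects = "integer"
))
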