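# Normative adjustment of WMH volumes: log10 volume regressed on age and sex
# in healthy controls; everyone's adjusted value is observed minus predicted.

WMH_REGIONS <- c(
  "total", "lh_frontal", "rh_frontal", "lh_temporal", "rh_temporal",
  "lh_parietal", "rh_parietal", "lh_occipital", "rh_occipital"
)

wmhColumn <- function(region) {
  if (!region %in% WMH_REGIONS) {
    ftdStop("ftdConfigError", sprintf(
      "unknown WMH region '%s'; expected one of: %s",
      region, paste(WMH_REGIONS, collapse = ", ")
    ))
  }
  if (region == "total") "wmh_total" else paste0("wmh_", region)
}

#' Fit the normative WMH model on healthy controls
#'
#' Ordinary least squares of log10 WMH volume on age and sex. The caller
#' supplies control records only; records with missing age, sex or volume are
#' dropped. When a single sex is present the sex contrast is not estimable
#' and is reported as 0; constant age is a rank-deficiency error.
#'
#' @param logWmh numeric vector of log10 WMH volumes (mm^3).
#' @param age numeric vector of ages in years.
#' @param sex character vector, `"male"`/`"female"`.
#' @param region region label stored on the model.
#' @return a [NormativeModel-class].
#' @examples
#' m <- fitNormativeModel(c(3.0, 3.5, 4.0), c(40, 50, 60), rep("female", 3))
#' m@ageCoefficient  # 0.05
#' @export
fitNormativeModel <- function(logWmh, age, sex, region = "total") {
  keep <- stats::complete.cases(logWmh, age, sex)
  logWmh <- logWmh[keep]; age <- age[keep]; sex <- sex[keep]
  if (length(logWmh) < 3L) {
    ftdStop("ftdInsufficientDataError",
            "need at least 3 complete control records to fit the normative model")
  }
  if (!all(sex %in% SEXES)) {
    ftdStop("ftdConfigError", "sex must be coded 'male'/'female'")
  }
  if (stats::var(age) == 0) {
    ftdStop("ftdRankDeficiencyError",
            "normative model is rank-deficient: 'age' is constant",
            data = list(term = "age"))
  }
  male <- as.numeric(sex == "male")
  bothSexes <- length(unique(male)) == 2L
  fit <- if (bothSexes) stats::lm(logWmh ~ age + male) else stats::lm(logWmh ~ age)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    ftdStop("ftdRankDeficiencyError", sprintf(
      "normative model is rank-deficient: collinear term '%s'",
      paste(names(cf)[is.na(cf)], collapse = ", ")
    ), data = list(term = names(cf)[is.na(cf)]))
  }
  res <- stats::resid(fit)
  rsd <- if (fit$df.residual > 0) sqrt(sum(res^2) / fit$df.residual) else 0
  methods::new(
    "NormativeModel",
    intercept = unname(cf[["(Intercept)"]]),
    ageCoefficient = unname(cf[["age"]]),
    sexCoefficient = if (bothSexes) unname(cf[["male"]]) else 0,
    residualSd = rsd,
    nControls = length(logWmh),
    region = region
  )
}

predictNormative <- function(model, age, sex) {
  model@intercept + model@ageCoefficient * age +
    model@sexCoefficient * as.numeric(sex == "male")
}

#' Age/sex-adjusted WMH values
#'
#' Computes, for every eligible subject-visit, the difference between the
#' observed log10 WMH volume and the normative model's prediction. Records
#' with missing age or sex cannot be adjusted and are excluded (the count is
#' attached as attribute `"excluded"` and logged); a non-positive WMH volume
#' is a value error naming the record.
#'
#' @param cohort an [FTDCohort-class] or the flat data.frame from
#'   [cohortTable()].
#' @param model a [NormativeModel-class] from [fitNormativeModel()].
#' @param region one of `"total"` or the eight `lh_`/`rh_` lobes.
#' @return data.frame with `subject_id`, `genotype`, `status`, `region`,
#'   `adjusted`; attribute `"excluded"` counts dropped records.
#' @export
adjustWmh <- function(cohort, model, region = "total") {
  df <- if (methods::is(cohort, "FTDCohort")) cohortTable(cohort) else cohort
  col <- wmhColumn(region)
  if (!col %in% colnames(df)) {
    ftdStop("ftdSchemaError", sprintf("cohort has no column '%s'", col))
  }
  observed <- !is.na(df[[col]])
  bad <- observed & df[[col]] <= 0
  if (any(bad)) {
    ftdStop("ftdValueError", sprintf(
      "non-positive WMH volume for record(s): %s",
      paste(df$subject_id[bad], collapse = ", ")
    ))
  }
  eligible <- observed & !is.na(df$age) & !is.na(df$sex)
  excluded <- sum(observed & !eligible)
  if (excluded > 0) {
    ftdLog("adjustWmh(%s): %d record(s) excluded for missing demographics", region, excluded)
  }
  sub <- df[eligible, , drop = FALSE]
  out <- data.frame(
    subject_id = sub$subject_id,
    genotype = sub$genotype,
    status = sub$status,
    region = region,
    adjusted = log10(sub[[col]]) - predictNormative(model, sub$age, sub$sex),
    stringsAsFactors = FALSE
  )
  attr(out, "excluded") <- excluded
  out
}
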