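# Directional cross-lagged analysis: does baseline lesion load predict the
# rate of change of subcortical volumes (and vice versa)?

CROSSLAG_PREDICTORS <- c("wmh_total", "wmh_frontal", "wmh_temporal", "wmh_parietal")
CROSSLAG_RESPONSES <- c("insula", "basal_ganglia", "thalamus", "hippocampus",
                        "amygdala", "cingulate")

#' Annualized rate of change
#'
#' Per-subject OLS slope of a biomarker against visit time in years; with
#' exactly two visits this reduces to the difference quotient. Requires at
#' least two observed visits (otherwise NA).
#'
#' @param times visit times in years.
#' @param values biomarker values at those visits (already z-scored by the
#'   caller when used in the cross-lag model).
#' @return slope per year, or NA when fewer than two observations.
#' @examples
#' annualizedChange(c(0, 2), c(1.0, 0.5))     # -0.25
#' annualizedChange(c(0, 1, 2), c(0, 1, 2))   # 1
#' @export
annualizedChange <- function(times, values) {
  ok <- !is.na(times) & !is.na(values)
  if (sum(ok) < 2L) return(NA_real_)
  t <- times[ok]; v <- values[ok]
  if (stats::var(t) == 0) return(NA_real_)
  sum((t - mean(t)) * (v - mean(v))) / sum((t - mean(t))^2)
}

# z-scoring constants per biomarker over the analysis dataset at baseline;
# WMH and NfL are log10-transformed first.
zScoreConstants <- function(baseline, markers) {
  man <- markerManifest()
  lapply(stats::setNames(markers, markers), function(m) {
    tr <- man$transform[match(m, man$name)] %||% "identity"
    if (is.na(tr)) tr <- "identity"
    v <- transformValue(baseline[[m]], tr)
    c(mean = mean(v, na.rm = TRUE), sd = stats::sd(v, na.rm = TRUE), log = tr == "log10")
  })
}

zScoreValue <- function(v, const) {
  z <- if (const[["log"]] == 1) log10(v) else v
  (z - const[["mean"]]) / const[["sd"]]
}

#' Fit one cross-lagged pair model
#'
#' OLS of the response biomarker's annualized z-score rate on the z-scored
#' baseline predictor plus age, sex, education, log NfL (z-scored) and the
#' z-scored baseline value of the response. Returns the predictor
#' coefficient, its t statistic and two-sided p, and the number of complete
#' subjects.
#'
#' @param data data.frame with columns `rate`, `predictor_baseline`, `age`,
#'   `sex`, `education`, `nfl_z`, `response_baseline` (one row per subject).
#' @return one-row data.frame with `coefficient`, `t`, `p`, `n`.
#' @export
fitPairModel <- function(data) {
  need <- c("rate", "predictor_baseline", "age", "sex", "education",
            "nfl_z", "response_baseline")
  missing_cols <- setdiff(need, colnames(data))
  if (length(missing_cols)) {
    ftdStop("ftdSchemaError", sprintf(
      "pair-model data missing column(s): %s", paste(missing_cols, collapse = ", ")
    ))
  }
  data$male <- as.numeric(data$sex == "male")
  cc <- stats::complete.cases(data[, c(need[need != "sex"], "male")])
  data <- data[cc, , drop = FALSE]
  if (nrow(data) < 10L) {
    ftdStop("ftdInsufficientDataError", sprintf(
      "only %d complete subjects (need >= 10)", nrow(data)
    ))
  }
  fit <- stats::lm(rate ~ predictor_baseline + age + male + education +
                     nfl_z + response_baseline, data = data)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    ftdStop("ftdRankDeficiencyError", sprintf(
      "cross-lag model is rank-deficient: collinear term(s) %s",
      paste(names(cf)[is.na(cf)], collapse = ", ")
    ))
  }
  sm <- summary(fit)$coefficients
  data.frame(
    coefficient = sm["predictor_baseline", "Estimate"],
    t = sm["predictor_baseline", "t value"],
    p = sm["predictor_baseline", "Pr(>|t|)"],
    n = nrow(data)
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment via [stats::p.adjust()]; inputs
#' outside \[0, 1\] are an error.
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values, capped at 1.
#' @examples
#' fdrCorrect(c(0.006, 0.023, 0.025))  # 0.018 0.025 0.025
#' @export
fdrCorrect <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    ftdStop("ftdValueError", "p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Cross-lagged association matrix
#'
#' Fits [fitPairModel()] for every predictor-response pair in both
#' directions (by default the four WMH measures against the six subcortical
#' volumes: 48 models), applies one Benjamini-Hochberg family across all
#' pairs, and returns a tidy result table plus a chord-ready square t-matrix.
#'
#' @param cohort a longitudinal [FTDCohort-class] (or flat table) with at
#'   least two visits per subject.
#' @param predictors,responses biomarker name sets; each pair is fitted in
#'   both directions.
#' @param fdr significance threshold on the adjusted p (default 0.05).
#' @return list of class `crossLagResultSet` with elements `results` (one
#'   row per directed pair: `predictor`, `response`, `direction`, `n`,
#'   `coefficient`, `t`, `p_raw`, `p_fdr`, `significant`) and `tMatrix`
#'   (square matrix over all biomarkers; entry \[p, r\] is the t statistic of
#'   baseline p predicting the rate of r).
#' @export
crossLagMatrix <- function(cohort, predictors = CROSSLAG_PREDICTORS,
                           responses = CROSSLAG_RESPONSES, fdr = 0.05) {
  df <- if (methods::is(cohort, "FTDCohort")) cohortTable(cohort) else cohort
  all_markers <- union(predictors, responses)
  missing_cols <- setdiff(c(all_markers, "nfl"), colnames(df))
  if (length(missing_cols)) {
    ftdStop("ftdSchemaError", sprintf(
      "cohort lacks column(s): %s", paste(missing_cols, collapse = ", ")
    ))
  }
  baseline <- df[df$visit_time == 0, , drop = FALSE]
  consts <- zScoreConstants(baseline, c(all_markers, "nfl"))

  # per-subject annualized z-score rates for every marker
  bySubj <- split(df, df$subject_id)
  rates <- t(vapply(bySubj, function(s) {
    vapply(all_markers, function(m) {
      annualizedChange(s$visit_time, zScoreValue(s[[m]], consts[[m]]))
    }, 0)
  }, numeric(length(all_markers))))
  baseline <- baseline[match(rownames(rates), baseline$subject_id), , drop = FALSE]

  dropped <- sum(is.na(rates))
  if (dropped > 0) ftdLog("crossLagMatrix: %d marker rates undefined (< 2 visits)", dropped)

  pairs <- rbind(
    expand.grid(predictor = predictors, response = responses,
                stringsAsFactors = FALSE),
    expand.grid(predictor = responses, response = predictors,
                stringsAsFactors = FALSE)
  )
  pairs$direction <- rep(c("forward", "reverse"),
                         c(length(predictors) * length(responses),
                           length(predictors) * length(responses)))
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    pred <- pairs$predictor[i]; resp <- pairs$response[i]
    d <- data.frame(
      rate = rates[, resp],
      predictor_baseline = zScoreValue(baseline[[pred]], consts[[pred]]),
      age = baseline$age,
      sex = baseline$sex,
      education = baseline$education,
      nfl_z = zScoreValue(baseline$nfl, consts[["nfl"]]),
      response_baseline = zScoreValue(baseline[[resp]], consts[[resp]])
    )
    fitPairModel(d)
  })
  res <- do.call(rbind, res)
  out <- cbind(pairs, res)
  out$p_fdr <- fdrCorrect(out$p)
  out$significant <- out$p_fdr < fdr
  names(out)[names(out) == "p"] <- "p_raw"

  tMatrix <- matrix(NA_real_, length(all_markers), length(all_markers),
                    dimnames = list(all_markers, all_markers))
  for (i in seq_len(nrow(out))) {
    tMatrix[out$predictor[i], out$response[i]] <- out$t[i]
  }
  structure(list(results = out, tMatrix = tMatrix, fdr = fdr),
            class = "crossLagResultSet")
}

#' @export
print.crossLagResultSet <- function(x, ...) {
  cat(sprintf("crossLagResultSet: %d directed pair models, FDR threshold %.3g\n",
              nrow(x$results), x$fdr))
  sig <- x$results[x$results$significant, c("predictor", "response", "t", "p_fdr")]
  if (nrow(sig)) {
    cat("significant associations:\n")
    print(sig, row.names = FALSE)
  } else {
    cat("no significant associations\n")
  }
  invisible(x)
}
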