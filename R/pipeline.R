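# End-to-end orchestration: simulate (or read) a cohort, adjust and compare
# WMH, fit the event-based model, run the cross-lagged analysis, and write
# reproducible artifacts with a manifest.

#' Pipeline run configuration
#'
#' @param simulate generate the cohort (`TRUE`, default) or read it from
#'   `inputCsv`.
#' @param cohort a [cohortConfig()] used when simulating.
#' @param longitudinal a [longitudinalConfig()] for the follow-up stage
#'   (`NULL` skips the cross-lagged analysis).
#' @param inputCsv path of a cohort CSV when `simulate = FALSE`.
#' @param outDir directory for stage artifacts (created if needed).
#' @param seed master seed for analysis stages (bootstrap, CV folds).
#' @param alpha significance level, `bootstrap` replicate count, `folds` CV
#'   folds, `mseThreshold` GMM admission threshold: analysis thresholds.
#' @param alpha,bootstrap,folds,mseThreshold analysis thresholds.
#' @return object of class `runConfig`.
#' @export
runConfig <- function(simulate = TRUE, cohort = cohortConfig(),
                      longitudinal = longitudinalConfig(),
                      inputCsv = NULL, outDir = tempfile("ftdcascade_run_"),
                      seed = 1L, alpha = 0.05, bootstrap = 100L,
                      folds = 10L, mseThreshold = 1e-3) {
  if (!simulate && is.null(inputCsv)) {
    ftdStop("ftdConfigError", "either simulate = TRUE or inputCsv must be given")
  }
  if (alpha <= 0 || mseThreshold <= 0 || !isCount(bootstrap) || !isCount(folds)) {
    ftdStop("ftdConfigError", "thresholds must be positive")
  }
  cfg <- list(
    simulate = simulate, cohort = cohort, longitudinal = longitudinal,
    inputCsv = inputCsv, outDir = outDir, seed = as.integer(seed),
    alpha = alpha, bootstrap = as.integer(bootstrap),
    folds = as.integer(folds), mseThreshold = mseThreshold
  )
  class(cfg) <- "runConfig"
  cfg
}

#' Validate a cohort table against the pipeline schema
#'
#' Report-only checks: required columns present and numeric where expected,
#' ICV-normalized volumes inside (0, 1), WMH volumes strictly positive, and
#' genotype/status consistency (noncarriers must be controls).
#'
#' @param table flat cohort data.frame (or an [FTDCohort-class]).
#' @return object of class `cohortValidation`: list with `pass`, a `checks`
#'   data.frame and a `rowIssues` data.frame of offending records.
#' @export
validateInput <- function(table) {
  df <- if (methods::is(table, "FTDCohort")) cohortTable(table) else table
  checks <- list()
  issues <- list()
  addCheck <- function(name, pass, detail = "") {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = name, pass = pass, detail = detail, stringsAsFactors = FALSE
    )
  }
  addIssue <- function(rows, problem) {
    if (length(rows)) {
      issues[[length(issues) + 1L]] <<- data.frame(
        row = rows, subject_id = df$subject_id[rows], problem = problem,
        stringsAsFactors = FALSE
      )
    }
  }

  missing_cols <- setdiff(DEMOGRAPHIC_COLS, colnames(df))
  addCheck("required columns", length(missing_cols) == 0L,
           paste(missing_cols, collapse = ", "))
  if (length(missing_cols)) {
    return(structure(list(pass = FALSE, checks = do.call(rbind, checks),
                          rowIssues = data.frame()), class = "cohortValidation"))
  }

  numericCols <- intersect(c("age", "education", "visit_time"), colnames(df))
  nonNum <- numericCols[!vapply(df[numericCols], is.numeric, TRUE)]
  addCheck("numeric types", length(nonNum) == 0L, paste(nonNum, collapse = ", "))

  badGeno <- which(!df$genotype %in% GENOTYPES | !df$status %in% STATUSES)
  addIssue(badGeno, "unknown genotype or status label")
  addCheck("genotype/status labels", length(badGeno) == 0L)

  inconsistent <- which(df$genotype == "noncarrier" & df$status != "control")
  addIssue(inconsistent, "noncarrier labelled as carrier status")
  addCheck("noncarrier => control", length(inconsistent) == 0L)

  man <- markerManifest()
  volCols <- intersect(man$name[man$transform == "identity"], colnames(df))
  for (cl in volCols) {
    bad <- which(!is.na(df[[cl]]) & (df[[cl]] <= 0 | df[[cl]] >= 1))
    addIssue(bad, sprintf("'%s' outside (0, 1): not ICV-normalized?", cl))
  }
  volPass <- !any(vapply(volCols, function(cl) {
    any(!is.na(df[[cl]]) & (df[[cl]] <= 0 | df[[cl]] >= 1))
  }, TRUE))
  addCheck("ICV-normalized volumes in (0, 1)", volPass)

  wmhCols <- intersect(grep("^wmh_", man$name, value = TRUE), colnames(df))
  for (cl in wmhCols) {
    bad <- which(!is.na(df[[cl]]) & df[[cl]] <= 0)
    addIssue(bad, sprintf("non-positive WMH volume '%s'", cl))
  }
  wmhPass <- !any(vapply(wmhCols, function(cl) {
    any(!is.na(df[[cl]]) & df[[cl]] <= 0)
  }, TRUE))
  addCheck("positive WMH volumes", wmhPass)

  negTime <- which(!is.na(df$visit_time) & df$visit_time < 0)
  addIssue(negTime, "negative visit_time")
  addCheck("visit_time >= 0", length(negTime) == 0L)

  checks <- do.call(rbind, checks)
  rowIssues <- if (length(issues)) do.call(rbind, issues) else
    data.frame(row = integer(0), subject_id = character(0), problem = character(0))
  structure(list(pass = all(checks$pass), checks = checks, rowIssues = rowIssues),
            class = "cohortValidation")
}

#' @export
print.cohortValidation <- function(x, ...) {
  cat(sprintf("cohortValidation: %s\n", if (x$pass) "PASS" else "FAIL"))
  print(x$checks, row.names = FALSE)
  if (nrow(x$rowIssues)) {
    cat(sprintf("%d row-level issue(s); first few:\n", nrow(x$rowIssues)))
    print(utils::head(x$rowIssues), row.names = FALSE)
  }
  invisible(x)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort simulation (or CSV ingest), schema validation,
#' normative WMH adjustment and regional group comparison, the
#' discriminative event-based model, and (when longitudinal data are
#' configured or present) the cross-lagged analysis. Per-stage CSV/JSON
#' artifacts and a manifest (config hash, seeds, exclusion counts, package
#' version) are written to `config$outDir`. Reruns with an identical
#' configuration produce identical artifacts and manifest hash.
#'
#' @param config a [runConfig()].
#' @return invisible list with the per-stage results and the manifest.
#' @export
runFullAnalysis <- function(config = runConfig()) {
  if (!inherits(config, "runConfig")) {
    ftdStop("ftdConfigError", "config must be created with runConfig()")
  }
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package = "ftdcascade",
    version = as.character(utils::packageVersion("ftdcascade")),
    seeds = list(analysis = config$seed),
    thresholds = list(alpha = config$alpha, bootstrap = config$bootstrap,
                      folds = config$folds, mseThreshold = config$mseThreshold),
    exclusions = list()
  )

  # stage 1: cohort
  cohort <- tryCatch({
    if (config$simulate) {
      manifest$seeds$cohort <- config$cohort$seed
      simulateCohort(config$cohort)
    } else {
      readCohortCsv(config$inputCsv)
    }
  }, ftdError = function(e) ftdStop("ftdSchemaError",
                                    paste("stage 'cohort' failed:", conditionMessage(e))))
  writeCohortCsv(cohort, file.path(config$outDir, "cohort.csv"))
  df <- cohortTable(cohort)

  validation <- validateInput(df)
  if (!validation$pass) {
    ftdStop("ftdSchemaError", "stage 'validate' failed; see validateInput(table)")
  }

  # stage 2: normative adjustment + regional comparison
  baseline <- df[df$visit_time == 0, , drop = FALSE]
  controls <- baseline[baseline$status == "control", , drop = FALSE]
  adjusted <- lapply(WMH_REGIONS, function(rg) {
    model <- fitNormativeModel(log10(controls[[wmhColumn(rg)]]),
                               controls$age, controls$sex, region = rg)
    adjustWmh(baseline, model, region = rg)
  })
  manifest$exclusions$missingDemographics <- sum(
    vapply(adjusted, function(a) attr(a, "excluded"), 0L)
  )
  adjusted <- do.call(rbind, adjusted)
  comparisons <- regionalWmhAnalysis(adjusted)
  manifest$bonferroniFamily <- attr(comparisons, "familySize")
  utils::write.csv(adjusted, file.path(config$outDir, "adjusted_wmh.csv"),
                   row.names = FALSE)
  utils::write.csv(comparisons, file.path(config$outDir, "group_comparisons.csv"),
                   row.names = FALSE)

  # stage 3: event-based model
  debm <- tryCatch(
    runDEBM(baseline, bootstrap = config$bootstrap, seed = config$seed,
            mseThreshold = config$mseThreshold, alpha = config$alpha,
            folds = config$folds),
    ftdError = function(e) ftdStop("ftdConvergenceError",
                                   paste("stage 'debm' failed:", conditionMessage(e)))
  )
  manifest$debm <- list(
    admitted = admittedMarkers(debm),
    ordering = eventSequence(debm),
    bootstrapReplicates = if (is.null(debm@positional)) 0L else debm@positional@B,
    cvFolds = config$folds,
    aucMean = unname(debm@auc[["mean"]]),
    excludedSubjects = debm@excludedSubjects
  )
  utils::write.csv(stageTable(debm), file.path(config$outDir, "stages.csv"),
                   row.names = FALSE)
  if (!is.null(debm@positional)) {
    utils::write.csv(as.data.frame(positionCounts(debm)),
                     file.path(config$outDir, "positional_variance.csv"))
  }
  jsonlite::write_json(
    list(
      admitted = admittedMarkers(debm),
      ordering = eventSequence(debm),
      cost = debm@ordering@cost,
      auc = as.list(debm@auc),
      gmm = lapply(debm@fits, function(f) list(
        marker = f@marker, normalMean = f@normalMean, normalSd = f@normalSd,
        abnormalMean = f@abnormalMean, abnormalSd = f@abnormalSd,
        mse = f@mse, screenP = f@screenP, admitted = f@admitted
      )),
      clinical = debm@clinical
    ),
    file.path(config$outDir, "debm_report.json"),
    auto_unbox = TRUE, digits = NA
  )

  # stage 4: cross-lagged longitudinal analysis
  crosslag <- NULL
  if (!is.null(config$longitudinal)) {
    long <- tryCatch({
      manifest$seeds$longitudinal <- config$longitudinal$seed
      simulateLongitudinal(config$longitudinal, cohort)
    }, ftdError = function(e) ftdStop("ftdConfigError",
                                      paste("stage 'longitudinal' failed:", conditionMessage(e))))
    crosslag <- crossLagMatrix(long, fdr = config$alpha)
    utils::write.csv(crosslag$results,
                     file.path(config$outDir, "crosslag_results.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(crosslag$tMatrix),
                     file.path(config$outDir, "crosslag_t_matrix.csv"))
    manifest$crosslag <- list(
      nModels = nrow(crosslag$results),
      nSignificant = sum(crosslag$results$significant)
    )
  }

  manifest$configHash <- rlang::hash(config)
  manifest$manifestHash <- rlang::hash(manifest)
  jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(
    cohort = cohort, validation = validation, adjusted = adjusted,
    comparisons = comparisons, debm = debm, crosslag = crosslag,
    manifest = manifest
  ))
}
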