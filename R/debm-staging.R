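# Patient staging along the central ordering, with cross-validated AUC and
# clinical-score validation.

#' Stage subjects along the event ordering
#'
#' The discrete stage of a subject is the event count k in 0..K maximizing
#' the log-score `sum_{j<=k} log P_sigma(j) + sum_{j>k} log(1 - P_sigma(j))`
#' over the subject's observed biomarkers (posteriors clipped to
#' \[1e-6, 1 - 1e-6\]; ties resolve to the smallest k). The continuous stage
#' is the mean of the observed posteriors, in \[0, 1\]. Subjects with no
#' observed biomarker are excluded (count attached as attribute
#' `"excluded"`).
#'
#' @param P subjects x K posterior matrix (rownames = subject ids).
#' @param ordering an [EventOrdering-class] or character vector.
#' @return data.frame with `subject_id`, `stage` (0..K), `continuous_stage`,
#'   `n_observed`.
#' @export
stageSubjects <- function(P, ordering) {
  if (methods::is(ordering, "EventOrdering")) ordering <- ordering@ordering
  if (!setequal(ordering, colnames(P))) {
    ftdStop("ftdConfigError", "ordering must cover the biomarker columns of P")
  }
  P <- P[, ordering, drop = FALSE]
  K <- ncol(P)
  ids <- rownames(P) %||% as.character(seq_len(nrow(P)))
  stage <- integer(nrow(P))
  cont <- numeric(nrow(P))
  nObs <- integer(nrow(P))
  for (i in seq_len(nrow(P))) {
    p <- P[i, ]
    obs <- !is.na(p)
    nObs[i] <- sum(obs)
    if (nObs[i] == 0L) {
      stage[i] <- NA_integer_
      cont[i] <- NA_real_
      next
    }
    pc <- clipProb(p)
    lp <- ifelse(obs, log(pc), 0)
    lq <- ifelse(obs, log1p(-pc), 0)
    # scores[k + 1] = sum_{j <= k} lp_j + sum_{j > k} lq_j
    scores <- vapply(0:K, function(k) {
      sum(lp[seq_len(k)]) + sum(lq[setdiff(seq_len(K), seq_len(k))])
    }, 0)
    stage[i] <- which.max(scores) - 1L
    cont[i] <- mean(pc[obs])
  }
  excluded <- sum(is.na(stage))
  if (excluded > 0) ftdLog("stageSubjects: %d subject(s) with no observed biomarker", excluded)
  out <- data.frame(
    subject_id = ids, stage = stage, continuous_stage = cont,
    n_observed = nObs, stringsAsFactors = FALSE
  )
  attr(out, "excluded") <- excluded
  out
}

#' Cross-validated staging AUC
#'
#' Stratified k-fold assessment of how well the continuous stage separates
#' symptomatic carriers from controls: per fold, the rank-based AUC of the
#' held-out subjects' stages, returned as mean and sd across folds.
#'
#' @param stage numeric continuous stages.
#' @param labels diagnosis labels aligned with `stage`.
#' @param folds number of folds (default 10).
#' @param seed RNG seed for the fold assignment.
#' @return named numeric `c(mean = ..., sd = ...)` with attribute
#'   `"foldAuc"`.
#' @export
stagingAuc <- function(stage, labels, folds = 10L, seed = 1L) {
  if (!isCount(folds) || folds < 2) ftdStop("ftdConfigError", "folds must be >= 2")
  keep <- labels %in% c("symptomatic", "control") & !is.na(stage)
  stage <- stage[keep]
  labels <- labels[keep]
  pos <- labels == "symptomatic"
  if (sum(pos) < folds || sum(!pos) < folds) {
    ftdStop("ftdInsufficientDataError",
            "need at least `folds` subjects per class for stratified folds")
  }
  withSeed(seed, {
    fold <- integer(length(stage))
    for (cls in c(TRUE, FALSE)) {
      ii <- which(pos == cls)
      fold[ii] <- sample(rep(seq_len(folds), length.out = length(ii)))
    }
    aucs <- vapply(seq_len(folds), function(f) {
      held <- fold == f
      rankAuc(stage[held & pos], stage[held & !pos])
    }, 0)
    out <- c(mean = mean(aucs), sd = stats::sd(aucs))
    attr(out, "foldAuc") <- aucs
    out
  })
}

#' Spearman correlation of stage with clinical scores
#'
#' Pairwise-complete Spearman rank correlations between the estimated stage
#' and each clinical score; scores with fewer than three paired observations
#' are skipped with a log entry.
#'
#' @param stage numeric stages.
#' @param scores data.frame of clinical scores aligned with `stage`.
#' @return data.frame with `score`, `rho`, `p`, `n`.
#' @export
clinicalStageCorrelation <- function(stage, scores) {
  res <- lapply(colnames(scores), function(sc) {
    y <- scores[[sc]]
    ok <- !is.na(stage) & !is.na(y)
    if (sum(ok) < 3L) {
      ftdLog("clinicalStageCorrelation: score '%s' skipped (< 3 pairs)", sc)
      return(NULL)
    }
    ct <- suppressWarnings(
      stats::cor.test(stage[ok], y[ok], method = "spearman", exact = FALSE)
    )
    data.frame(score = sc, rho = unname(ct$estimate), p = ct$p.value,
               n = sum(ok), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) out <- data.frame(score = character(0), rho = numeric(0),
                                      p = numeric(0), n = integer(0))
  out
}

#' Fit the discriminative event-based model to a cohort
#'
#' End-to-end DEBM on baseline visits: transforms the selected biomarkers
#' (log10 where flagged), residualizes them against age and sex on controls,
#' screens and fits the constrained mixture per biomarker, computes posterior
#' abnormality probabilities over the admitted biomarkers, estimates the
#' central ordering, runs the stratified bootstrap positional-variance
#' diagram, stages every subject, and computes the cross-validated AUC and
#' clinical-score correlations.
#'
#' @param cohort an [FTDCohort-class] or flat cohort table.
#' @param markers manifest data.frame (`name`, `direction`, `transform`);
#'   defaults to the nine cascade biomarkers of [debmMarkers()].
#' @param genotypes genotype subset analysed (default controls plus GRN
#'   carriers, the cohort with prominent WMH burden).
#' @param bootstrap number of bootstrap replicates (default 100; 0 skips the
#'   positional-variance diagram).
#' @param seed RNG seed governing bootstrap, restarts and CV folds.
#' @param mseThreshold GMM admission threshold (default 1e-3).
#' @param alpha screen significance level.
#' @param folds CV folds for the staging AUC.
#' @param refit refit mixtures within each bootstrap replicate.
#' @param ... further arguments to [fitBiomarkerGMM()].
#' @return a [DEBMFit-class].
#' @export
runDEBM <- function(cohort, markers = debmMarkers(),
                    genotypes = c("noncarrier", "GRN"),
                    bootstrap = 100L, seed = 1L, mseThreshold = 1e-3,
                    alpha = 0.05, folds = 10L, refit = TRUE, ...) {
  df <- if (methods::is(cohort, "FTDCohort")) cohortTable(cohort) else cohort
  df <- df[df$visit_time == 0 & df$genotype %in% genotypes, , drop = FALSE]
  missing_cols <- setdiff(markers$name, colnames(df))
  if (length(missing_cols)) {
    ftdStop("ftdSchemaError", sprintf(
      "cohort lacks biomarker column(s): %s", paste(missing_cols, collapse = ", ")
    ))
  }
  values <- as.matrix(df[, markers$name, drop = FALSE])
  rownames(values) <- df$subject_id
  for (i in seq_len(nrow(markers))) {
    if (markers$transform[i] == "log10") {
      v <- values[, i]
      if (any(v <= 0, na.rm = TRUE)) {
        ftdStop("ftdValueError", sprintf(
          "biomarker '%s' must be strictly positive before log transform",
          markers$name[i]
        ))
      }
      values[, i] <- log10(v)
    }
  }
  labels <- df$status
  directions <- stats::setNames(markers$direction, markers$name)
  adjusted <- adjustConfounds(values, labels, df$age, df$sex)

  withSeed(seed, {
    fits <- lapply(markers$name, function(m) {
      tryCatch(
        fitBiomarkerGMM(adjusted[, m], labels, direction = directions[[m]],
                        marker = m, mseThreshold = mseThreshold,
                        alpha = alpha, ...),
        ftdError = function(e) {
          ftdLog("runDEBM: biomarker '%s' not admitted (%s)", m, conditionMessage(e))
          NULL
        }
      )
    })
    names(fits) <- markers$name
    fits <- fits[!vapply(fits, is.null, TRUE)]
    admitted <- names(fits)[vapply(fits, function(f) f@admitted, TRUE)]
    if (length(admitted) < 2L) {
      ftdStop("ftdInsufficientDataError", "fewer than two biomarkers admitted")
    }
    P <- eventProbabilities(fits[admitted], adjusted)
    ordering <- estimateOrdering(P)
    excluded <- attr(ordering, "excludedSubjects")

    positional <- NULL
    if (bootstrap > 0) {
      positional <- bootstrapOrdering(
        adjusted[, admitted, drop = FALSE], labels, directions,
        B = bootstrap, seed = sample.int(.Machine$integer.max, 1L),
        refit = refit, fits = fits[admitted], ordering = ordering,
        mseThreshold = mseThreshold, alpha = alpha, ...
      )
    }

    stages <- stageSubjects(P, ordering)
    auc <- stagingAuc(stages$continuous_stage, labels, folds = folds,
                      seed = sample.int(.Machine$integer.max, 1L))
    scoreCols <- intersect(CLINICAL_SCORES, colnames(df))
    clinical <- clinicalStageCorrelation(stages$continuous_stage,
                                         df[, scoreCols, drop = FALSE])
    methods::new(
      "DEBMFit",
      fits = fits, probabilities = P, ordering = ordering,
      positional = positional, stages = stages, auc = auc,
      clinical = clinical, excludedSubjects = as.integer(excluded %||% 0L)
    )
  })
}
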