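# Synthetic cohort generator: a latent-stage event cascade with Gaussian
# normal/abnormal biomarker states, age/sex confounds and missingness.

markerThresholds <- function(cfg) {
  mk <- cfg$markers
  K <- length(cfg$ordering)
  thr <- mk$threshold
  pos <- match(mk$name, cfg$ordering)
  thr[!is.na(pos)] <- pos[!is.na(pos)] / (K + 1)
  names(thr) <- mk$name
  thr
}

#' Simulate a baseline cohort
#'
#' Draws one baseline visit per subject. Each subject receives a latent
#' disease stage from its status-specific distribution (controls are fixed at
#' stage 0); biomarker k at ground-truth position j of K is drawn from its
#' abnormal component iff the latent stage exceeds j/(K+1), otherwise from
#' its normal component, on the transform scale declared in the manifest.
#' Age and sex confound terms are then added (age centred at 50 years, sex
#' effect is the male contrast), values are back-transformed, and entries are
#' masked missing at the manifest's per-biomarker rates. Identical seeds give
#' identical cohorts.
#'
#' Clinical scores are noisy monotone transforms of the latent stage so that
#' downstream stage-validation correlations carry signal.
#'
#' @param config a [cohortConfig()].
#' @return an [FTDCohort-class] with `visit_time = 0` for every record.
#' @examples
#' coh <- simulateCohort(cohortConfig(seed = 7))
#' table(cohortTable(coh)$status)
#' @export
simulateCohort <- function(config = cohortConfig()) {
  if (!inherits(config, "cohortConfig")) {
    ftdStop("ftdConfigError", "config must be created with cohortConfig()")
  }
  validateCohortConfig(config)
  withSeed(config$seed, {
    gs <- config$groupSizes
    n <- sum(gs$n)
    genotype <- rep(gs$genotype, gs$n)
    status <- rep(gs$status, gs$n)
    age <- pmin(pmax(rnorm(n, rep(gs$ageMean, gs$n), rep(gs$ageSd, gs$n)), 18), 90)
    sex <- ifelse(runif(n) < rep(gs$maleFrac, gs$n), "male", "female")
    education <- pmax(round(rnorm(n, rep(gs$eduMean, gs$n), rep(gs$eduSd, gs$n))), 5)

    lower <- vapply(status, function(s) config$stageDistribution[[s]][1], 0)
    upper <- vapply(status, function(s) config$stageDistribution[[s]][2], 0)
    stage <- lower + runif(n) * (upper - lower)

    mk <- config$markers
    thr <- markerThresholds(config)
    male <- as.numeric(sex == "male")
    values <- matrix(NA_real_, nrow = nrow(mk), ncol = n,
                     dimnames = list(mk$name, NULL))
    for (i in seq_len(nrow(mk))) {
      ab <- stage > thr[mk$name[i]]
      z <- rnorm(n,
                 mean = ifelse(ab, mk$abnormalMean[i], mk$normalMean[i]),
                 sd = ifelse(ab, mk$abnormalSd[i], mk$normalSd[i]))
      z <- z + mk$ageEffect[i] * (age - 50) + mk$sexEffect[i] * male
      v <- if (mk$transform[i] == "log10") 10^z else z
      if (mk$missingRate[i] > 0) v[runif(n) < mk$missingRate[i]] <- NA_real_
      values[i, ] <- v
    }

    scores <- data.frame(
      cdr_sob = pmax(0, 16 * stage^1.5 + rnorm(n, 0, 0.8)),
      mmse = pmin(30, 30 - 12 * stage + rnorm(n, 0, 1)),
      tmt_b = pmax(20, 60 + 180 * stage + rnorm(n, 0, 15)),
      boston_naming = pmin(30, 30 - 10 * stage + rnorm(n, 0, 1.5)),
      digit_symbol = pmax(0, 50 - 25 * stage + rnorm(n, 0, 4)),
      verbal_fluency = pmax(0, 40 - 20 * stage + rnorm(n, 0, 4))
    )

    cd <- S4Vectors::DataFrame(
      subject_id = sprintf("SUB%04d", seq_len(n)),
      genotype = genotype, status = status,
      age = age, sex = sex, education = as.numeric(education),
      visit_time = rep(0, n),
      latent_stage = stage,
      scores
    )
    rd <- S4Vectors::DataFrame(
      direction = mk$direction, transform = mk$transform,
      threshold = unname(thr), row.names = mk$name
    )
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(values = values), colData = cd, rowData = rd,
      metadata = list(config = config, groundTruth = config$ordering)
    )
    colnames(se) <- paste0(cd$subject_id, "_v0")
    methods::new("FTDCohort", se)
  })
}

transformValue <- function(v, transform) {
  if (transform == "log10") log10(v) else v
}

backTransform <- function(z, transform) {
  if (transform == "log10") 10^z else z
}

#' Simulate longitudinal follow-up of GRN carriers
#'
#' Selects presymptomatic and symptomatic GRN carriers from a baseline cohort
#' and extends each with follow-up visits. Trajectories are linear on the
#' z-scale of each followed biomarker (standardized over the selected
#' subjects at baseline): the per-subject annual slope is the biomarker's
#' base slope plus the configured couplings times the subject's standardized
#' baseline predictor values, plus Gaussian slope noise. Biomarkers without a
#' base-slope entry are carried forward unchanged. With all couplings and
#' base slopes zero and `noiseSd = 0`, follow-up visits replicate baseline
#' values exactly.
#'
#' @param config a [longitudinalConfig()].
#' @param baseline an [FTDCohort-class] from [simulateCohort()].
#' @return an [FTDCohort-class] containing the selected subjects with
#'   `visitsPerSubject` visits each (baseline rows are reused verbatim).
#' @export
simulateLongitudinal <- function(config = longitudinalConfig(), baseline) {
  if (!inherits(config, "longitudinalConfig")) {
    ftdStop("ftdConfigError", "config must be created with longitudinalConfig()")
  }
  if (missing(baseline) || !methods::is(baseline, "FTDCohort")) {
    ftdStop("ftdConfigError", "baseline must be an FTDCohort")
  }
  cd <- SummarizedExperiment::colData(baseline)
  base_idx <- which(cd$visit_time == 0)
  pre <- base_idx[cd$genotype[base_idx] == "GRN" & cd$status[base_idx] == "presymptomatic"]
  sym <- base_idx[cd$genotype[base_idx] == "GRN" & cd$status[base_idx] == "symptomatic"]
  if (length(pre) < config$nPresymptomatic || length(sym) < config$nSymptomatic) {
    ftdStop("ftdConfigError", "baseline cohort has fewer GRN carriers than requested")
  }
  withSeed(config$seed, {
    sel <- c(sample(pre, config$nPresymptomatic), sample(sym, config$nSymptomatic))
    sub <- baseline[, sel]
    vals <- SummarizedExperiment::assay(sub, "values")
    rd <- SummarizedExperiment::rowData(sub)
    traj <- intersect(names(config$baseSlopes), rownames(vals))

    # z-scoring constants over the selected subjects at baseline
    zc <- lapply(traj, function(m) {
      z <- transformValue(vals[m, ], rd[m, "transform"])
      c(mean = mean(z, na.rm = TRUE), sd = stats::sd(z, na.rm = TRUE))
    })
    names(zc) <- traj

    nsub <- ncol(vals)
    zbase <- vapply(traj, function(m) {
      (transformValue(vals[m, ], rd[m, "transform"]) - zc[[m]]["mean"]) / zc[[m]]["sd"]
    }, numeric(nsub))            # nsub x length(traj)

    cp <- config$coupling
    slopes <- vapply(traj, function(m) {
      s <- rep(config$baseSlopes[[m]], nsub)
      preds <- intersect(rownames(cp)[cp[, m] != 0], traj)
      for (p in preds) s <- s + cp[p, m] * zbase[, p]
      s + rnorm(nsub, 0, config$noiseSd)
    }, numeric(nsub))            # nsub x length(traj)

    times <- (seq_len(config$visitsPerSubject) - 1L) * config$followUpInterval
    pieces <- list(sub)
    cdb <- SummarizedExperiment::colData(sub)
    for (vi in seq_along(times)[-1]) {
      t <- times[vi]
      v2 <- vals
      for (j in seq_along(traj)) {
        m <- traj[j]
        zt <- zbase[, j] + slopes[, j] * t + rnorm(nsub, 0, config$noiseSd)
        v2[m, ] <- backTransform(zc[[m]]["mean"] + zc[[m]]["sd"] * zt, rd[m, "transform"])
      }
      cdv <- cdb
      cdv$visit_time <- rep(t, nsub)
      sev <- SummarizedExperiment::SummarizedExperiment(
        assays = list(values = v2), colData = cdv, rowData = rd
      )
      colnames(sev) <- sprintf("%s_v%d", cdv$subject_id, vi - 1L)
      pieces[[vi]] <- methods::new("FTDCohort", sev)
    }
    out <- do.call(SummarizedExperiment::cbind, pieces)
    S4Vectors::metadata(out) <- c(
      S4Vectors::metadata(baseline), list(longitudinalConfig = config)
    )
    methods::new("FTDCohort", out)
  })
}

#' @describeIn groundTruthOrdering ordering stored in a cohort configuration.
#' @export
setMethod("groundTruthOrdering", "cohortConfig", function(x) {
  methods::new("EventOrdering", ordering = x$ordering, cost = NA_real_,
               method = "ground_truth")
})

#' @describeIn groundTruthOrdering ordering recorded when the cohort was
#'   simulated.
#' @export
setMethod("groundTruthOrdering", "FTDCohort", function(x) {
  gt <- S4Vectors::metadata(x)$groundTruth
  if (is.null(gt)) ftdStop("ftdConfigError", "cohort carries no ground-truth ordering")
  methods::new("EventOrdering", ordering = gt, cost = NA_real_,
               method = "ground_truth")
})
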