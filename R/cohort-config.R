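# Configuration objects for the synthetic genetic-FTD cohort generator.

setOldClass("cohortConfig")
setOldClass("longitudinalConfig")

#' Biomarker manifest for the synthetic cohort
#'
#' One row per generated biomarker: the abnormality direction, the transform
#' under which the normal/abnormal components are Gaussian (`log10` markers
#' are generated as 10^z with z Gaussian), the component parameters on the
#' transform scale, linear age/sex confound coefficients, the missingness
#' rate, and (for biomarkers outside the event ordering) the latent-stage
#' threshold at which the marker turns abnormal.
#'
#' Defaults: the nine cascade biomarkers (frontal/temporal/total WMH,
#' ventricles, NfL, GFAP, frontal/temporal grey matter, cerebellum) with a
#' two-pooled-sd separation between components; six subcortical volumes used
#' by the longitudinal module; combined parietal WMH; and the eight
#' left/right lobar WMH volumes used by the regional comparison. WMH, NfL,
#' GFAP and ventricles are log-normal with abnormality = increase; grey
#' matter volumes are Gaussian ICV fractions with abnormality = decrease.
#' Missingness defaults reflect the fluid-biomarker availability of the
#' cohort the simulator emulates (NfL 21.4%, GFAP 38.1% missing).
#'
#' @return data.frame with columns `name`, `direction`, `transform`,
#'   `normalMean`, `normalSd`, `abnormalMean`, `abnormalSd`, `ageEffect`,
#'   `sexEffect`, `missingRate`, `threshold`.
#' @export
markerManifest <- function() {
  m <- function(name, direction, transform, nm, ns, am, as_, age = 0, sex = 0,
                miss = 0, thr = NA_real_) {
    data.frame(
      name = name, direction = direction, transform = transform,
      normalMean = nm, normalSd = ns, abnormalMean = am, abnormalSd = as_,
      ageEffect = age, sexEffect = sex, missingRate = miss, threshold = thr,
      stringsAsFactors = FALSE
    )
  }
  rbind(
    # cascade biomarkers (position set by the ground-truth ordering)
    m("wmh_total",    "increase", "log10", 3.47, 0.35, 4.17, 0.35, 0.010, 0.05),
    m("wmh_frontal",  "increase", "log10", 3.10, 0.35, 3.80, 0.35, 0.010, 0.05),
    m("wmh_temporal", "increase", "log10", 2.70, 0.35, 3.40, 0.35, 0.008, 0.04),
    m("ventricles",   "increase", "log10", -1.70, 0.12, -1.46, 0.12, 0.004, 0.02),
    m("nfl",          "increase", "log10", 1.00, 0.25, 1.50, 0.25, 0.008, 0.00, miss = 0.214),
    m("gfap",         "increase", "log10", 2.00, 0.20, 2.40, 0.20, 0.006, 0.00, miss = 0.381),
    m("gm_frontal",   "decrease", "identity", 0.1050, 0.0080, 0.0890, 0.0080, -2e-4, -1e-3),
    m("gm_temporal",  "decrease", "identity", 0.0850, 0.0060, 0.0730, 0.0060, -1.5e-4, -8e-4),
    m("cerebellum",   "decrease", "identity", 0.0880, 0.0070, 0.0740, 0.0070, -1e-4, -5e-4),
    # combined parietal WMH (cross-lag predictor set), tied to the first event
    m("wmh_parietal", "increase", "log10", 2.90, 0.35, 3.25, 0.35, 0.009, 0.04, thr = 0.1),
    # subcortical volumes followed longitudinally; turn abnormal late
    m("insula",        "decrease", "identity", 0.00450, 4.0e-4, 0.00370, 4.0e-4, -4e-6, -2e-5, thr = 0.6),
    m("basal_ganglia", "decrease", "identity", 0.01200, 1.0e-3, 0.01000, 1.0e-3, -1e-5, -5e-5, thr = 0.6),
    m("thalamus",      "decrease", "identity", 0.00950, 8.0e-4, 0.00790, 8.0e-4, -8e-6, -4e-5, thr = 0.6),
    m("hippocampus",   "decrease", "identity", 0.00480, 4.0e-4, 0.00400, 4.0e-4, -4e-6, -2e-5, thr = 0.6),
    m("amygdala",      "decrease", "identity", 0.00170, 1.5e-4, 0.00140, 1.5e-4, -1.5e-6, -8e-6, thr = 0.6),
    m("cingulate",     "decrease", "identity", 0.01100, 9.0e-4, 0.00920, 9.0e-4, -9e-6, -4e-5, thr = 0.6),
    # left/right lobar WMH for the regional comparison; frontal-dominant
    # abnormal shifts, all keyed to the first-event threshold
    m("wmh_lh_frontal",   "increase", "log10", 2.80, 0.35, 3.50, 0.35, 0.010, 0.05, thr = 0.1),
    m("wmh_rh_frontal",   "increase", "log10", 2.80, 0.35, 3.50, 0.35, 0.010, 0.05, thr = 0.1),
    m("wmh_lh_temporal",  "increase", "log10", 2.40, 0.35, 2.75, 0.35, 0.008, 0.04, thr = 0.1),
    m("wmh_rh_temporal",  "increase", "log10", 2.40, 0.35, 2.75, 0.35, 0.008, 0.04, thr = 0.1),
    m("wmh_lh_parietal",  "increase", "log10", 2.60, 0.35, 2.95, 0.35, 0.009, 0.04, thr = 0.1),
    m("wmh_rh_parietal",  "increase", "log10", 2.60, 0.35, 2.95, 0.35, 0.009, 0.04, thr = 0.1),
    m("wmh_lh_occipital", "increase", "log10", 2.30, 0.35, 2.45, 0.35, 0.006, 0.03, thr = 0.1),
    m("wmh_rh_occipital", "increase", "log10", 2.30, 0.35, 2.45, 0.35, 0.006, 0.03, thr = 0.1)
  )
}

#' Manifest of the nine cascade biomarkers used by the event-based model
#'
#' @return data.frame with columns `name`, `direction`, `transform`.
#' @export
debmMarkers <- function() {
  man <- markerManifest()
  keep <- c(
    "wmh_frontal", "wmh_temporal", "wmh_total", "ventricles", "cerebellum",
    "gm_frontal", "gm_temporal", "gfap", "nfl"
  )
  man[match(keep, man$name), c("name", "direction", "transform")]
}

#' Default ground-truth event ordering of the synthetic cascade
#'
#' WMH measures first, then ventricular enlargement and NfL, then grey
#' matter volumes, with GFAP last.
#' @return character vector of nine biomarker names.
#' @export
defaultOrdering <- function() {
  c(
    "wmh_total", "wmh_frontal", "wmh_temporal", "ventricles", "nfl",
    "gm_temporal", "gm_frontal", "cerebellum", "gfap"
  )
}

#' Default cohort composition
#'
#' Cell sizes and demographic moments per genotype-by-status group of the
#' emulated cohort (298 controls; 129/77 C9orf72, 137/45 GRN and 50/27 MAPT
#' presymptomatic/symptomatic carriers).
#' @return data.frame consumed by [cohortConfig()].
#' @export
defaultGroupSizes <- function() {
  data.frame(
    genotype = c("noncarrier", "C9orf72", "C9orf72", "GRN", "GRN", "MAPT", "MAPT"),
    status = c("control", "presymptomatic", "symptomatic",
               "presymptomatic", "symptomatic", "presymptomatic", "symptomatic"),
    n = c(298L, 129L, 77L, 137L, 45L, 50L, 27L),
    ageMean = c(47.3, 44.9, 65.0, 47.3, 63.8, 41.4, 57.1),
    ageSd = c(13.6, 11.1, 7.6, 12.3, 8.4, 11.2, 9.6),
    maleFrac = c(0.409, 0.403, 0.649, 0.365, 0.422, 0.380, 0.592),
    eduMean = c(14.4, 14.3, 12.9, 14.8, 11.9, 14.0, 13.3),
    eduSd = c(3.2, 2.9, 3.7, 3.4, 3.5, 3.4, 3.5),
    stringsAsFactors = FALSE
  )
}

#' Configuration of the synthetic cross-sectional cohort
#'
#' Defines the generative model the analysis modules are exercised against:
#' cell sizes per genotype-by-status group, the biomarker manifest, a
#' ground-truth event ordering, latent-stage distributions per clinical
#' status (uniform on the given interval; controls are fixed at 0), and the
#' RNG seed. Events fire in ground-truth order at equally spaced stage
#' thresholds j/(K+1): biomarker at position j is drawn from its abnormal
#' component iff the subject's latent stage exceeds j/(K+1).
#'
#' @param groupSizes data.frame with columns `genotype`, `status`, `n`,
#'   `ageMean`, `ageSd`, `maleFrac`, `eduMean`, `eduSd`.
#' @param markers biomarker manifest, see [markerManifest()].
#' @param ordering ground-truth permutation of a subset of marker names.
#' @param stageDistribution named list of `c(lower, upper)` latent-stage
#'   bounds per status.
#' @param seed integer RNG seed.
#' @return object of class `cohortConfig`.
#' @export
cohortConfig <- function(groupSizes = defaultGroupSizes(),
                         markers = markerManifest(),
                         ordering = defaultOrdering(),
                         stageDistribution = list(
                           control = c(0, 0),
                           presymptomatic = c(0, 0.5),
                           symptomatic = c(0.4, 1)
                         ),
                         seed = 1234L) {
  cfg <- list(
    groupSizes = groupSizes, markers = markers, ordering = ordering,
    stageDistribution = stageDistribution, seed = as.integer(seed)
  )
  class(cfg) <- "cohortConfig"
  validateCohortConfig(cfg)
  cfg
}

validateCohortConfig <- function(cfg) {
  gs <- cfg$groupSizes
  if (any(gs$n < 0)) ftdStop("ftdConfigError", "group sizes must be >= 0")
  if (!all(gs$genotype %in% GENOTYPES) || !all(gs$status %in% STATUSES)) {
    ftdStop("ftdConfigError", "unknown genotype or status label in groupSizes")
  }
  mk <- cfg$markers
  if (any(mk$normalSd < 0) || any(mk$abnormalSd < 0)) {
    ftdStop("ftdConfigError", "biomarker sds must be >= 0")
  }
  if (any(mk$missingRate < 0 | mk$missingRate > 1)) {
    ftdStop("ftdConfigError", "missing rates must lie in [0, 1]")
  }
  ord <- cfg$ordering
  if (anyDuplicated(ord) || !all(ord %in% mk$name)) {
    ftdStop("ftdConfigError", "ordering must be a permutation of biomarker names")
  }
  # every ordered marker must not also carry a fixed threshold
  idx <- match(mk$name, ord)
  shift <- mk$abnormalMean - mk$normalMean
  badDir <- (mk$direction == "increase" & shift <= 0) |
    (mk$direction == "decrease" & shift >= 0)
  if (any(badDir)) {
    ftdStop("ftdConfigError", sprintf(
      "abnormal mean must differ from normal mean in the declared direction: %s",
      paste(mk$name[badDir], collapse = ", ")
    ))
  }
  unthresholded <- is.na(mk$threshold) & is.na(idx)
  if (any(unthresholded)) {
    ftdStop("ftdConfigError", sprintf(
      "markers outside the ordering need an explicit threshold: %s",
      paste(mk$name[unthresholded], collapse = ", ")
    ))
  }
  for (st in STATUSES) {
    b <- cfg$stageDistribution[[st]]
    if (is.null(b) || length(b) != 2L || b[1] > b[2] || b[1] < 0 || b[2] > 1) {
      ftdStop("ftdConfigError", sprintf("invalid stage distribution for status '%s'", st))
    }
  }
  invisible(cfg)
}

#' Default slope-coupling matrix of the longitudinal generator
#'
#' Baseline total WMH steepens the decline of amygdala, hippocampus and
#' cingulate volumes (coefficient -0.3 z per year per baseline z); all other
#' couplings, including every reverse (subcortical-to-WMH) pair, are zero.
#' @return square named matrix `coupling[predictor, response]`.
#' @export
defaultCoupling <- function() {
  preds <- c("wmh_total", "wmh_frontal", "wmh_temporal", "wmh_parietal")
  resps <- c("insula", "basal_ganglia", "thalamus", "hippocampus", "amygdala", "cingulate")
  all <- c(preds, resps)
  cp <- matrix(0, length(all), length(all), dimnames = list(all, all))
  cp["wmh_total", c("amygdala", "hippocampus", "cingulate")] <- -0.3
  cp
}

#' Default annual base slopes of the followed biomarkers
#'
#' z units per year: lesion load grows, subcortical volumes decline.
#' @return named numeric vector.
#' @export
defaultBaseSlopes <- function() {
  c(
    wmh_total = 0.10, wmh_frontal = 0.10, wmh_temporal = 0.08, wmh_parietal = 0.08,
    insula = -0.05, basal_ganglia = -0.05, thalamus = -0.05,
    hippocampus = -0.05, amygdala = -0.05, cingulate = -0.05
  )
}

#' Configuration of the synthetic longitudinal follow-up
#'
#' Describes the multi-visit extension of a baseline cohort: how many GRN
#' carriers are followed, the visit schedule, and the directional coupling of
#' annual slopes to standardized baseline predictor values. Each followed
#' biomarker's per-subject annual slope (on the z scale) is
#' `base slope + sum_p coupling[p, m] * z(baseline p) + N(0, noiseSd)`;
#' visit values add `N(0, noiseSd)` measurement noise on top of the linear
#' trajectory. Reverse couplings (subcortical volume to WMH) default to zero.
#'
#' @param nPresymptomatic,nSymptomatic number of presymptomatic and
#'   symptomatic GRN carriers followed (defaults 70 and 13).
#' @param visitsPerSubject number of visits including baseline (>= 2).
#' @param followUpInterval years between consecutive visits.
#' @param coupling square numeric matrix of slope-modulation coefficients,
#'   `coupling[predictor, response]`, covering every tested pair.
#' @param baseSlopes named annual base slopes (z units per year).
#' @param noiseSd slope heterogeneity and visit noise sd (> 0 unless exactly
#'   0 for deterministic checks).
#' @param seed integer RNG seed.
#' @return object of class `longitudinalConfig`.
#' @export
longitudinalConfig <- function(nPresymptomatic = 70L, nSymptomatic = 13L,
                               visitsPerSubject = 3L, followUpInterval = 1.1,
                               coupling = defaultCoupling(),
                               baseSlopes = defaultBaseSlopes(),
                               noiseSd = 0.1, seed = 5678L) {
  if (!isCount(visitsPerSubject) || visitsPerSubject < 2) {
    ftdStop("ftdConfigError", "visitsPerSubject must be an integer >= 2")
  }
  if (noiseSd < 0) ftdStop("ftdConfigError", "noiseSd must be >= 0")
  if (!is.matrix(coupling) || nrow(coupling) != ncol(coupling) ||
      is.null(rownames(coupling)) ||
      !identical(rownames(coupling), colnames(coupling))) {
    ftdStop("ftdConfigError", "coupling must be a square named matrix")
  }
  missing_slope <- setdiff(rownames(coupling), names(baseSlopes))
  if (length(missing_slope)) {
    ftdStop("ftdConfigError", sprintf(
      "baseSlopes missing for: %s", paste(missing_slope, collapse = ", ")
    ))
  }
  cfg <- list(
    nPresymptomatic = as.integer(nPresymptomatic),
    nSymptomatic = as.integer(nSymptomatic),
    visitsPerSubject = as.integer(visitsPerSubject),
    followUpInterval = followUpInterval,
    coupling = coupling, baseSlopes = baseSlopes,
    noiseSd = noiseSd, seed = as.integer(seed)
  )
  class(cfg) <- "longitudinalConfig"
  cfg
}
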