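# Shared fixtures, built in code at test time.

# Small cohort: same structure as the default, ~1/4 of the size.
smallGroupSizes <- function() {
  gs <- defaultGroupSizes()
  gs$n <- c(80L, 30L, 20L, 40L, 20L, 15L, 10L)
  gs
}

smallCohort <- function(seed = 301L) {
  simulateCohort(cohortConfig(groupSizes = smallGroupSizes(), seed = seed))
}

# Manifest with confound effects switched off (for marginal-moment checks).
noConfoundMarkers <- function() {
  mk <- markerManifest()
  mk$ageEffect <- 0
  mk$sexEffect <- 0
  mk
}

# Zero-noise three-marker configuration: controls at stage 0, symptomatic
# carriers at stage 1, degenerate components.
degenerateThreeMarkerConfig <- function(seed = 99L) {
  mk <- data.frame(
    name = c("m_a", "m_b", "m_c"),
    direction = "increase", transform = "identity",
    normalMean = c(0, 1, 2), normalSd = 0,
    abnormalMean = c(5, 6, 7), abnormalSd = 0,
    ageEffect = 0, sexEffect = 0, missingRate = 0,
    threshold = NA_real_, stringsAsFactors = FALSE
  )
  gs <- data.frame(
    genotype = c("noncarrier", "GRN"), status = c("control", "symptomatic"),
    n = c(20L, 20L), ageMean = 50, ageSd = 5, maleFrac = 0.5,
    eduMean = 14, eduSd = 2, stringsAsFactors = FALSE
  )
  cohortConfig(
    groupSizes = gs, markers = mk, ordering = c("m_a", "m_b", "m_c"),
    stageDistribution = list(control = c(0, 0), presymptomatic = c(0, 0.5),
                             symptomatic = c(1, 1)),
    seed = seed
  )
}

# Strong-signal five-marker configuration for ordering-recovery sanity:
# latent stages spread across the carrier range and 3-sd component
# separation, so the central ordering is identifiable.
strongSignalConfig <- function(seed = 1L) {
  mk <- data.frame(
    name = paste0("bm_", letters[1:5]),
    direction = "increase", transform = "identity",
    normalMean = 0, normalSd = 1, abnormalMean = 3, abnormalSd = 1,
    ageEffect = 0, sexEffect = 0, missingRate = 0,
    threshold = NA_real_, stringsAsFactors = FALSE
  )
  gs <- data.frame(
    genotype = c("noncarrier", "GRN", "GRN"),
    status = c("control", "presymptomatic", "symptomatic"),
    n = c(150L, 150L, 150L), ageMean = c(47, 47, 64), ageSd = c(13, 12, 8),
    maleFrac = 0.45, eduMean = 14, eduSd = 3, stringsAsFactors = FALSE
  )
  cohortConfig(
    groupSizes = gs, markers = mk, ordering = paste0("bm_", letters[1:5]),
    stageDistribution = list(control = c(0, 0), presymptomatic = c(0, 0.7),
                             symptomatic = c(0.3, 1)),
    seed = seed
  )
}

# Random posterior matrices for ordering property tests.
randomPosteriorMatrix <- function(n, K, seed) {
  withr_seed <- seed
  set.seed(withr_seed)
  P <- matrix(runif(n * K), n, K, dimnames = list(NULL, paste0("mk", seq_len(K))))
  P
}

# Independent rank arithmetic used as the oracle for Dunn's test: ranks are
# built from an explicit sort, the tie term from run lengths of sorted
# values.
bruteForceDunnZ <- function(g1, g2, allGroups) {
  x <- unlist(allGroups, use.names = FALSE)
  N <- length(x)
  sorted <- sort(x)
  rankOf <- function(v) mean(which(sorted == v))
  r <- vapply(x, rankOf, 0)
  gLab <- rep(seq_along(allGroups), lengths(allGroups))
  tie <- rle(sorted)$lengths
  v0 <- N * (N + 1) / 12 - sum(tie^3 - tie) / (12 * (N - 1))
  m1 <- mean(r[gLab == g1]); m2 <- mean(r[gLab == g2])
  (m1 - m2) / sqrt(v0 * (1 / sum(gLab == g1) + 1 / sum(gLab == g2)))
}

kendallTauDistance <- function(a, b) {
  stopifnot(setequal(a, b))
  K <- length(a)
  d <- 0L
  for (i in seq_len(K - 1L)) {
    for (j in (i + 1L):K) {
      d <- d + (sign(match(a[i], b) - match(a[j], b)) != sign(i - j))
    }
  }
  d
}
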