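test_that("default cohort reproduces the published cell sizes", {
  coh <- simulateCohort(cohortConfig(seed = 11))
  df <- cohortTable(coh)
  expect_equal(sum(df$status == "control"), 298)
  expect_equal(sum(df$genotype == "GRN" & df$status == "presymptomatic"), 137)
  expect_equal(sum(df$genotype == "GRN" & df$status == "symptomatic"), 45)
  expect_equal(nrow(df), 763)
  expect_true(all(df$visit_time == 0))
  expect_true(all(df$status[df$genotype == "noncarrier"] == "control"))
})

test_that("identical seed and config give byte-identical cohorts", {
  a <- cohortTable(simulateCohort(cohortConfig(seed = 21)))
  b <- cohortTable(simulateCohort(cohortConfig(seed = 21)))
  expect_identical(a, b)
  c_ <- cohortTable(simulateCohort(cohortConfig(seed = 22)))
  expect_false(identical(a, c_))
})

test_that("stage concentrated at zero draws every biomarker from its normal component", {
  cfg <- cohortConfig(
    markers = noConfoundMarkers(),
    stageDistribution = list(control = c(0, 0), presymptomatic = c(0, 0),
                             symptomatic = c(0, 0)),
    seed = 31
  )
  df <- cohortTable(simulateCohort(cfg))
  mk <- cfg$markers
  for (i in seq_len(nrow(mk))) {
    v <- df[[mk$name[i]]]
    z <- if (mk$transform[i] == "log10") log10(v) else v
    n <- sum(!is.na(z))
    se <- mk$normalSd[i] / sqrt(n)
    expect_lt(abs(mean(z, na.rm = TRUE) - mk$normalMean[i]), 3 * se + 1e-12)
  }
})

test_that("degenerate zero-noise config puts patients exactly at abnormal means", {
  cfg <- degenerateThreeMarkerConfig()
  df <- cohortTable(simulateCohort(cfg))
  pat <- df[df$status == "symptomatic", ]
  ctl <- df[df$status == "control", ]
  expect_true(all(pat$m_a == 5 & pat$m_b == 6 & pat$m_c == 7))
  expect_true(all(ctl$m_a == 0 & ctl$m_b == 1 & ctl$m_c == 2))
})

test_that("event prevalence is non-increasing along the ground-truth ordering", {
  cfg <- degenerateThreeMarkerConfig()
  cfg$stageDistribution$symptomatic <- c(0, 1)   # spread stages over the cascade
  df <- cohortTable(simulateCohort(cfg))
  # zero component sds: abnormal draws are exactly at the abnormal means
  prev <- c(mean(df$m_a == 5), mean(df$m_b == 6), mean(df$m_c == 7))
  expect_true(all(diff(prev) <= 0))
  expect_true(prev[1] > 0)
})

test_that("realized missingness stays within the binomial 99% interval", {
  gs <- defaultGroupSizes()[1, ]
  gs$n <- 10000L
  df <- cohortTable(simulateCohort(cohortConfig(groupSizes = gs, seed = 41)))
  for (m in c("nfl", "gfap")) {
    rate <- markerManifest()$missingRate[markerManifest()$name == m]
    half <- 2.576 * sqrt(rate * (1 - rate) / nrow(df))
    expect_lt(abs(mean(is.na(df[[m]])) - rate), half + 1e-12)
  }
  expect_false(anyNA(df$wmh_total))
})

test_that("group moments match the stage-weighted mixture with confounds off", {
  gs <- data.frame(
    genotype = "GRN", status = "symptomatic", n = 10000L,
    ageMean = 64, ageSd = 8, maleFrac = 0.45, eduMean = 12, eduSd = 3,
    stringsAsFactors = FALSE
  )
  cfg <- cohortConfig(groupSizes = gs, markers = noConfoundMarkers(), seed = 51)
  df <- cohortTable(simulateCohort(cfg))
  # nfl sits at position 5 of 9: abnormal iff stage > 0.5, so
  # P(abnormal | symptomatic ~ U(0.4, 1)) = 5/6
  p <- 5 / 6
  mu <- (1 - p) * 1.0 + p * 1.5
  sdMix <- sqrt(0.25^2 + p * (1 - p) * 0.5^2)
  z <- log10(df$nfl)
  n <- sum(!is.na(z))
  expect_lt(abs(mean(z, na.rm = TRUE) - mu), 3 * sdMix / sqrt(n))
})

test_that("configuration errors are raised for malformed configs", {
  mk <- markerManifest()
  mk$normalSd[1] <- -1
  expect_error(cohortConfig(markers = mk), class = "ftdConfigError")
  expect_error(cohortConfig(ordering = c("wmh_total", "wmh_total")),
               class = "ftdConfigError")
  mk2 <- markerManifest()
  mk2$missingRate[2] <- 1.5
  expect_error(cohortConfig(markers = mk2), class = "ftdConfigError")
  expect_error(longitudinalConfig(visitsPerSubject = 1),
               class = "ftdConfigError")
})

test_that("ground-truth accessor returns the configured permutation", {
  cfg <- cohortConfig(seed = 61)
  expect_identical(eventSequence(groundTruthOrdering(cfg)), cfg$ordering)
  rev_cfg <- cohortConfig(ordering = rev(cfg$ordering), seed = 61)
  expect_identical(eventSequence(groundTruthOrdering(rev_cfg)), rev(cfg$ordering))
  coh <- simulateCohort(cfg)
  expect_identical(eventSequence(groundTruthOrdering(coh)), cfg$ordering)
})

test_that("zero couplings, zero base slopes and zero noise reproduce baseline", {
  coh <- smallCohort()
  cp <- defaultCoupling() * 0
  lcfg <- longitudinalConfig(
    nPresymptomatic = 30L, nSymptomatic = 15L, coupling = cp,
    baseSlopes = defaultBaseSlopes() * 0, noiseSd = 0, seed = 71
  )
  long <- simulateLongitudinal(lcfg, coh)
  df <- cohortTable(long)
  traj <- names(defaultBaseSlopes())
  for (id in unique(df$subject_id)[1:5]) {
    sub <- df[df$subject_id == id, ]
    for (m in traj) {
      expect_equal(sub[[m]], rep(sub[[m]][1], nrow(sub)), tolerance = 1e-8)
    }
  }
})

test_that("WMH coupling steepens amygdala decline for high-WMH subjects", {
  coh <- simulateCohort(cohortConfig(seed = 81))
  cp <- defaultCoupling() * 0
  cp["wmh_total", "amygdala"] <- -0.3
  lcfg <- longitudinalConfig(coupling = cp, baseSlopes = defaultBaseSlopes() * 0,
                             noiseSd = 0, seed = 82)
  long <- simulateLongitudinal(lcfg, coh)
  df <- cohortTable(long)
  base <- df[df$visit_time == 0, ]
  slopes <- vapply(split(df, df$subject_id), function(s) {
    annualizedChange(s$visit_time, s$amygdala)
  }, 0)
  wmh <- log10(base$wmh_total[match(names(slopes), base$subject_id)])
  hi <- slopes[wmh >= quantile(wmh, 0.9)]
  lo <- slopes[wmh <= quantile(wmh, 0.1)]
  expect_true(max(hi) < min(lo))   # strictly steeper decline in the top decile
})

test_that("default longitudinal design follows 83 carriers with repeat visits", {
  coh <- simulateCohort(cohortConfig(seed = 91))
  long <- simulateLongitudinal(longitudinalConfig(seed = 92), coh)
  df <- cohortTable(long)
  visits <- table(df$subject_id)
  expect_equal(length(visits), 83L)
  expect_true(all(visits >= 2))
  expect_equal(sum(df$visit_time == 0), 83L)
  # determinism
  df2 <- cohortTable(simulateLongitudinal(longitudinalConfig(seed = 92), coh))
  expect_identical(df, df2)
})
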