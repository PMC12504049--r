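# Independent step-up oracle for Benjamini-Hochberg.
bruteForceBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  pmin(adj, 1)[order(o)]
}

test_that("annualized change reduces to the expected slopes", {
  expect_equal(annualizedChange(c(0, 2), c(1.0, 0.5)), -0.25)
  expect_equal(annualizedChange(c(0, 1, 2), c(3, 3, 3)), 0)
  expect_equal(annualizedChange(c(0, 1, 2), c(0, 1, 2)), 1)
  expect_true(is.na(annualizedChange(c(0), c(1))))
  expect_true(is.na(annualizedChange(c(0, 1, 2), c(1, NA, NA))))
})

test_that("BH adjustment matches the printed fixture and the step-up oracle", {
  expect_equal(fdrCorrect(c(0.006, 0.023, 0.025)), c(0.018, 0.025, 0.025),
               tolerance = 1e-12)
  expect_equal(fdrCorrect(rep(1, 4)), rep(1, 4))
  expect_equal(fdrCorrect(0.04), 0.04)
  set.seed(701)
  for (i in 1:25) {
    p <- round(runif(sample(1:10, 1)), 3)
    expect_equal(fdrCorrect(p), bruteForceBH(p), tolerance = 1e-12)
  }
  expect_error(fdrCorrect(c(0.5, 1.2)), class = "ftdValueError")
  expect_error(fdrCorrect(c(-0.1)), class = "ftdValueError")
})

test_that("the pair model recovers an exact linear relationship", {
  set.seed(702)
  n <- 40
  d <- data.frame(
    predictor_baseline = rnorm(n),
    age = runif(n, 30, 70),
    sex = sample(c("male", "female"), n, replace = TRUE),
    education = runif(n, 8, 20),
    nfl_z = rnorm(n),
    response_baseline = rnorm(n)
  )
  d$rate <- 2 * d$predictor_baseline
  res <- suppressWarnings(fitPairModel(d))   # lm warns on a perfect fit
  expect_equal(res$coefficient, 2, tolerance = 1e-10)
  expect_equal(res$n, n)
  expect_lt(res$p, 1e-10)
})

test_that("pair-model preconditions raise classed errors", {
  d <- data.frame(
    rate = rnorm(5), predictor_baseline = rnorm(5), age = runif(5, 30, 70),
    sex = rep("male", 5), education = 12, nfl_z = rnorm(5),
    response_baseline = rnorm(5)
  )
  expect_error(fitPairModel(d), class = "ftdInsufficientDataError")
  set.seed(703)
  d2 <- data.frame(
    rate = rnorm(20), predictor_baseline = rnorm(20), age = runif(20, 30, 70),
    sex = sample(c("male", "female"), 20, replace = TRUE),
    education = rep(12, 20), nfl_z = rnorm(20), response_baseline = rnorm(20)
  )
  d2$response_baseline <- d2$predictor_baseline   # collinear
  expect_error(fitPairModel(d2), regexp = "collinear",
               class = "ftdRankDeficiencyError")
  expect_error(fitPairModel(d2[, -1]), class = "ftdSchemaError")
})

test_that("the association matrix covers 48 directed pairs deterministically", {
  coh <- simulateCohort(cohortConfig(seed = 711))
  long <- simulateLongitudinal(longitudinalConfig(seed = 712), coh)
  cl <- crossLagMatrix(long)
  expect_equal(nrow(cl$results), 48L)
  expect_equal(sum(cl$results$direction == "forward"), 24L)
  expect_true(all(cl$results$p_fdr >= cl$results$p_raw - 1e-15))
  cl2 <- crossLagMatrix(long)
  expect_identical(cl$results, cl2$results)
  expect_identical(cl$tMatrix, cl2$tMatrix)
  expect_equal(dim(cl$tMatrix), c(10L, 10L))
})

test_that("default couplings are detected forward and not in reverse", {
  coh <- simulateCohort(cohortConfig(seed = 721))
  long <- simulateLongitudinal(longitudinalConfig(seed = 722), coh)
  cl <- crossLagMatrix(long)
  res <- cl$results
  sigF <- res[res$significant & res$direction == "forward", ]
  expect_setequal(sigF$response, c("amygdala", "hippocampus", "cingulate"))
  expect_true(all(sigF$predictor == "wmh_total"))
  expect_true(all(sigF$coefficient < 0))
  expect_false(any(res$significant & res$direction == "reverse"))
})

test_that("dropping one subject's follow-ups leaves other rates unchanged", {
  coh <- simulateCohort(cohortConfig(seed = 731))
  long <- simulateLongitudinal(
    longitudinalConfig(nPresymptomatic = 25, nSymptomatic = 13, seed = 732), coh
  )
  df <- cohortTable(long)
  victim <- unique(df$subject_id)[1]
  df2 <- df[!(df$subject_id == victim & df$visit_time > 0), ]
  # the victim now has a single visit: its rate is undefined and it drops
  # out of every model, while all other subjects' raw slopes are unchanged
  ratesOf <- function(tab) {
    vapply(split(tab, tab$subject_id), function(s) {
      annualizedChange(s$visit_time, s$amygdala)
    }, 0)
  }
  r1 <- ratesOf(df)
  r2 <- ratesOf(df2)
  others <- setdiff(names(r1), victim)
  expect_equal(r1[others], r2[others], tolerance = 1e-12)
  expect_true(is.na(r2[victim]))
  cl1 <- crossLagMatrix(df)
  cl2 <- crossLagMatrix(df2)
  expect_true(all(cl2$results$n <= cl1$results$n))
  expect_true(all(is.finite(cl1$results$t)))
})

test_that("the predictor coefficient converges to the coupling as noise vanishes", {
  gs <- data.frame(
    genotype = c("noncarrier", "GRN", "GRN"),
    status = c("control", "presymptomatic", "symptomatic"),
    n = c(30L, 400L, 100L), ageMean = c(47, 47, 64), ageSd = c(13, 12, 8),
    maleFrac = 0.45, eduMean = 14, eduSd = 3, stringsAsFactors = FALSE
  )
  mk <- noConfoundMarkers()
  mk$missingRate <- 0
  coh <- simulateCohort(cohortConfig(groupSizes = gs, markers = mk, seed = 741))
  cp <- defaultCoupling() * 0
  cp["wmh_total", "amygdala"] <- -0.3
  long <- simulateLongitudinal(
    longitudinalConfig(nPresymptomatic = 400L, nSymptomatic = 100L,
                       coupling = cp, noiseSd = 1e-4, seed = 742),
    coh
  )
  cl <- crossLagMatrix(long)
  est <- cl$results[cl$results$predictor == "wmh_total" &
                      cl$results$response == "amygdala", "coefficient"]
  expect_lt(abs(est - (-0.3)), 0.01)
})
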