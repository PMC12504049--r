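test_that("subjects are ranked by descending posterior with canonical ties", {
  p <- c(A = 0.9, B = 0.2, C = 0.7)
  expect_equal(subjectOrdering(p), c("A", "C", "B"))
  expect_equal(subjectOrdering(c(B = 0.5, A = 0.5, C = 0.5)), c("A", "B", "C"))
  expect_equal(subjectOrdering(c(A = 0.9, B = NA, C = 0.2)), c("A", "C"))
  expect_null(subjectOrdering(c(A = 0.9, B = NA, C = NA)))
})

test_that("ordering cost matches hand-computed cases", {
  # every subject concordant with sigma: zero cost
  P <- matrix(c(0.9, 0.5, 0.1, 0.8, 0.6, 0.2), nrow = 2, byrow = TRUE,
              dimnames = list(NULL, c("A", "B", "C")))
  expect_equal(orderingCost(c("A", "B", "C"), P), 0)
  # single subject, P = (1, 0), reversed sigma: one discordant pair, weight 1
  P1 <- matrix(c(1, 0), 1, dimnames = list(NULL, c("A", "B")))
  expect_equal(orderingCost(c("B", "A"), P1), 1)
  expect_equal(orderingCost(c("A", "B"), P1), 0)
})

test_that("cost of an ordering plus its reverse equals the pairwise spread", {
  set.seed(501)
  for (i in 1:10) {
    P <- randomPosteriorMatrix(n = 15, K = 5, seed = 500 + i)
    sigma <- sample(colnames(P))
    total <- 0
    for (a in 1:4) for (b in (a + 1):5) {
      total <- total + sum(abs(P[, a] - P[, b]))
    }
    expect_equal(orderingCost(sigma, P) + orderingCost(rev(sigma), P), total,
                 tolerance = 1e-10)
  }
})

test_that("cost is equivariant under biomarker relabeling", {
  P <- randomPosteriorMatrix(n = 20, K = 6, seed = 511)
  sigma <- sample(colnames(P))
  relabel <- setNames(paste0("new", seq_len(6)), colnames(P))
  P2 <- P
  colnames(P2) <- relabel[colnames(P)]
  expect_equal(orderingCost(sigma, P), orderingCost(unname(relabel[sigma]), P2),
               tolerance = 1e-12)
})

test_that("two-biomarker estimation is trivially ordered by posteriors", {
  P <- matrix(rep(c(0.9, 0.1), each = 10), ncol = 2,
              dimnames = list(NULL, c("first", "second")))
  est <- estimateOrdering(P)
  expect_equal(eventSequence(est), c("first", "second"))
  expect_equal(est@cost, 0)
  expect_equal(est@method, "exhaustive")
})

test_that("greedy search attains the exhaustive minimum on random instances", {
  agree <- 0L
  for (i in 1:40) {
    P <- randomPosteriorMatrix(n = 12, K = 6, seed = 520 + i)
    exhaustive <- estimateOrdering(P, exhaustiveMax = 7)
    greedy <- estimateOrdering(P, exhaustiveMax = 0, restarts = 10, seed = i)
    expect_equal(greedy@method, "greedy")
    agree <- agree + (abs(greedy@cost - exhaustive@cost) < 1e-9)
  }
  expect_gte(agree, 38L)   # >= 95% oracle equivalence
})

test_that("the central ordering is recovered under a strong event signal", {
  recovered <- 0L
  for (s in 1:5) {
    cfg <- strongSignalConfig(seed = 530 + s)
    fit <- runDEBM(simulateCohort(cfg), markers = cfg$markers[, c("name", "direction", "transform")],
                   genotypes = c("noncarrier", "GRN"), bootstrap = 0, seed = s)
    recovered <- recovered +
      (kendallTauDistance(eventSequence(fit), cfg$ordering) == 0)
  }
  expect_gte(recovered, 4L)
})

test_that("subjects with fewer than two observed biomarkers are excluded", {
  P <- randomPosteriorMatrix(n = 8, K = 4, seed = 541)
  P[1, ] <- NA
  P[2, 2:4] <- NA
  est <- estimateOrdering(P)
  expect_equal(attr(est, "excludedSubjects"), 2L)
  allNA <- matrix(NA_real_, 3, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_error(estimateOrdering(allNA), class = "ftdInsufficientDataError")
})

test_that("bootstrap position counts conserve replicate mass deterministically", {
  cfg <- strongSignalConfig(seed = 551)
  coh <- simulateCohort(cfg)
  df <- cohortTable(coh)
  values <- as.matrix(df[, cfg$markers$name])
  rownames(values) <- df$subject_id
  directions <- setNames(cfg$markers$direction, cfg$markers$name)
  pv <- bootstrapOrdering(values, df$status, directions, B = 20, seed = 7)
  expect_true(all(rowSums(positionCounts(pv)) == 20))
  expect_true(all(colSums(positionCounts(pv)) == 20))
  pv2 <- bootstrapOrdering(values, df$status, directions, B = 20, seed = 7)
  expect_identical(positionCounts(pv), positionCounts(pv2))
})

test_that("near-deterministic posteriors concentrate bootstrap mass on the diagonal", {
  set.seed(561)
  n <- 60
  # ideal data: every subject far into one component per biomarker
  stageIdx <- sample(0:3, n, replace = TRUE)
  values <- sapply(1:3, function(k) ifelse(stageIdx >= k, 10, 0) + rnorm(n, 0, 0.05))
  colnames(values) <- c("e1", "e2", "e3")
  labels <- c("control", "presymptomatic", "symptomatic", "symptomatic")[stageIdx + 1]
  directions <- c(e1 = "increase", e2 = "increase", e3 = "increase")
  pv <- bootstrapOrdering(values, labels, directions, B = 25, seed = 9)
  expect_equal(pv@ordering, c("e1", "e2", "e3"))
  expect_true(all(diag(positionCounts(pv)) == 25))
})
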