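test_that("Kruskal-Wallis H matches the closed form on the three-group fixture", {
  kw <- kruskalWallisH(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(kw$H, 7.2, tolerance = 1e-12)
  expect_equal(kw$df, 2L)
  expect_equal(kw$p, pchisq(7.2, 2, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("identical or fully tied groups give H = 0 and p = 1", {
  kw <- kruskalWallisH(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(kw$H, 0, tolerance = 1e-12)
  expect_equal(kw$p, 1, tolerance = 1e-12)
  kwT <- kruskalWallisH(list(c(1, 1, 1), c(1, 1, 1)))
  expect_equal(kwT$H, 0)
  expect_equal(kwT$p, 1)
})

test_that("H is invariant under strictly monotone transforms", {
  set.seed(7)
  for (i in 1:20) {
    groups <- lapply(1:3, function(k) rnorm(sample(4:9, 1), mean = k / 2))
    h1 <- kruskalWallisH(groups)$H
    h2 <- kruskalWallisH(lapply(groups, function(g) exp(3 * g) - 1))$H
    expect_equal(h1, h2, tolerance = 1e-10)
  }
})

test_that("Dunn z agrees with brute-force rank arithmetic on small instances", {
  set.seed(11)
  for (i in 1:30) {
    sizes <- sample(2:5, 3, replace = TRUE)
    while (sum(sizes) > 12) sizes <- sample(2:5, 3, replace = TRUE)
    # integer draws so ties occur regularly
    groups <- lapply(sizes, function(n) sample(1:6, n, replace = TRUE))
    if (length(unique(unlist(groups))) == 1L) next
    names(groups) <- c("a", "b", "c")
    dn <- dunnPosthoc(groups)
    for (r in seq_len(nrow(dn))) {
      i1 <- match(dn$group1[r], names(groups))
      i2 <- match(dn$group2[r], names(groups))
      expect_equal(dn$z[r], bruteForceDunnZ(i1, i2, groups), tolerance = 1e-10)
    }
  }
})

test_that("Dunn post hoc handles the printed toy groups and ties", {
  groups <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  dn <- dunnPosthoc(groups)
  # brute force for the extreme pair: mean ranks 2 and 8, variance N(N+1)/12
  zExpected <- (2 - 8) / sqrt((9 * 10 / 12) * (1 / 3 + 1 / 3))
  expect_equal(dn$z[dn$group1 == "a" & dn$group2 == "c"], zExpected,
               tolerance = 1e-12)
  same <- dunnPosthoc(list(x = c(1, 2, 3), y = c(1, 2, 3)))
  expect_equal(same$z, 0)
  expect_equal(same$p_raw, 1)
})

test_that("Bonferroni correction caps at one and never decreases p", {
  groups <- list(a = c(1, 3, 2), b = c(2, 1, 3), c = c(3, 2, 1))
  dn <- dunnPosthoc(groups, familySize = 3)
  expect_true(all(dn$p_bonferroni >= dn$p_raw))
  expect_true(all(dn$p_bonferroni <= 1))
  # raw p of 0.4 with family 3 saturates at 1
  expect_equal(min(1, 0.4 * 3), 1)
  expect_true(all(dn$p_bonferroni[dn$p_raw >= 1 / 3] == 1))
})

test_that("Cliff's delta matches pair enumeration and is antisymmetric", {
  expect_equal(cliffsDelta(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cliffsDelta(c(4, 5, 6), c(1, 2, 3)), 1)
  # four pairs, one tied: #(a>b) = 0, #(a<b) = 3, so delta = -3/4
  expect_equal(cliffsDelta(c(1, 2), c(2, 3)), -0.75)
  set.seed(13)
  for (i in 1:20) {
    a <- sample(1:10, 5, replace = TRUE)
    b <- sample(1:10, 4, replace = TRUE)
    expect_equal(cliffsDelta(a, b), -cliffsDelta(b, a), tolerance = 1e-12)
    expect_true(abs(cliffsDelta(a, b)) <= 1)
  }
  expect_error(cliffsDelta(numeric(0), 1:3), class = "ftdValueError")
})

test_that("regional analysis emits one comparison table per region", {
  df <- cohortTable(smallCohort(seed = 311))
  controls <- df[df$status == "control", ]
  adj <- do.call(rbind, lapply(
    c("total", "lh_frontal", "rh_frontal"), function(rg) {
      col <- if (rg == "total") "wmh_total" else paste0("wmh_", rg)
      m <- fitNormativeModel(log10(controls[[col]]), controls$age, controls$sex,
                             region = rg)
      adjustWmh(df, m, region = rg)
    }
  ))
  res <- regionalWmhAnalysis(adj)
  nGroups <- length(unique(paste(adj$genotype, adj$status)))
  expect_equal(nrow(res), 3 * choose(nGroups, 2))
  expect_equal(attr(res, "familySize"), 3 * choose(nGroups, 2))
  expect_true(all(res$p_bonferroni >= res$p_raw - 1e-15))
  bad <- adj
  bad$region[1] <- "midbrain"
  expect_error(regionalWmhAnalysis(bad), class = "ftdConfigError")
})

test_that("elevated symptomatic GRN frontal WMH is detected against controls", {
  # generator defaults already encode frontal-dominant WMH abnormality
  df <- cohortTable(simulateCohort(cohortConfig(seed = 321)))
  controls <- df[df$status == "control", ]
  m <- fitNormativeModel(log10(controls$wmh_lh_frontal), controls$age,
                         controls$sex, region = "lh_frontal")
  adj <- adjustWmh(df, m, region = "lh_frontal")
  res <- regionalWmhAnalysis(adj)
  row <- res[(res$group1 == "control" & res$group2 == "GRN_symptomatic") |
               (res$group2 == "control" & res$group1 == "GRN_symptomatic"), ]
  expect_lt(row$p_bonferroni, 0.05)
  delta <- cliffsDelta(
    adj$adjusted[adj$genotype == "GRN" & adj$status == "symptomatic"],
    adj$adjusted[adj$status == "control"]
  )
  expect_gt(delta, 0.2)
})
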