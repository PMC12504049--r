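# Nonparametric group comparison: Kruskal-Wallis, Dunn's post hoc test with
# tie correction, Bonferroni correction, and Cliff's delta effect sizes.

checkGroups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    ftdStop("ftdConfigError", "need a list of at least two groups")
  }
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (any(lengths(groups) == 0L)) {
    ftdStop("ftdValueError", "every group must contain at least one value")
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  groups
}

#' Kruskal-Wallis test across groups
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square p-value on
#' (number of groups - 1) degrees of freedom, via [stats::kruskal.test()].
#' Fully tied data are an H of 0 with p = 1.
#'
#' @param groups list of numeric vectors (NAs dropped).
#' @return list with `H`, `p`, `df`.
#' @examples
#' kruskalWallisH(list(1:3, 4:6, 7:9))$H  # 7.2
#' @export
kruskalWallisH <- function(groups) {
  groups <- checkGroups(groups)
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  if (length(unique(x)) == 1L) {
    return(list(H = 0, p = 1, df = length(groups) - 1L))
  }
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), p = kt$p.value, df = unname(kt$parameter))
}

#' Dunn's post hoc pairwise comparisons
#'
#' Pairwise z statistics from mean-rank differences on the pooled ranking,
#' with the standard tie-corrected variance
#' `(N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j)` where
#' `T = sum(t^3 - t)` over tie groups. Raw p-values are two-sided normal;
#' Bonferroni p = min(1, p * familySize).
#'
#' @param groups named list of numeric vectors.
#' @param familySize number of comparisons in the Bonferroni family; defaults
#'   to the number of pairs formed here.
#' @return data.frame with `group1`, `group2`, `n1`, `n2`, `z`, `p_raw`,
#'   `p_bonferroni`.
#' @export
dunnPosthoc <- function(groups, familySize = NULL) {
  groups <- checkGroups(groups)
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  ties <- table(x)
  tieTerm <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tieTerm
  meanRanks <- tapply(r, g, mean)
  ns <- lengths(groups)
  pairs <- utils::combn(names(groups), 2L)
  familySize <- familySize %||% ncol(pairs)
  if (familySize < ncol(pairs)) {
    ftdStop("ftdConfigError", "familySize must cover at least the pairs tested")
  }
  out <- data.frame(
    group1 = pairs[1, ], group2 = pairs[2, ],
    n1 = unname(ns[pairs[1, ]]), n2 = unname(ns[pairs[2, ]]),
    stringsAsFactors = FALSE
  )
  se <- sqrt(v0 * (1 / out$n1 + 1 / out$n2))
  diff <- unname(meanRanks[out$group1] - meanRanks[out$group2])
  out$z <- ifelse(se > 0, diff / se, 0)
  out$p_raw <- 2 * stats::pnorm(-abs(out$z))
  out$p_bonferroni <- pmin(1, out$p_raw * familySize)
  out
}

#' Cliff's delta effect size
#'
#' `delta = (#(a_i > b_j) - #(a_i < b_j)) / (n_a n_b)`, in \[-1, 1\].
#'
#' @param a,b numeric samples (NAs dropped).
#' @return the effect size, positive when `a` tends to exceed `b`.
#' @examples
#' cliffsDelta(c(4, 5, 6), c(1, 2, 3))  # 1
#' cliffsDelta(c(1, 2), c(2, 3))        # -0.75 (one tied pair of four)
#' @export
cliffsDelta <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) {
    ftdStop("ftdValueError", "both samples must be nonempty")
  }
  mean(sign(outer(a, b, "-")))
}

#' Group comparison table for one variable
#'
#' Kruskal-Wallis across all groups plus Dunn's pairwise post hoc tests and
#' Cliff's delta per pair, Bonferroni-corrected within the given family.
#'
#' @param groups named list of numeric vectors.
#' @param familySize Bonferroni family size (default: pairs tested here).
#' @return data.frame of pairwise rows (`group1`, `group2`, `z`, `p_raw`,
#'   `p_bonferroni`, `delta`, ...) with the overall `H`, `p_kw` and `df`
#'   repeated on every row.
#' @export
compareGroups <- function(groups, familySize = NULL) {
  groups <- checkGroups(groups)
  kw <- kruskalWallisH(groups)
  dn <- dunnPosthoc(groups, familySize)
  dn$delta <- mapply(function(g1, g2) cliffsDelta(groups[[g1]], groups[[g2]]),
                     dn$group1, dn$group2)
  dn$H <- kw$H
  dn$p_kw <- kw$p
  dn$df <- kw$df
  dn
}

#' Regional WMH group comparison
#'
#' Runs [compareGroups()] on adjusted WMH values per region, with one
#' Bonferroni family spanning every pairwise contrast in the whole regional
#' table (pairs x regions), mirroring a single corrected analysis table.
#'
#' @param adjusted data.frame from [adjustWmh()] stacked over regions
#'   (columns `region`, `adjusted`, plus a grouping column).
#' @param grouping name of the column holding group labels (default
#'   `"group"`; a convenience `genotype_status` label is built when absent).
#' @return data.frame with one row per region and pairwise contrast.
#' @export
regionalWmhAnalysis <- function(adjusted, grouping = "group") {
  if (!grouping %in% colnames(adjusted)) {
    if (all(c("genotype", "status") %in% colnames(adjusted))) {
      adjusted[[grouping]] <- ifelse(
        adjusted$status == "control", "control",
        paste(adjusted$genotype, adjusted$status, sep = "_")
      )
    } else {
      ftdStop("ftdSchemaError", sprintf("no grouping column '%s'", grouping))
    }
  }
  regions <- unique(adjusted$region)
  bad <- setdiff(regions, WMH_REGIONS)
  if (length(bad)) {
    ftdStop("ftdConfigError", sprintf(
      "unknown region label(s): %s", paste(bad, collapse = ", ")
    ))
  }
  nGroups <- length(unique(adjusted[[grouping]]))
  family <- choose(nGroups, 2) * length(regions)
  ftdLog("regionalWmhAnalysis: Bonferroni family size %d", family)
  res <- lapply(regions, function(rg) {
    sub <- adjusted[adjusted$region == rg, ]
    groups <- split(sub$adjusted, sub[[grouping]])
    cmp <- compareGroups(groups, familySize = family)
    cbind(region = rg, cmp, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "familySize") <- family
  rownames(out) <- NULL
  out
}
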