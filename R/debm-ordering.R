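# Central-ordering estimation: probability-weighted Kendall aggregation of
# per-subject posterior rankings, exhaustive for small K, greedy with
# restarts otherwise, and the bootstrap positional-variance diagram.

#' Per-subject biomarker ranking
#'
#' Observed biomarkers sorted by descending posterior abnormality
#' probability; ties are broken by canonical (alphabetical) biomarker-name
#' order. Subjects with fewer than two observed biomarkers return `NULL`.
#'
#' @param p named numeric vector of posteriors (NA = missing).
#' @return character vector of observed biomarker names, most abnormal
#'   first, or `NULL`.
#' @export
subjectOrdering <- function(p) {
  obs <- !is.na(p)
  if (sum(obs) < 2L) return(NULL)
  nm <- names(p)[obs]
  v <- p[obs]
  canon <- match(nm, canonicalOrder(nm))
  nm[order(-v, canon)]
}

# D[k, l] = sum over subjects of max(P_il - P_ik, 0): the cost contributed by
# placing k before l. Pairs with a missing member contribute nothing.
pairCostMatrix <- function(P) {
  K <- ncol(P)
  D <- matrix(0, K, K, dimnames = list(colnames(P), colnames(P)))
  for (k in seq_len(K)) {
    for (l in seq_len(K)) {
      if (k == l) next
      D[k, l] <- sum(pmax(P[, l] - P[, k], 0), na.rm = TRUE)
    }
  }
  D
}

permutationCost <- function(perm, D) {
  K <- length(perm)
  s <- 0
  for (a in seq_len(K - 1L)) {
    s <- s + sum(D[perm[a], perm[(a + 1L):K]])
  }
  s
}

#' Cost of an event ordering
#'
#' Probability-weighted Kendall distance between the ordering and all
#' per-subject posterior rankings: the sum over subjects and over observed
#' biomarker pairs discordant with the subject's posterior-sorted ranking of
#' `|P_ik - P_il|`. Zero when every subject's ranking matches the ordering;
#' for any ordering sigma, `cost(sigma) + cost(rev(sigma))` equals the total
#' pairwise posterior spread.
#'
#' @param ordering an [EventOrdering-class] or character vector of biomarker
#'   names, earliest first.
#' @param P subjects x K posterior matrix with named columns.
#' @return non-negative cost.
#' @export
orderingCost <- function(ordering, P) {
  if (methods::is(ordering, "EventOrdering")) ordering <- ordering@ordering
  if (!setequal(ordering, colnames(P)) || anyDuplicated(ordering)) {
    ftdStop("ftdConfigError", "ordering must be a permutation of the biomarker columns")
  }
  D <- pairCostMatrix(P)
  permutationCost(match(ordering, colnames(P)), D)
}

allPermutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- allPermutations(n - 1L)
  rows <- nrow(sub)
  out <- matrix(0L, n * rows, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    idx <- (k - 1L) * rows + seq_len(rows)
    out[idx, 1L] <- k
    out[idx, -1L] <- matrix(rest[sub], rows)
  }
  out
}

localSearch <- function(perm, D) {
  K <- length(perm)
  cost <- permutationCost(perm, D)
  repeat {
    best <- cost
    bestPerm <- NULL
    for (i in seq_len(K - 1L)) {
      for (j in (i + 1L):K) {
        p2 <- perm
        p2[c(i, j)] <- p2[c(j, i)]
        c2 <- permutationCost(p2, D)
        if (c2 < best - 1e-12) {
          best <- c2
          bestPerm <- p2
        }
      }
    }
    if (is.null(bestPerm)) return(list(perm = perm, cost = cost))
    perm <- bestPerm
    cost <- best
  }
}

#' Estimate the central event ordering
#'
#' Minimizes [orderingCost()] over permutations of the admitted biomarkers.
#' For K up to `exhaustiveMax` (default 7) the minimization is exhaustive
#' over all K! permutations; beyond that, a greedy best-improving pairwise
#' swap search is run from a descending-column-mean initialization plus
#' `restarts - 1` random restarts. Equal-cost solutions are resolved to the
#' lexicographically smallest permutation in canonical name order. Subjects
#' with fewer than two observed biomarkers cannot constrain the ordering and
#' are counted in attribute `"excludedSubjects"`.
#'
#' @param P subjects x K posterior matrix with named columns.
#' @param exhaustiveMax largest K solved exhaustively.
#' @param restarts number of greedy starts (first is deterministic).
#' @param seed optional seed for the random restarts.
#' @return an [EventOrdering-class].
#' @export
estimateOrdering <- function(P, exhaustiveMax = 7L, restarts = 10L, seed = NULL) {
  if (is.null(colnames(P)) || ncol(P) < 2L) {
    ftdStop("ftdConfigError", "P must have at least two named biomarker columns")
  }
  eligible <- rowSums(!is.na(P)) >= 2L
  if (!any(eligible)) {
    ftdStop("ftdInsufficientDataError", "no subject has two or more observed biomarkers")
  }
  excluded <- sum(!eligible)
  if (excluded > 0) {
    ftdLog("estimateOrdering: %d subject(s) with < 2 observed biomarkers excluded", excluded)
  }
  # reorder columns canonically so that index-lexicographic = name-canonical
  canon <- canonicalOrder(colnames(P))
  P <- P[, canon, drop = FALSE]
  D <- pairCostMatrix(P)
  K <- ncol(P)

  lexLess <- function(a, b) {
    d <- a - b
    nz <- which(d != 0)
    length(nz) > 0 && d[nz[1]] < 0
  }

  if (K <= exhaustiveMax) {
    perms <- allPermutations(K)   # generated in lexicographic order
    costs <- apply(perms, 1L, permutationCost, D = D)
    bestPerm <- perms[which.min(costs), ]   # first minimum = lexicographic tie-break
    bestCost <- min(costs)
    method <- "exhaustive"
  } else {
    run <- function(start) localSearch(start, D)
    starts <- list(order(-colMeans(P, na.rm = TRUE)))
    if (restarts > 1L) {
      extra <- withSeed(seed, replicate(restarts - 1L, sample.int(K), simplify = FALSE))
      starts <- c(starts, extra)
    }
    bestPerm <- NULL
    bestCost <- Inf
    for (st in starts) {
      sol <- run(st)
      if (sol$cost < bestCost - 1e-12 ||
          (abs(sol$cost - bestCost) <= 1e-12 && !is.null(bestPerm) &&
           lexLess(sol$perm, bestPerm))) {
        bestPerm <- sol$perm
        bestCost <- sol$cost
      }
    }
    method <- "greedy"
  }
  out <- methods::new("EventOrdering", ordering = canon[bestPerm],
                      cost = bestCost, method = method)
  attr(out, "excludedSubjects") <- excluded
  out
}

#' Bootstrap positional-variance diagram
#'
#' Resamples subjects with replacement `B` times, stratified by diagnosis
#' label so every replicate preserves the control/presymptomatic/symptomatic
#' design, re-estimates the ordering per replicate (refitting the mixtures on
#' the resampled data when `refit = TRUE`, the default), and counts how often
#' each biomarker lands at each position. A replicate in which a biomarker
#' cannot be fit is logged and redrawn, at most 10 times before erroring.
#'
#' @param values subjects x K confound-adjusted matrix over the admitted
#'   biomarkers.
#' @param labels diagnosis labels per row.
#' @param directions named abnormality directions per biomarker.
#' @param B number of bootstrap replicates (default 100).
#' @param seed RNG seed; the run is deterministic given the seed.
#' @param refit refit the mixtures per replicate (default TRUE); when FALSE,
#'   `fits` must supply full-data fits.
#' @param fits named list of [BiomarkerGMM-class] used when `refit = FALSE`.
#' @param ordering central [EventOrdering-class] used to arrange the rows of
#'   the count matrix (default: estimated from the full data).
#' @param ... further arguments passed to [fitBiomarkerGMM()].
#' @return a [PositionalVariance-class].
#' @export
bootstrapOrdering <- function(values, labels, directions, B = 100L, seed = 1L,
                              refit = TRUE, fits = NULL, ordering = NULL, ...) {
  if (!isCount(B) || B < 1) ftdStop("ftdConfigError", "B must be a positive integer")
  markers <- colnames(values)
  stopifnot(all(markers %in% names(directions)))
  withSeed(seed, {
    if (is.null(ordering)) {
      baseFits <- fits %||% fitAllGmms(values, labels, directions, ...)
      P0 <- eventProbabilities(baseFits, values)
      ordering <- estimateOrdering(P0)
    }
    central <- eventSequence(ordering)
    K <- length(markers)
    counts <- matrix(0L, K, K, dimnames = list(central, seq_len(K)))
    byLabel <- split(seq_along(labels), labels)
    for (b in seq_len(B)) {
      done <- FALSE
      for (try_ in seq_len(10L)) {
        idx <- unlist(lapply(byLabel, function(ii) ii[sample.int(length(ii), replace = TRUE)]),
                      use.names = FALSE)
        est <- tryCatch({
          bFits <- if (refit) {
            fitAllGmms(values[idx, , drop = FALSE], labels[idx], directions, ...)
          } else {
            fits
          }
          Pb <- eventProbabilities(bFits, values[idx, , drop = FALSE])
          estimateOrdering(Pb)
        }, ftdError = function(e) e)
        if (!inherits(est, "error")) {
          pos <- match(central, eventSequence(est))
          counts[cbind(seq_len(K), pos)] <- counts[cbind(seq_len(K), pos)] + 1L
          done <- TRUE
          break
        }
        ftdLog("bootstrapOrdering: replicate %d retry %d (%s)", b, try_,
               conditionMessage(est))
      }
      if (!done) {
        ftdStop("ftdConvergenceError", sprintf(
          "bootstrap replicate %d failed 10 consecutive redraws", b
        ))
      }
    }
    methods::new("PositionalVariance", counts = counts, B = as.integer(B),
                 ordering = central)
  })
}

# Fit every biomarker's mixture; errors propagate (callers decide whether to
# retry or mark the biomarker unadmitted).
fitAllGmms <- function(values, labels, directions, ...) {
  fits <- lapply(colnames(values), function(m) {
    fitBiomarkerGMM(values[, m], labels, direction = directions[[m]],
                    marker = m, ...)
  })
  names(fits) <- colnames(values)
  fits
}
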