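# Per-biomarker machinery of the discriminative event-based model:
# confound residualization, the carrier-vs-control screen, the constrained
# two-component Gaussian mixture, and posterior abnormality probabilities.

#' Residualize biomarkers against age and sex
#'
#' Each biomarker column (already on its transform scale) is regressed on age
#' and sex using control subjects only, and all subjects' values are replaced
#' by observed minus predicted. Control column means are therefore zero after
#' adjustment, and the missingness mask is preserved.
#'
#' @param values subjects x K numeric matrix (NAs = missing).
#' @param labels diagnosis labels (`control`/`presymptomatic`/`symptomatic`).
#' @param age,sex demographic vectors aligned with rows of `values`.
#' @return adjusted matrix of the same shape.
#' @export
adjustConfounds <- function(values, labels, age, sex) {
  stopifnot(is.matrix(values), nrow(values) == length(labels))
  out <- values
  demogOk <- !is.na(age) & !is.na(sex)
  for (k in seq_len(ncol(values))) {
    v <- values[, k]
    ctrl <- labels == "control" & !is.na(v) & demogOk
    model <- fitNormativeModel(v[ctrl], age[ctrl], sex[ctrl],
                               region = colnames(values)[k] %||% "biomarker")
    pred <- predictNormative(model, age, sex)
    adj <- v - pred
    adj[!demogOk] <- NA_real_
    out[, k] <- adj
  }
  out
}

#' Screen biomarkers for carrier-vs-control separation
#'
#' Two-sided Mann-Whitney U test of symptomatic carriers versus controls for
#' every biomarker; a biomarker passes when p < alpha. Biomarkers entirely
#' missing in either group are flagged not significant with a logged warning.
#'
#' @param values subjects x K matrix.
#' @param labels diagnosis labels per row.
#' @param alpha significance level (default 0.05).
#' @return data.frame with `marker`, `statistic`, `p`, `significant`.
#' @export
screenBiomarkers <- function(values, labels, alpha = 0.05) {
  if (length(unique(labels)) < 2L) {
    ftdStop("ftdConfigError", "need at least two diagnosis labels")
  }
  res <- lapply(seq_len(ncol(values)), function(k) {
    x <- values[labels == "symptomatic", k]
    y <- values[labels == "control", k]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (!length(x) || !length(y)) {
      ftdLog("screenBiomarkers: '%s' missing in a group; flagged not significant",
             colnames(values)[k])
      return(data.frame(marker = colnames(values)[k], statistic = NA_real_,
                        p = NA_real_, significant = FALSE))
    }
    if (length(unique(c(x, y))) == 1L) {
      return(data.frame(marker = colnames(values)[k], statistic = length(x) * length(y) / 2,
                        p = 1, significant = FALSE))
    }
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
    data.frame(marker = colnames(values)[k], statistic = unname(wt$statistic),
               p = wt$p.value, significant = wt$p.value < alpha)
  })
  do.call(rbind, res)
}

#' Fit the constrained normal/abnormal mixture for one biomarker
#'
#' Two-component Gaussian mixture fitted by EM on all non-missing values,
#' with the structure the event-based model needs: the normal component is
#' initialized at the control mean/sd and the abnormal component from the
#' direction-side tail of symptomatic values; mixing fractions are estimated
#' per diagnosis label with the control abnormal fraction capped at
#' `controlAbnormalMax`; component sds are floored at `sdFloor` times the
#' pooled sd. Fit quality is the mean squared error between the mixture's
#' per-bin probability masses and the empirical bin proportions on a 50-bin
#' grid. A biomarker is admitted when the carrier-vs-control screen is
#' significant, the MSE is at most `mseThreshold`, and the converged means
#' are separated in the declared direction.
#'
#' @param x numeric values for one biomarker (confound-adjusted; NAs allowed).
#' @param labels diagnosis labels aligned with `x`.
#' @param direction `"increase"` or `"decrease"`.
#' @param marker biomarker name carried on the result.
#' @param mseThreshold admission threshold for the fit MSE (default 1e-3).
#' @param alpha screen significance level.
#' @param sdFloor sd floor as a fraction of the pooled sd (default 0.05).
#' @param controlAbnormalMax cap on the control abnormal fraction (default
#'   0.10).
#' @param minSeparation minimum separation of the abnormal mean from the
#'   normal mean, in units of the normal sd (default 2, the conventional
#'   normative-modelling abnormality cut-off). Projected at every M-step;
#'   prevents the abnormal component from collapsing onto the bulk of the
#'   normal distribution when abnormal observations are scarce.
#' @param maxit,tol EM iteration cap (500) and log-likelihood tolerance.
#' @param bins number of bins of the empirical density grid (default 50).
#' @return a [BiomarkerGMM-class].
#' @export
fitBiomarkerGMM <- function(x, labels, direction = c("increase", "decrease"),
                            marker = "biomarker", mseThreshold = 1e-3,
                            alpha = 0.05, sdFloor = 0.05,
                            controlAbnormalMax = 0.10, minSeparation = 2,
                            maxit = 500L, tol = 1e-6, bins = 50L) {
  direction <- match.arg(direction)
  keep <- !is.na(x)
  x <- x[keep]; labels <- labels[keep]
  nCtrl <- sum(labels == "control")
  if (nCtrl < 10L || length(x) < 20L) {
    ftdStop("ftdInsufficientDataError", sprintf(
      "biomarker '%s': need >= 10 control and >= 20 total non-missing values", marker
    ))
  }
  scr <- if (length(unique(labels)) >= 2L) {
    screenBiomarkers(matrix(x, dimnames = list(NULL, marker)), labels, alpha)
  } else {
    data.frame(marker = marker, statistic = NA_real_, p = NA_real_,
               significant = FALSE)
  }

  pooledSd <- stats::sd(x)
  if (!is.finite(pooledSd) || pooledSd < 1e-12) {
    return(newGmm(marker, direction, mean(x), 1e-12 + 1, mean(x), 1e-12 + 1,
                  mixing = degenerateMixing(labels), mse = Inf, scr = scr,
                  admitted = FALSE, converged = TRUE, logLik = NA_real_,
                  reason = "degenerate: zero variance"))
  }
  floorSd <- sdFloor * pooledSd

  ctrl <- x[labels == "control"]
  mu0 <- mean(ctrl)
  s0 <- max(stats::sd(ctrl), floorSd)
  carriers <- x[labels == "symptomatic"]
  if (length(carriers) < 5L) carriers <- x
  tail_ <- if (direction == "increase") carriers[carriers >= mu0] else carriers[carriers <= mu0]
  if (length(tail_) < 5L) {
    q <- stats::quantile(carriers, if (direction == "increase") 0.75 else 0.25)
    tail_ <- if (direction == "increase") carriers[carriers >= q] else carriers[carriers <= q]
  }
  mu1 <- mean(tail_)
  s1 <- stats::sd(tail_)
  if (!is.finite(s1)) s1 <- s0
  s1 <- max(s1, floorSd)
  project <- function(mu1, mu0, s0) {
    if (direction == "increase") max(mu1, mu0 + minSeparation * s0)
    else min(mu1, mu0 - minSeparation * s0)
  }
  mu1 <- project(mu1, mu0, s0)

  labSet <- unique(labels)
  piInit <- c(control = 0.05, presymptomatic = 0.30, symptomatic = 0.80)
  piL <- ifelse(labSet %in% names(piInit), piInit[labSet], 0.5)
  names(piL) <- labSet
  piL["control"] <- min(piL["control"], controlAbnormalMax)

  ll <- -Inf
  converged <- FALSE
  reason <- ""
  for (it in seq_len(maxit)) {
    pi_i <- piL[labels]
    l1 <- stats::dnorm(x, mu1, s1, log = TRUE) + log(pi_i)
    l0 <- stats::dnorm(x, mu0, s0, log = TRUE) + log(1 - pi_i)
    m <- pmax(l0, l1)
    llNew <- sum(m + log(exp(l0 - m) + exp(l1 - m)))
    g <- 1 / (1 + exp(l0 - l1))
    w1 <- sum(g); w0 <- sum(1 - g)
    if (w1 < 1e-8 || w0 < 1e-8) {
      reason <- "degenerate: a component collapsed"
      break
    }
    mu1 <- sum(g * x) / w1
    s1 <- max(sqrt(sum(g * (x - mu1)^2) / w1), floorSd)
    mu0 <- sum((1 - g) * x) / w0
    s0 <- max(sqrt(sum((1 - g) * (x - mu0)^2) / w0), floorSd)
    mu1 <- project(mu1, mu0, s0)
    piL <- tapply(g, labels, mean)[labSet]
    piL <- pmin(pmax(piL, 1e-4), 1 - 1e-4)
    if ("control" %in% labSet) {
      piL["control"] <- min(piL["control"], controlAbnormalMax)
    }
    if (is.finite(ll) && abs(llNew - ll) < tol * (1 + abs(llNew))) {
      converged <- TRUE
      ll <- llNew
      break
    }
    ll <- llNew
  }
  if (!converged && reason == "") {
    ftdStop("ftdConvergenceError", sprintf(
      "EM did not converge in %d iterations for biomarker '%s'", maxit, marker
    ), data = list(
      marker = marker,
      parameters = list(normalMean = mu0, normalSd = s0,
                        abnormalMean = mu1, abnormalSd = s1, mixing = piL)
    ))
  }

  directionOk <- if (direction == "increase") mu1 > mu0 else mu1 < mu0
  mse <- gmmFitMse(x, labels, mu0, s0, mu1, s1, piL, bins)
  admitted <- isTRUE(scr$significant) && is.finite(mse) && mse <= mseThreshold &&
    directionOk && converged
  if (!admitted && reason == "") {
    reason <- if (!isTRUE(scr$significant)) {
      "screen not significant"
    } else if (!directionOk) {
      "components not separated in the declared direction"
    } else if (!is.finite(mse) || mse > mseThreshold) {
      sprintf("fit MSE %.2e above threshold %.2e", mse, mseThreshold)
    } else {
      "not converged"
    }
  } else if (reason != "") {
    admitted <- FALSE
  }
  newGmm(marker, direction, mu0, s0, mu1, s1, mixing = piL, mse = mse,
         scr = scr, admitted = admitted, converged = converged,
         logLik = ll, reason = reason)
}

degenerateMixing <- function(labels) {
  labSet <- unique(labels)
  stats::setNames(rep(0, length(labSet)), labSet)
}

newGmm <- function(marker, direction, mu0, s0, mu1, s1, mixing, mse, scr,
                   admitted, converged, logLik, reason) {
  methods::new(
    "BiomarkerGMM",
    marker = marker, direction = direction,
    normalMean = mu0, normalSd = s0, abnormalMean = mu1, abnormalSd = s1,
    mixing = unlist(mixing), mse = mse,
    screenStatistic = scr$statistic, screenP = scr$p,
    significant = isTRUE(scr$significant),
    admitted = admitted, converged = converged,
    logLik = logLik, reason = reason
  )
}

# MSE between empirical bin proportions and the mixture's bin masses on an
# equal-width grid; probability-mass units make the admission threshold
# scale-free.
gmmFitMse <- function(x, labels, mu0, s0, mu1, s1, piL, bins) {
  rg <- range(x)
  if (diff(rg) <= 0) return(Inf)
  breaks <- seq(rg[1], rg[2], length.out = bins + 1L)
  emp <- graphics::hist(x, breaks = breaks, plot = FALSE)$counts / length(x)
  pbar <- mean(piL[labels])
  model <- pbar * diff(stats::pnorm(breaks, mu1, s1)) +
    (1 - pbar) * diff(stats::pnorm(breaks, mu0, s0))
  mean((emp - model)^2)
}

#' Posterior abnormality probabilities
#'
#' For each subject and admitted biomarker, the posterior probability that
#' the value was generated by the abnormal component, with equal component
#' priors (a pure likelihood-ratio quantity, independent of cohort
#' composition). Missing values stay missing.
#'
#' @param fits named list of [BiomarkerGMM-class] objects.
#' @param values subjects x K matrix aligned with `names(fits)`.
#' @return subjects x K matrix of probabilities in \[0, 1\] (NA = missing).
#' @export
eventProbabilities <- function(fits, values) {
  markers <- names(fits)
  stopifnot(all(markers %in% colnames(values)))
  P <- matrix(NA_real_, nrow(values), length(markers),
              dimnames = list(rownames(values), markers))
  for (m in markers) {
    f <- fits[[m]]
    v <- values[, m]
    ok <- !is.na(v)
    if (any(!is.finite(v[ok]))) {
      ftdStop("ftdValueError", sprintf(
        "non-finite value for biomarker '%s' (records %s)",
        m, paste(which(ok & !is.finite(v)), collapse = ", ")
      ))
    }
    l1 <- stats::dnorm(v[ok], f@abnormalMean, f@abnormalSd, log = TRUE)
    l0 <- stats::dnorm(v[ok], f@normalMean, f@normalSd, log = TRUE)
    P[ok, m] <- stats::plogis(l1 - l0)
  }
  P
}
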