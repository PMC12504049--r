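# Internal helpers shared across modules.

# Structured conditions: every user-facing failure carries a class so callers
# (and the bootstrap retry loop) can distinguish configuration errors from
# convergence failures.
ftdStop <- function(class, msg, data = list()) {
  cond <- structure(
    class = c(class, "ftdError", "error", "condition"),
    c(list(message = msg, call = sys.call(-1)), data)
  )
  stop(cond)
}

ftdLog <- function(...) {
  if (isTRUE(getOption("ftdcascade.verbose", FALSE))) {
    message(sprintf(...))
  }
  invisible(NULL)
}

# Evaluate `expr` under a temporary RNG state; the global stream is restored
# afterwards so simulation functions do not perturb the caller's RNG.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Locale-independent name order used for every tie-break in the package.
canonicalOrder <- function(x) sort(x, method = "radix")

# Wilcoxon rank identity for the AUC of `pos` vs `neg` scores.
rankAuc <- function(pos, neg) {
  n1 <- length(pos)
  n0 <- length(neg)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

clipProb <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

isCount <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)

`%||%` <- function(x, y) if (is.null(x)) y else x
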