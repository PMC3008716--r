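# Naive reference implementations, independent of the package's compiled
# evolution path.  Deliberately written with explicit loops and full-history
# recurrence search so they share no code with what they check.

oracleStep <- function(w, x) {
  y <- integer(length(x))
  for (i in seq_along(x)) {
    acc <- 0
    for (j in seq_along(x)) acc <- acc + w[i, j] * x[j]
    y[i] <- if (acc >= 0) 1L else -1L
  }
  y
}

# Evolve with recurrence detection against the *entire* history; returns the
# recurring state, its period, and the step count at first detection.
oracleEvolve <- function(w, x0, maxIters = 500) {
  seen <- list(x0)
  x <- x0
  for (n in seq_len(maxIters)) {
    x <- oracleStep(w, x)
    for (d in seq_along(seen)) {
      prev <- seen[[length(seen) - d + 1L]]
      if (all(x == prev))
        return(list(outcome = if (d == 1L) "fixed_point" else "limit_cycle",
                    period = d, iterations = n - d, state = x))
    }
    seen[[length(seen) + 1L]] <- x
  }
  list(outcome = "nonconvergent", period = NA_integer_,
       iterations = NA_integer_, state = x)
}

# All 2^n states of an n-node network as columns, n small.
allStates <- function(n) {
  idx <- 0:(2^n - 1)
  bits <- vapply(2^(seq_len(n) - 1), function(p) (idx %/% p) %% 2,
                 numeric(length(idx)))
  t(2 * bits - 1)
}

# Exhaustive basin census via the oracle evolver; attractors keyed by the
# sorted set of states in the recurring orbit.
oracleEnumerate <- function(w, maxIters = 500) {
  states <- allStates(nrow(w))
  keys <- character(ncol(states))
  for (k in seq_len(ncol(states))) {
    res <- oracleEvolve(w, states[, k], maxIters)
    if (res$outcome == "nonconvergent") { keys[k] <- "nonconvergent"; next }
    orbit <- matrix(res$state, ncol = 1)
    x <- res$state
    if (res$period > 1L) for (p in seq_len(res$period - 1L)) {
      x <- oracleStep(w, x)
      orbit <- cbind(orbit, x)
    }
    keys[k] <- paste(sort(apply(orbit, 2, paste, collapse = "")),
                     collapse = "|")
  }
  table(keys)
}

# A random +/-1 pattern with nonzero component sum (so the all-ones state is
# not an accidental extra fixed point of the full outer-product net).
unbalancedAttractor <- function(n) {
  s <- randomAttractor(n)
  while (sum(s) == 0) s <- randomAttractor(n)
  s
}
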