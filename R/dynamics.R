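#' Hebbian outer-product weight matrix for one stored pattern
#'
#' Builds the N x N connectivity matrix `T` with `T[i, j] = s[i] * s[j]`
#' (the dyad product of the pattern with itself, diagonal included).  The
#' result is symmetric, rank 1, and has a single nonzero eigenvalue N with
#' eigenvector `s`, which makes `s` (and its complement `-s`) a fixed point
#' of the synchronous threshold dynamics.  Entry `(i, j)` is the strength
#' of the directed link from sender `j` into receiver `i`.
#'
#' @param s A -1/+1 state vector (the designated attractor).
#' @return An integer matrix of -1/+1 entries.
#' @examples
#' outerAttractorMatrix(c(1, -1))
#' @export
outerAttractorMatrix <- function(s) {
  s <- checkStateVector(s)
  m <- outer(s, s)
  storage.mode(m) <- "integer"
  m
}

#' One synchronous update of the network state
#'
#' Applies the threshold rule to every node simultaneously: node `i`
#' becomes +1 when `sum_j w[i, j] * x[j] >= 0` and -1 otherwise.  The
#' tie at exactly zero input resolves to +1; in particular a node with no
#' surviving incoming links is pinned at +1.
#'
#' @param w Square weight matrix (row = receiving node).
#' @param x A -1/+1 state vector of matching length.
#' @return The next -1/+1 state vector.
#' @examples
#' s <- c(1, -1, 1, -1)
#' w <- outerAttractorMatrix(s)
#' identical(hopfieldStep(w, s), s)
#' @export
hopfieldStep <- function(w, x) {
  w <- checkWeightMatrix(w)
  x <- checkStateVector(x, nrow(w))
  ifelse(as.vector(w %*% x) >= 0, 1L, -1L)
}

#' Is a state a fixed point of the network?
#'
#' @inheritParams hopfieldStep
#' @return `TRUE` if one synchronous update returns `x` unchanged.
#' @examples
#' s <- c(1, 1, -1, 1)
#' isFixedPoint(outerAttractorMatrix(s), s)
#' @export
isFixedPoint <- function(w, x) {
  identical(hopfieldStep(w, x), checkStateVector(x, nrow(w)))
}

#' Evolve one initial state to convergence
#'
#' Iterates the synchronous update from `x0` for at most `maxIters` steps,
#' after each step comparing the new state exactly against the previous
#' `maxPeriod` states.  A repeat at distance 1 is a fixed point; at
#' distance d in `2..maxPeriod` a limit cycle of period d (cycles can only
#' arise once pruning has broken the symmetry of the outer-product matrix).
#' If no repeat is seen within `maxIters` steps the trajectory is classed
#' nonconvergent.
#'
#' @inheritParams hopfieldStep
#' @param x0 Initial -1/+1 state vector.
#' @param maxIters Iteration cap (default 500).
#' @param maxPeriod Longest limit-cycle period screened for (default 4).
#' @return An object of class `"convergenceResult"`: a list with elements
#'   `outcome` (`"fixed_point"`, `"limit_cycle"` or `"nonconvergent"`),
#'   `period` (1 for a fixed point, `NA` when nonconvergent), `iterations`
#'   (update steps until the recurring state was first reached, so 0 for a
#'   start that is already a fixed point; `NA` when nonconvergent) and
#'   `terminalStates` (a matrix whose columns are
#'   the fixed point, the cycle states in order, or the last state seen).
#' @examples
#' s <- c(1, -1, 1, 1)
#' evolveNetwork(outerAttractorMatrix(s), c(-1, 1, 1, 1))
#' @export
evolveNetwork <- function(w, x0, maxIters = 500, maxPeriod = 4) {
  w <- checkWeightMatrix(w)
  x0 <- checkStateVector(x0, nrow(w))
  maxIters <- checkCount(maxIters, "maxIters")
  maxPeriod <- checkCount(maxPeriod, "maxPeriod")
  res <- evolveBatch(w, matrix(x0, ncol = 1L), maxIters, maxPeriod)
  outcome <- res$outcome[1L]
  period <- res$period[1L]
  term <- matrix(as.integer(res$terminal[, 1L]), ncol = 1L)
  if (outcome == "limit_cycle" && period > 1L) {
    states <- matrix(0L, nrow(w), period)
    states[, 1L] <- term[, 1L]
    for (k in seq_len(period - 1L))
      states[, k + 1L] <- hopfieldStep(w, states[, k])
    term <- states
  }
  structure(list(outcome = outcome,
                 period = if (outcome == "nonconvergent") NA_integer_ else period,
                 iterations = res$iterations[1L],
                 terminalStates = term),
            class = "convergenceResult")
}

#' @export
print.convergenceResult <- function(x, ...) {
  cat("Synchronous Hopfield trajectory:", x$outcome)
  if (x$outcome == "limit_cycle") cat(" (period ", x$period, ")", sep = "")
  if (!is.na(x$iterations)) cat(" after", x$iterations, "iterations")
  cat("\n")
  invisible(x)
}

# Batched trajectory evolution (columns of x0 are independent starts).
# Thin wrapper over the compiled core; outcomes are decoded to labels.
# `targets` may hold designated fixed points as columns; with
# `earlyAbort = TRUE` the batch stops at the first probe that finishes
# anywhere other than a target fixed point.
evolveBatch <- function(w, x0, maxIters = 500L, maxPeriod = 4L,
                        targets = NULL, earlyAbort = FALSE) {
  if (is.null(targets)) targets <- matrix(numeric(0), nrow(w), 0L)
  res <- evolveBatchCpp(matrixNumeric(w), matrixNumeric(x0),
                        as.integer(maxIters), as.integer(maxPeriod),
                        matrixNumeric(targets), isTRUE(earlyAbort))
  res$outcome <- c("fixed_point", "limit_cycle", "nonconvergent")[res$outcome + 1L]
  res
}

matrixNumeric <- function(m) {
  storage.mode(m) <- "double"
  m
}

#' Exhaustively enumerate attractors and exact basin sizes
#'
#' Evolves every one of the 2^N states of a small network and catalogues
#' the distinct terminal fixed points and limit cycles together with the
#' exact number of initial states captured by each.  This is the brute
#' force oracle against which sampled retention tests can be checked; it
#' is only feasible for small N (the full state space is visited).
#'
#' @inheritParams evolveNetwork
#' @param maxNodes Refusal threshold on N (default 20).
#' @param chunkSize States evolved per batch (memory/speed trade-off).
#' @return An object of class `"attractorCatalogue"`: a list with
#'   `attractors` (each with `outcome`, `period`, `states` matrix in cycle
#'   order, and `basinSize`), `nNonconvergent`, `nStates` and `nNodes`.
#'   Basin sizes plus nonconvergent states sum to 2^N.
#' @examples
#' s <- c(1, -1, 1, 1)
#' enumerateAttractors(outerAttractorMatrix(s))
#' @export
enumerateAttractors <- function(w, maxIters = 500, maxPeriod = 4,
                                maxNodes = 20, chunkSize = 4096) {
  w <- checkWeightMatrix(w)
  n <- nrow(w)
  if (n > maxNodes)
    stop("exhaustive enumeration over 2^", n, " states refused ",
         "(maxNodes = ", maxNodes, ")", call. = FALSE)
  nStates <- 2^n
  basins <- new.env(parent = emptyenv())
  catalogue <- new.env(parent = emptyenv())
  nNoncon <- 0L
  pow <- 2^(seq_len(n) - 1L)
  for (lo in seq(0, nStates - 1, by = chunkSize)) {
    idx <- lo:min(lo + chunkSize - 1, nStates - 1)
    bits <- vapply(pow, function(p) (idx %/% p) %% 2, numeric(length(idx)))
    x0 <- t(2 * bits - 1)
    res <- evolveBatch(w, x0, maxIters, maxPeriod)
    for (c in seq_along(idx)) {
      if (res$outcome[c] == "nonconvergent") { nNoncon <- nNoncon + 1L; next }
      term <- as.integer(res$terminal[, c])
      period <- res$period[c]
      key <- attractorKey(w, term, period)
      if (is.null(basins[[key$id]])) {
        basins[[key$id]] <- 0L
        catalogue[[key$id]] <- list(outcome = res$outcome[c],
                                    period = period, states = key$states)
      }
      basins[[key$id]] <- basins[[key$id]] + 1L
    }
  }
  ids <- ls(basins)
  attractors <- lapply(ids, function(id) {
    a <- catalogue[[id]]
    a$basinSize <- basins[[id]]
    a
  })
  ord <- order(vapply(attractors, `[[`, integer(1), "basinSize"),
               decreasing = TRUE)
  structure(list(attractors = attractors[ord], nNonconvergent = nNoncon,
                 nStates = nStates, nNodes = n),
            class = "attractorCatalogue")
}

# Canonical identity of an attractor: cycle states in dynamical order,
# rotated to start at the lexicographically smallest state.
attractorKey <- function(w, term, period) {
  if (period == 1L) {
    states <- matrix(term, ncol = 1L)
  } else {
    states <- matrix(0L, length(term), period)
    states[, 1L] <- term
    for (k in seq_len(period - 1L))
      states[, k + 1L] <- hopfieldStep(w, states[, k])
    labs <- apply(states, 2L, paste, collapse = "")
    shift <- which.min(labs)
    if (shift > 1L)
      states <- states[, c(shift:period, seq_len(shift - 1L)), drop = FALSE]
  }
  list(id = paste(states, collapse = ""), states = states)
}

#' @export
print.attractorCatalogue <- function(x, ...) {
  cat("Attractor catalogue over all", x$nStates, "states of a",
      x$nNodes, "node network\n")
  for (a in x$attractors)
    cat(sprintf("  %-12s period %d  basin %d (%.1f%%)\n", a$outcome,
                a$period, a$basinSize, 100 * a$basinSize / x$nStates))
  if (x$nNonconvergent > 0)
    cat("  nonconvergent states:", x$nNonconvergent, "\n")
  invisible(x)
}

#' Mean number of directed links per node
#'
#' The connectivity axis of the pruning experiments: the count of nonzero
#' directed weight entries (diagonal included) divided by N.
#'
#' @param w Square weight matrix.
#' @return A single number, `sum(w != 0) / nrow(w)`.
#' @export
linksPerNode <- function(w) {
  w <- checkWeightMatrix(w)
  sum(w != 0) / nrow(w)
}
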