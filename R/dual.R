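#' Graft a second orthogonal attractor onto a minimal skeleton
#'
#' Builds the dual-attractor connectivity matrix `U` from a minimal
#' single-attractor skeleton `tstar` (whose nonzero entries form the
#' protected set) and two orthogonal patterns `s` and `r`:
#' protected entries keep their skeleton values, and every other entry
#' takes the standard two-pattern Hebbian value `s[i]*s[j] + r[i]*r[j]`
#' (which is -2, 0 or +2; zeros are absent links).  `U` therefore differs
#' from the plain two-pattern Hopfield matrix only at the roughly N
#' protected entries inherited from the skeleton.  Both `s` and `r` (and
#' by symmetry their complements) are verified to be fixed points of the
#' constructed matrix before it is returned.
#'
#' @param tstar Minimal skeleton weight matrix (may also be a zero matrix,
#'   giving the pure two-pattern Hopfield net).
#' @param s First designated attractor (-1/+1 vector).
#' @param r Second designated attractor, exactly orthogonal to `s`.
#' @return The weight matrix `U`, with attribute `protectedSet` holding the
#'   linear indices of the skeleton's nonzero entries.
#' @examples
#' s <- c(1, 1, -1, -1, 1, -1)
#' r <- c(1, -1, 1, -1, 1, -1)   # r . s == 0
#' u <- buildDualMatrix(matrix(0, 6, 6), s, r)
#' isFixedPoint(u, r)
#' @export
buildDualMatrix <- function(tstar, s, r) {
  tstar <- checkWeightMatrix(tstar)
  s <- checkStateVector(s, nrow(tstar))
  r <- checkStateVector(r, nrow(tstar))
  if (sum(r * s) != 0)
    stop("'r' must be exactly orthogonal to 's' (r . s = ", sum(r * s), ")",
         call. = FALSE)
  protected <- which(tstar != 0)
  u <- outer(s, s) + outer(r, r)
  u[protected] <- tstar[protected]
  sOK <- isFixedPoint(u, s) && isFixedPoint(u, -s)
  rOK <- isFixedPoint(u, r) && isFixedPoint(u, -r)
  if (!sOK || !rOK)
    stop("dual construction failed: ",
         paste(c(if (!sOK) "s", if (!rOK) "r"), collapse = " and "),
         " (or its complement) not a fixed point of the constructed matrix",
         call. = FALSE)
  attr(u, "protectedSet") <- protected
  u
}

#' Monte-Carlo retention test for a dual-attractor network
#'
#' Checks that the two designated attractors still exist — `s`, `r` and
#' (complement identification, as in [retentionTest()]) their negations
#' must all be fixed points — and that every one of `nStarts` fresh random
#' probe states converges to a fixed point in `{s, -s, r, -r}`.  Also
#' reports the fraction of probes captured by the second attractor.  When
#' a fixed-point check already fails, no probes are run.
#'
#' @inheritParams retentionTest
#' @param u Square weight matrix with both attractors grafted.
#' @param r Second designated attractor.
#' @param nStarts Number of random probes (default 200).
#' @return A list: `retained`, `fractionToSecond` and `fractionToFirst`
#'   (shares of probes ending at `+/-r` and `+/-s`; computed over probes
#'   that finished at a designated attractor, so they sum to 1 whenever any
#'   did), `meanIterations` (over those probes), `firstIsFixedPoint`
#'   (`s` and `-s` both fixed), `secondIsFixedPoint` (`r` and `-r` both
#'   fixed).
#' @export
dualRetentionTest <- function(u, s, r, nStarts = 200, maxIters = 500,
                              maxPeriod = 4) {
  u <- checkWeightMatrix(u)
  s <- checkStateVector(s, nrow(u))
  r <- checkStateVector(r, nrow(u))
  nStarts <- checkCount(nStarts, "nStarts")
  sOK <- isFixedPoint(u, s) && isFixedPoint(u, -s)
  rOK <- isFixedPoint(u, r) && isFixedPoint(u, -r)
  if (!sOK || !rOK)
    return(list(retained = FALSE, fractionToSecond = NaN,
                fractionToFirst = NaN, meanIterations = NaN,
                firstIsFixedPoint = sOK, secondIsFixedPoint = rOK))
  x0 <- randomInitialStates(nrow(u), nStarts)
  res <- evolveBatch(u, x0, maxIters, maxPeriod,
                     targets = cbind(s, -s, r, -r), earlyAbort = TRUE)
  ok <- res$outcome == "fixed_point" & !is.na(res$targetIndex)
  nFirst <- sum(res$targetIndex[ok] <= 2L)
  nSecond <- sum(res$targetIndex[ok] >= 3L)
  list(retained = !res$aborted && all(ok),
       fractionToSecond = if (any(ok)) nSecond / sum(ok) else NaN,
       fractionToFirst = if (any(ok)) nFirst / sum(ok) else NaN,
       meanIterations = mean(res$iterations[ok]),
       firstIsFixedPoint = sOK,
       secondIsFixedPoint = rOK)
}

#' Bulk-prune the added links of a dual-attractor network
#'
#' Zeroes a uniformly random subset of the *non-protected* nonzero entries
#' of `u` so that `round(targetLinksPerNode * N)` links remain in total,
#' then verifies the result with [dualRetentionTest()], resampling the
#' removal set on failure.  Protected skeleton entries are never touched.
#'
#' @inheritParams dualRetentionTest
#' @param protectedSet Linear indices of the protected skeleton entries
#'   (defaults to `attr(u, "protectedSet")`).
#' @param targetLinksPerNode Surviving links per node (default 15); the
#'   implied link count must be at least the size of the protected set.
#' @param maxResample Resampling budget for failed verifications.
#' @return The pruned matrix with attributes `protectedSet`, `retention`
#'   and `resamples`.
#' @export
dualBulkPrune <- function(u, s, r, protectedSet = attr(u, "protectedSet"),
                          targetLinksPerNode = 15, nStarts = 200,
                          maxIters = 500, maxPeriod = 4, maxResample = 20) {
  u <- checkWeightMatrix(u)
  s <- checkStateVector(s, nrow(u))
  r <- checkStateVector(r, nrow(u))
  if (is.null(protectedSet)) protectedSet <- integer(0)
  target <- as.integer(round(targetLinksPerNode * nrow(u)))
  if (target < length(protectedSet))
    stop("target of ", target, " links is below the ", length(protectedSet),
         " protected skeleton links", call. = FALSE)
  free <- setdiff(which(u != 0), protectedSet)
  nKeep <- target - length(protectedSet)
  if (nKeep >= length(free)) return(u)
  for (attempt in 0:maxResample) {
    keep <- sample(free, nKeep)
    u2 <- matrix(0, nrow(u), ncol(u))
    u2[c(protectedSet, keep)] <- u[c(protectedSet, keep)]
    rt <- dualRetentionTest(u2, s, r, nStarts, maxIters, maxPeriod)
    if (rt$retained) {
      attr(u2, "protectedSet") <- protectedSet
      attr(u2, "retention") <- rt
      attr(u2, "resamples") <- attempt
      return(u2)
    }
  }
  stop("dual bulk pruning to ", target, " links failed verification in all ",
       maxResample + 1, " resamples", call. = FALSE)
}

#' Sequentially prune the added links of a dual-attractor network
#'
#' The dual-attractor analogue of [sequentialPrune()].  Removal candidates
#' are drawn only from non-protected links; the skeleton supporting the
#' first attractor is immutable.  The run has two phases.  In the dual
#' phase a removal is kept only if [dualRetentionTest()] passes (both
#' attractor pairs still fixed, all probes captured by one of them); the
#' phase ends when every remaining non-protected link has been tried and
#' rejected — the dual-minimal net, from which no link can be removed
#' without destroying one of the two attractors.  The run then does not
#' stop: eligibility is reset and pruning continues under the
#' single-attractor criterion for `s` alone, so the trace spans the full
#' connectivity range and records where the second attractor stops being
#' a fixed point.
#'
#' @inheritParams dualBulkPrune
#' @param snapshotEvery Accepted-removal cadence for edge-list snapshots.
#' @return An object of class `"dualTrace"`: a list with `steps` (data
#'   frame with `step`, `linksRemaining`, `linksPerNode`, `accepted`,
#'   `meanIterations`, `fractionToSecond`, `secondIsFixedPoint`, `mode`),
#'   `finalNetwork`, `snapshots`, `protectedSet`, `secondLossLinksPerNode`
#'   (links per node at the first accepted state where `r` is not a fixed
#'   point; `NA` if that never happened), `transitionStep`, `s`, `r`,
#'   `nNodes`.
#' @export
dualSequentialPrune <- function(u, s, r, protectedSet = attr(u, "protectedSet"),
                                nStarts = 200, maxIters = 500, maxPeriod = 4,
                                snapshotEvery = 25) {
  u <- checkWeightMatrix(u)
  if (is.null(protectedSet)) protectedSet <- integer(0)
  u <- stripMatrixAttributes(u)
  s <- checkStateVector(s, nrow(u))
  r <- checkStateVector(r, nrow(u))
  n <- nrow(u)
  protectedValues <- u[protectedSet]
  mode <- "dual"
  transitionStep <- NA_integer_
  secondLossLpn <- NA_real_
  eligible <- setdiff(which(u != 0), protectedSet)
  steps <- list()
  snapshots <- list()
  accepted <- 0L
  i <- 0L
  repeat {
    if (length(eligible) == 0L) {
      if (mode != "dual") break
      # dual-minimal: no further link can go without losing one of the two
      # attractors; continue under the single-attractor criterion.
      mode <- "single"
      transitionStep <- i + 1L
      eligible <- setdiff(which(u != 0), protectedSet)
      if (length(eligible) == 0L) break
    }
    i <- i + 1L
    pick <- eligible[sample.int(length(eligible), 1L)]
    old <- u[pick]
    u[pick] <- 0
    if (mode == "dual") {
      rt <- dualRetentionTest(u, s, r, nStarts, maxIters, maxPeriod)
      accept <- rt$retained
      frac <- rt$fractionToSecond
    } else {
      rt <- retentionTest(u, s, nStarts, maxIters, maxPeriod)
      accept <- rt$retained
      frac <- 0
    }
    if (accept) {
      accepted <- accepted + 1L
      eligible <- setdiff(which(u != 0), protectedSet)
      if (is.finite(snapshotEvery) && accepted %% snapshotEvery == 0L)
        snapshots[[paste0("accepted", accepted)]] <- edgeListFrame(u)
    } else {
      u[pick] <- old
      eligible <- eligible[eligible != pick]
    }
    # state of the network as it stands after the accept/reinstate decision
    rFixedNow <- isFixedPoint(u, r)
    if (accept && !rFixedNow && is.na(secondLossLpn))
      secondLossLpn <- sum(u != 0) / n
    steps[[i]] <- data.frame(step = i, linksRemaining = sum(u != 0),
                             linksPerNode = sum(u != 0) / n,
                             accepted = accept,
                             meanIterations = rt$meanIterations,
                             fractionToSecond = frac,
                             secondIsFixedPoint = rFixedNow,
                             mode = mode)
  }
  stopifnot(identical(as.vector(u[protectedSet]), as.vector(protectedValues)))
  snapshots[["final"]] <- edgeListFrame(u)
  structure(list(steps = do.call(rbind, steps), finalNetwork = u,
                 snapshots = snapshots, protectedSet = protectedSet,
                 secondLossLinksPerNode = secondLossLpn,
                 transitionStep = transitionStep,
                 s = s, r = r, nNodes = n),
            class = "dualTrace")
}

#' @export
print.dualTrace <- function(x, ...) {
  final <- sum(x$finalNetwork != 0)
  cat("Dual-attractor pruning trace (N =", x$nNodes, "nodes,",
      length(x$protectedSet), "protected skeleton links)\n")
  cat("  attempted removals:", nrow(x$steps),
      " accepted:", sum(x$steps$accepted), "\n")
  cat(sprintf("  final net: %d links (%.2f links/node)\n",
              final, final / x$nNodes))
  if (!is.na(x$secondLossLinksPerNode))
    cat(sprintf("  second attractor lost as fixed point at %.2f links/node\n",
                x$secondLossLinksPerNode))
  invisible(x)
}
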