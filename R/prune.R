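#' Monte-Carlo retention test for the designated attractor
#'
#' Tests for the continued existence and global stability of the
#' designated attractor: both `s` and its complement `-s` must still be
#' fixed points, and every one of `nStarts` fresh uniform random probe
#' states must converge, within `maxIters` synchronous updates, to a fixed
#' point equal to `s` or `-s`.  The complement is identified with `s`: for
#' a symmetric +/-1-pattern matrix `-s` is automatically a fixed point and
#' captures roughly half of all random starts, so global attraction is
#' only meaningful up to sign (the counts reaching each sign are
#' reported).  Trajectories that enter a limit cycle (period up to
#' `maxPeriod`), stop at any other fixed point, or fail to converge all
#' defeat retention.
#'
#' Requiring `-s` to stay fixed is what makes complement identification
#' coherent: under the zero-input-ties-to-+1 rule, dropping it would let
#' the pruning loop strip every incoming link from nodes with `s[i] = +1`
#' once random probes stop sampling the shrinking basin of `-s`, silently
#' destroying the complement attractor and collapsing the net to about
#' half the link count that the attractor pair actually needs.  With the
#' existence check in place every node must keep at least one incoming
#' link, so a minimal net always has at least N links.
#'
#' Fresh probe states are drawn from the current RNG stream on every call;
#' a fixed probe panel would bias the pruned net toward those probes.
#'
#' @param w Square weight matrix.
#' @param s Designated attractor (-1/+1 vector).
#' @param nStarts Number of random probe states (default 100).
#' @param maxIters Iteration cap per probe (default 500).
#' @param maxPeriod Longest limit-cycle period screened for (default 4).
#' @return A list: `retained` (logical), `attractorIsFixed` (are both `s`
#'   and `-s` fixed points), `meanIterations` (mean update count over
#'   probes that reached `s` or `-s`; `NaN` if none did, or if the
#'   fixed-point check already failed and no probes were run),
#'   `nToAttractor` and `nToComplement` (probe counts reaching `s` and
#'   `-s`; the remainder failed).
#' @examples
#' set.seed(1)
#' s <- c(1, 1, -1, 1, -1, 1)   # sum(s) != 0
#' retentionTest(outerAttractorMatrix(s), s, nStarts = 20)
#' @export
retentionTest <- function(w, s, nStarts = 100, maxIters = 500, maxPeriod = 4) {
  w <- checkWeightMatrix(w)
  s <- checkStateVector(s, nrow(w))
  nStarts <- checkCount(nStarts, "nStarts")
  fixed <- isFixedPoint(w, s) && isFixedPoint(w, -s)
  if (!fixed)
    return(list(retained = FALSE, attractorIsFixed = FALSE,
                meanIterations = NaN,
                nToAttractor = 0L, nToComplement = 0L))
  x0 <- randomInitialStates(nrow(w), nStarts)
  res <- evolveBatch(w, x0, maxIters, maxPeriod,
                     targets = cbind(s, -s), earlyAbort = TRUE)
  ok <- res$outcome == "fixed_point" & !is.na(res$targetIndex)
  list(retained = !res$aborted && all(ok),
       attractorIsFixed = TRUE,
       meanIterations = mean(res$iterations[ok]),
       nToAttractor = sum(res$targetIndex[ok] == 1L),
       nToComplement = sum(res$targetIndex[ok] == 2L))
}

#' Bulk-prune a network to a target link density
#'
#' Removes a uniformly random subset of the nonzero entries so that exactly
#' `round(targetLinksPerNode * N)` directed links remain, then verifies
#' with [retentionTest()] that the designated attractor still captures all
#' probes.  If the verification fails the removal set is resampled, up to
#' `maxResample` times; failures are rare because a random cut this deep
#' almost never destroys the attractor.  A target at or above the current
#' density returns the matrix unchanged.
#'
#' @inheritParams retentionTest
#' @param targetLinksPerNode Surviving links per node (default 10).
#' @param maxResample Resampling budget for failed verifications.
#' @return The pruned weight matrix, with attributes `retention` (the
#'   passing test result) and `resamples` (removal sets discarded).
#' @export
bulkPrune <- function(w, s, targetLinksPerNode = 10, nStarts = 100,
                      maxIters = 500, maxPeriod = 4, maxResample = 20) {
  w <- checkWeightMatrix(w)
  s <- checkStateVector(s, nrow(w))
  nz <- which(w != 0)
  target <- as.integer(round(targetLinksPerNode * nrow(w)))
  if (target < 1)
    stop("'targetLinksPerNode' leaves no links", call. = FALSE)
  if (target >= length(nz)) return(w)
  for (attempt in 0:maxResample) {
    keep <- sample(nz, target)
    w2 <- matrix(0, nrow(w), ncol(w))
    w2[keep] <- w[keep]
    rt <- retentionTest(w2, s, nStarts, maxIters, maxPeriod)
    if (rt$retained) {
      attr(w2, "retention") <- rt
      attr(w2, "resamples") <- attempt
      return(w2)
    }
  }
  stop("bulk pruning to ", target, " links failed the retention test in all ",
       maxResample + 1, " resamples (N = ", nrow(w), ", nStarts = ", nStarts,
       ")", call. = FALSE)
}

#' Prune links one at a time down to a minimal attractor-supporting net
#'
#' The core reduction loop.  Repeatedly selects one remaining link
#' uniformly at random, removes it, and re-runs [retentionTest()] with
#' fresh probe states.  If every probe still reaches the designated
#' attractor (or its complement) the removal is kept; otherwise the link is
#' reinstated and marked ineligible.  Eligibility is reset whenever some
#' other link is successfully removed, since its loss may change which
#' links are dispensable.  The loop terminates when every remaining link
#' has been tried and rejected since the last acceptance: the result is a
#' minimal configuration from which no single link can be removed without
#' losing the attractor.
#'
#' @inheritParams retentionTest
#' @param snapshotEvery Save an edge-list snapshot of the network every
#'   this many accepted removals (`Inf` to disable).
#' @return An object of class `"pruneTrace"`: a list with `steps` (a data
#'   frame with one row per attempted removal: `step`, `linksRemaining`,
#'   `linksPerNode`, `accepted`, `meanIterations`), `finalNetwork` (the
#'   minimal matrix T*), `snapshots` (named list of edge-list data frames),
#'   `s`, and `nNodes`.
#' @examples
#' \donttest{
#' set.seed(42)
#' s <- randomAttractor(30)
#' w <- bulkPrune(outerAttractorMatrix(s), s, 10, nStarts = 50)
#' tr <- sequentialPrune(w, s, nStarts = 50)
#' tr
#' }
#' @export
sequentialPrune <- function(w, s, nStarts = 100, maxIters = 500,
                            maxPeriod = 4, snapshotEvery = 25) {
  w <- stripMatrixAttributes(checkWeightMatrix(w))
  s <- checkStateVector(s, nrow(w))
  n <- nrow(w)
  eligible <- which(w != 0)
  steps <- list()
  snapshots <- list()
  accepted <- 0L
  i <- 0L
  while (length(eligible) > 0L) {
    i <- i + 1L
    pick <- eligible[sample.int(length(eligible), 1L)]
    old <- w[pick]
    w[pick] <- 0
    rt <- retentionTest(w, s, nStarts, maxIters, maxPeriod)
    if (rt$retained) {
      accepted <- accepted + 1L
      eligible <- which(w != 0)
      if (is.finite(snapshotEvery) && accepted %% snapshotEvery == 0L)
        snapshots[[paste0("accepted", accepted)]] <- edgeListFrame(w)
    } else {
      w[pick] <- old
      eligible <- eligible[eligible != pick]
    }
    steps[[i]] <- c(sum(w != 0), rt$retained, rt$meanIterations)
  }
  stepMat <- do.call(rbind, steps)
  trace <- data.frame(step = seq_len(nrow(stepMat)),
                      linksRemaining = as.integer(stepMat[, 1L]),
                      linksPerNode = stepMat[, 1L] / n,
                      accepted = as.logical(stepMat[, 2L]),
                      meanIterations = stepMat[, 3L])
  snapshots[["final"]] <- edgeListFrame(w)
  structure(list(steps = trace, finalNetwork = w, snapshots = snapshots,
                 s = s, nNodes = n),
            class = "pruneTrace")
}

#' @export
print.pruneTrace <- function(x, ...) {
  final <- sum(x$finalNetwork != 0)
  cat("Sequential pruning trace (N =", x$nNodes, "nodes)\n")
  cat("  attempted removals:", nrow(x$steps),
      " accepted:", sum(x$steps$accepted), "\n")
  cat(sprintf("  minimal net: %d links (%.2f links/node)\n",
              final, final / x$nNodes))
  invisible(x)
}

#' Survival of the designated attractor under random mass link elimination
#'
#' For each trial, removes a fresh uniformly random fraction of the links
#' of `w` in one stroke and runs [retentionTest()] on the result.  Returns
#' the fraction of trials in which the attractor survived — the robustness
#' counterpoint to the fragility of minimal nets, where a single removal is
#' always fatal.
#'
#' @inheritParams retentionTest
#' @param fractionRemoved Fraction of the nonzero links removed per trial,
#'   in `[0, 1)`.
#' @param nTrials Number of independent removal trials.
#' @return The survival fraction (number retained / `nTrials`), with the
#'   per-trial logical results as attribute `trials`.
#' @export
massEliminationSurvival <- function(w, s, fractionRemoved, nTrials = 20,
                                    nStarts = 100, maxIters = 500,
                                    maxPeriod = 4) {
  w <- checkWeightMatrix(w)
  s <- checkStateVector(s, nrow(w))
  if (!is.numeric(fractionRemoved) || length(fractionRemoved) != 1L ||
      fractionRemoved < 0 || fractionRemoved >= 1)
    stop("'fractionRemoved' must be in [0, 1)", call. = FALSE)
  nTrials <- checkCount(nTrials, "nTrials")
  nz <- which(w != 0)
  nRemove <- as.integer(round(fractionRemoved * length(nz)))
  trials <- vapply(seq_len(nTrials), function(t) {
    w2 <- w
    if (nRemove > 0L) w2[sample(nz, nRemove)] <- 0
    retentionTest(w2, s, nStarts, maxIters, maxPeriod)$retained
  }, logical(1))
  structure(mean(trials), trials = trials)
}

# internal: keep only the dim attribute (drop verification attributes that
# bulk pruning attaches, so downstream results compare cleanly)
stripMatrixAttributes <- function(w) {
  attributes(w) <- list(dim = dim(w))
  w
}

# internal: nonzero entries of w as a 0-based source/target/weight frame
edgeListFrame <- function(w) {
  nz <- which(w != 0, arr.ind = TRUE)
  data.frame(source = nz[, "col"] - 1L,
             target = nz[, "row"] - 1L,
             weight = w[nz])
}
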