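#' Degree histogram of a weight matrix
#'
#' For each node, the degree is the number of links both arriving and
#' leaving: nonzero entries in its row (incoming) plus its column
#' (outgoing), with a self-link counted once.  Returns the frequency of
#' nodes at each degree from 0 to the maximum observed.
#'
#' @param w Square weight matrix.
#' @return A data frame with columns `degree` and `count`; counts sum to N.
#' @examples
#' degreeHistogram(outerAttractorMatrix(c(1, -1, 1, -1)))
#' @export
degreeHistogram <- function(w) {
  w <- checkWeightMatrix(w)
  nz <- w != 0
  deg <- rowSums(nz) + colSums(nz) - diag(nz)
  degs <- 0:max(deg)
  data.frame(degree = degs,
             count = as.integer(tabulate(factor(deg, levels = degs),
                                         nbins = length(degs))))
}

#' Incoming-link counts per node
#'
#' @param w Square weight matrix (row = receiving node).
#' @return Integer vector of nonzero entries per row.
#' @export
incomingDegrees <- function(w) {
  w <- checkWeightMatrix(w)
  as.integer(rowSums(w != 0))
}

#' Convergence-speed curve normalised by ln(N)
#'
#' Bins the accepted steps of a pruning trace on a common links-per-node
#' grid and reports, per bin, the mean number of iterations needed to
#' converge and the same quantity divided by `log(N)`.  Dividing by ln(N)
#' collapses the curves for different network sizes onto a single
#' universal curve, which is what makes runs of different N comparable.
#'
#' @param trace A [sequentialPrune()] trace (or its `steps` data frame).
#' @param nNodes Network size N (at least 3; taken from the trace if
#'   omitted).
#' @param binWidth Width of the links-per-node bins (default 0.25).
#' @param lpnRange Range of the grid (default `c(1, 10)`).
#' @return A data frame with columns `linksPerNode` (bin midpoints),
#'   `meanIterations` and `normalizedIterations`; bins with no accepted
#'   steps are dropped.
#' @export
normalizedIterations <- function(trace, nNodes = NULL, binWidth = 0.25,
                                 lpnRange = c(1, 10)) {
  steps <- if (inherits(trace, "pruneTrace") || inherits(trace, "dualTrace"))
    trace$steps else trace
  if (is.null(nNodes)) {
    if (is.list(trace) && !is.null(trace$nNodes)) nNodes <- trace$nNodes
    else stop("'nNodes' is required when 'trace' is a bare data frame",
              call. = FALSE)
  }
  nNodes <- checkNodeCount(nNodes)
  if (nNodes < 3) stop("'nNodes' must be at least 3", call. = FALSE)
  acc <- steps[steps$accepted & is.finite(steps$meanIterations), ]
  breaks <- seq(lpnRange[1], lpnRange[2], by = binWidth)
  bin <- cut(acc$linksPerNode, breaks, include.lowest = TRUE)
  means <- tapply(acc$meanIterations, bin, mean)
  mids <- (breaks[-length(breaks)] + breaks[-1]) / 2
  keep <- !is.na(means)
  data.frame(linksPerNode = mids[keep],
             meanIterations = as.numeric(means[keep]),
             normalizedIterations = as.numeric(means[keep]) / log(nNodes))
}

#' Summarise one completed pruning run
#'
#' @param trace A [sequentialPrune()] or [dualSequentialPrune()] result.
#' @param binWidth,lpnRange Passed to [normalizedIterations()].
#' @return An object of class `"runSummary"`: a list with `nNodes`,
#'   `finalLinks`, `degreeHistogram`, `incomingDegrees`,
#'   `iterationsCurve`, and (for dual runs) `captureCurve` — the accepted
#'   steps' `(linksPerNode, fractionToSecond)` pairs.
#' @export
summarizeRun <- function(trace, binWidth = 0.25, lpnRange = c(1, 10)) {
  stopifnot(inherits(trace, "pruneTrace") || inherits(trace, "dualTrace"))
  w <- trace$finalNetwork
  out <- list(nNodes = trace$nNodes,
              finalLinks = sum(w != 0),
              degreeHistogram = degreeHistogram(w),
              incomingDegrees = incomingDegrees(w),
              iterationsCurve = normalizedIterations(trace, trace$nNodes,
                                                     binWidth, lpnRange))
  if (inherits(trace, "dualTrace")) {
    acc <- trace$steps[trace$steps$accepted, ]
    out$captureCurve <- data.frame(linksPerNode = acc$linksPerNode,
                                   fractionToSecond = acc$fractionToSecond)
    out$secondLossLinksPerNode <- trace$secondLossLinksPerNode
  }
  structure(out, class = "runSummary")
}

#' Aggregate several pruning runs of the same size
#'
#' Pools run summaries: per-degree mean node counts with standard errors
#' across runs, the pooled degree histogram, and the range of final link
#' counts.
#'
#' @param summaries A list of [summarizeRun()] objects, all with the same
#'   N.
#' @return A list with `nNodes`, `nRuns`, `finalLinks` (vector),
#'   `finalLinksRange`, and `degrees` (data frame with `degree`,
#'   `meanCount`, `seCount`, `totalCount`).
#' @export
aggregateRuns <- function(summaries) {
  stopifnot(is.list(summaries), length(summaries) >= 1L,
            all(vapply(summaries, inherits, logical(1), "runSummary")))
  ns <- vapply(summaries, `[[`, numeric(1), "nNodes")
  if (length(unique(ns)) != 1L)
    stop("all runs must have the same number of nodes (got ",
         paste(unique(ns), collapse = ", "), ")", call. = FALSE)
  maxDeg <- max(vapply(summaries, function(s) max(s$degreeHistogram$degree),
                       numeric(1)))
  counts <- vapply(summaries, function(s) {
    out <- numeric(maxDeg + 1)
    out[s$degreeHistogram$degree + 1] <- s$degreeHistogram$count
    out
  }, numeric(maxDeg + 1))
  counts <- matrix(counts, nrow = maxDeg + 1)
  se <- if (ncol(counts) > 1) apply(counts, 1, sd) / sqrt(ncol(counts))
        else rep(0, nrow(counts))
  finalLinks <- vapply(summaries, `[[`, numeric(1), "finalLinks")
  list(nNodes = ns[1], nRuns = length(summaries),
       finalLinks = finalLinks,
       finalLinksRange = range(finalLinks),
       degrees = data.frame(degree = 0:maxDeg,
                            meanCount = rowMeans(counts),
                            seCount = se,
                            totalCount = rowSums(counts)))
}
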