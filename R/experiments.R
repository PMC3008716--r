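#' Run the full single-attractor pruning experiment
#'
#' End-to-end pipeline: draw a random designated attractor `s`, build the
#' fully connected outer-product net, bulk-prune it to `bulkTarget` links
#' per node (verifying retention), then prune one link at a time with
#' [sequentialPrune()] until the minimal net T* is reached.  All
#' randomness is staged through [deriveSeeds()] so the run is reproducible
#' from the single master `seed`.
#'
#' @param nNodes Network size N (default 200).
#' @param seed Master seed.
#' @param nStarts Probe states per retention test (default 100).
#' @param bulkTarget Links per node after bulk pruning (default 10).
#' @param maxIters Iteration cap per probe (default 500).
#' @param maxPeriod Limit-cycle screening period (default 4).
#' @param snapshotEvery Snapshot cadence in accepted removals.
#' @param maxResample Bulk-prune resampling budget.
#' @param outDir If non-`NULL`, a directory into which `trace.csv`,
#'   `tstar.tsv`, `meta.json` and snapshot edge lists are written.
#' @return An object of class `"singleAttractorRun"`: a list with `s`,
#'   `tstar`, `trace` (the [sequentialPrune()] object), `summary` (a
#'   [summarizeRun()] object) and `meta` (config and derived seeds).
#' @examples
#' \donttest{
#' run <- runSingleAttractorExperiment(nNodes = 30, seed = 7, nStarts = 50)
#' run$summary$finalLinks
#' }
#' @export
runSingleAttractorExperiment <- function(nNodes = 200, seed = 1,
                                         nStarts = 100, bulkTarget = 10,
                                         maxIters = 500, maxPeriod = 4,
                                         snapshotEvery = 25, maxResample = 20,
                                         outDir = NULL) {
  seeds <- deriveSeeds(seed)
  set.seed(seeds[["attractor"]])
  s <- randomAttractor(nNodes)
  w <- outerAttractorMatrix(s)
  set.seed(seeds[["bulk"]])
  wBulk <- bulkPrune(w, s, bulkTarget, nStarts, maxIters, maxPeriod,
                     maxResample)
  set.seed(seeds[["prune"]])
  trace <- sequentialPrune(wBulk, s, nStarts, maxIters, maxPeriod,
                           snapshotEvery)
  meta <- list(experiment = "single-attractor pruning",
               nNodes = nNodes, masterSeed = seed,
               derivedSeeds = as.list(seeds),
               nStarts = nStarts, bulkTarget = bulkTarget,
               maxIters = maxIters, maxPeriod = maxPeriod,
               attractor = s,
               finalLinks = sum(trace$finalNetwork != 0),
               attemptedRemovals = nrow(trace$steps),
               packageVersion = as.character(utils::packageVersion("hopnet")))
  run <- structure(list(s = s, tstar = trace$finalNetwork, trace = trace,
                        summary = summarizeRun(trace), meta = meta),
                   class = "singleAttractorRun")
  if (!is.null(outDir)) writeSingleRun(run, outDir)
  run
}

#' @export
print.singleAttractorRun <- function(x, ...) {
  cat("Single-attractor pruning experiment (N =", x$meta$nNodes,
      ", seed =", x$meta$masterSeed, ")\n")
  cat(sprintf("  minimal net: %d links (%.2f links/node), incoming degrees %d-%d\n",
              x$summary$finalLinks, x$summary$finalLinks / x$meta$nNodes,
              min(x$summary$incomingDegrees), max(x$summary$incomingDegrees)))
  invisible(x)
}

#' Run the full dual-attractor pruning experiment
#'
#' Takes a completed single-attractor run (or a bare skeleton matrix plus
#' its attractor), draws a second pattern `r` exactly orthogonal to `s`,
#' grafts it on with [buildDualMatrix()], bulk-prunes the added links to
#' `bulkTarget` links per node, and prunes the remaining added links one
#' at a time with [dualSequentialPrune()], never touching the skeleton.
#'
#' @param skeleton A `"singleAttractorRun"` object, or a minimal skeleton
#'   weight matrix (then `s` must be given).
#' @param s Designated first attractor (ignored when `skeleton` is a run).
#' @param seed Master seed for this experiment's stages.
#' @param nStarts Probe states per retention test (default 200).
#' @param bulkTarget Links per node after bulk pruning (default 15).
#' @inheritParams runSingleAttractorExperiment
#' @return An object of class `"dualAttractorRun"`: a list with `s`, `r`,
#'   `uInitial`, `uFinal`, `trace` (the [dualSequentialPrune()] object),
#'   `secondLossLinksPerNode` and `meta`.
#' @export
runDualAttractorExperiment <- function(skeleton, s = NULL, seed = 1,
                                       nStarts = 200, bulkTarget = 15,
                                       maxIters = 500, maxPeriod = 4,
                                       snapshotEvery = 25, maxResample = 20,
                                       outDir = NULL) {
  if (inherits(skeleton, "singleAttractorRun")) {
    s <- skeleton$s
    tstar <- skeleton$tstar
  } else {
    tstar <- checkWeightMatrix(skeleton)
    if (is.null(s)) stop("'s' is required with a bare skeleton matrix",
                         call. = FALSE)
  }
  seeds <- deriveSeeds(seed)
  set.seed(seeds[["partner"]])
  r <- orthogonalPartner(s)
  u <- buildDualMatrix(tstar, s, r)
  protectedSet <- attr(u, "protectedSet")
  set.seed(seeds[["bulk"]])
  uBulk <- dualBulkPrune(u, s, r, protectedSet, bulkTarget, nStarts,
                         maxIters, maxPeriod, maxResample)
  set.seed(seeds[["prune"]])
  trace <- dualSequentialPrune(uBulk, s, r, protectedSet, nStarts,
                               maxIters, maxPeriod, snapshotEvery)
  meta <- list(experiment = "dual-attractor pruning",
               nNodes = length(s), masterSeed = seed,
               derivedSeeds = as.list(seeds),
               nStarts = nStarts, bulkTarget = bulkTarget,
               maxIters = maxIters, maxPeriod = maxPeriod,
               attractor = s, secondAttractor = r,
               protectedLinks = length(protectedSet),
               finalLinks = sum(trace$finalNetwork != 0),
               secondLossLinksPerNode = trace$secondLossLinksPerNode,
               packageVersion = as.character(utils::packageVersion("hopnet")))
  run <- structure(list(s = s, r = r, uInitial = u,
                        uFinal = trace$finalNetwork, trace = trace,
                        summary = summarizeRun(trace),
                        secondLossLinksPerNode = trace$secondLossLinksPerNode,
                        meta = meta),
                   class = "dualAttractorRun")
  if (!is.null(outDir)) writeDualRun(run, outDir)
  run
}

#' @export
print.dualAttractorRun <- function(x, ...) {
  cat("Dual-attractor pruning experiment (N =", x$meta$nNodes,
      ", seed =", x$meta$masterSeed, ")\n")
  cat(sprintf("  protected skeleton links: %d\n", x$meta$protectedLinks))
  if (!is.na(x$secondLossLinksPerNode))
    cat(sprintf("  second attractor lost as fixed point at %.2f links/node\n",
                x$secondLossLinksPerNode))
  cat(sprintf("  final net: %d links (%.2f links/node)\n",
              x$meta$finalLinks, x$meta$finalLinks / x$meta$nNodes))
  invisible(x)
}

# -- plain-text run outputs ---------------------------------------------------

writeSingleRun <- function(run, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$trace$steps, file.path(outDir, "trace.csv"),
                   row.names = FALSE)
  writeEdgeList(run$tstar, file.path(outDir, "tstar.tsv"))
  writeSnapshots(run$trace$snapshots, outDir)
  jsonlite::write_json(run$meta, file.path(outDir, "meta.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outDir)
}

writeDualRun <- function(run, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$trace$steps, file.path(outDir, "dual_trace.csv"),
                   row.names = FALSE)
  writeEdgeList(run$uInitial, file.path(outDir, "u_initial.tsv"))
  writeEdgeList(run$uFinal, file.path(outDir, "u_final.tsv"))
  writeSnapshots(run$trace$snapshots, outDir)
  jsonlite::write_json(run$meta, file.path(outDir, "meta.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outDir)
}

writeSnapshots <- function(snapshots, outDir) {
  nm <- setdiff(names(snapshots), "final")
  for (k in nm)
    write.table(snapshots[[k]],
                file.path(outDir, paste0("snapshot_", k, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
}
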