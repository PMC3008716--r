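#' Write a weight matrix as a directed edge-list TSV
#'
#' One row per nonzero entry, tab-separated with header
#' `source  target  weight`, 0-based node indices, `source` the sending
#' node `j` and `target` the receiving node `i` (so `weight` is
#' `w[target + 1, source + 1]`).  The round trip through
#' [readEdgeList()] is lossless given the node count.
#'
#' @param w Square weight matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(w, path) {
  w <- checkWeightMatrix(w)
  nz <- which(w != 0, arr.ind = TRUE)
  edges <- data.frame(source = nz[, "col"] - 1L,
                      target = nz[, "row"] - 1L,
                      weight = w[nz])
  edges <- edges[order(edges$source, edges$target), ]
  write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a directed edge-list TSV back into a weight matrix
#'
#' @param path File written by [writeEdgeList()].
#' @param nNodes Number of nodes; if `NULL`, inferred as one more than the
#'   largest node index in the file (isolated trailing nodes then need an
#'   explicit `nNodes`).
#' @return An N x N numeric weight matrix.
#' @export
readEdgeList <- function(path, nNodes = NULL) {
  edges <- read.delim(path, header = TRUE)
  if (!all(c("source", "target", "weight") %in% names(edges)))
    stop("edge list must have columns source, target, weight", call. = FALSE)
  if (is.null(nNodes))
    nNodes <- max(edges$source, edges$target, 1L) + 1L
  nNodes <- checkNodeCount(nNodes)
  w <- matrix(0, nNodes, nNodes)
  w[cbind(edges$target + 1L, edges$source + 1L)] <- edges$weight
  w
}
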