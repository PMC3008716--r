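#' Draw a random designated attractor state
#'
#' Generates a length-`nNodes` vector with each component independently -1
#' or +1 with probability 1/2.  Such a vector plays two roles: as the
#' designated attractor pattern written into the weight matrix by
#' [outerAttractorMatrix()], and as a random probe state.
#'
#' Randomness comes from the global R stream; call [set.seed()] (or use
#' [deriveSeeds()] for staged experiments) for reproducibility.
#'
#' @param nNodes Number of nodes N (at least 2).
#' @return An integer vector of -1/+1 values of length `nNodes`.
#' @seealso [orthogonalPartner()], [randomInitialStates()]
#' @examples
#' set.seed(1)
#' randomAttractor(8)
#' @export
randomAttractor <- function(nNodes) {
  nNodes <- checkNodeCount(nNodes)
  sample(c(-1L, 1L), nNodes, replace = TRUE)
}

#' Draw a second attractor orthogonal to a first
#'
#' Constructs a -1/+1 vector `r` with inner product zero (`sum(r * s) == 0`)
#' by choosing
#' uniformly at random the N/2 positions on which `r` agrees with `s` and
#' negating the rest.  Exact orthogonality of two +/-1 vectors requires an
#' even number of agreements and disagreements, so N must be even; odd N is
#' an error rather than an approximation.
#'
#' @param s A -1/+1 state vector of even length.
#' @return A -1/+1 vector `r` of the same length with `sum(r * s) == 0`.
#' @examples
#' set.seed(1)
#' s <- randomAttractor(10)
#' r <- orthogonalPartner(s)
#' sum(r * s)  # exactly 0
#' @export
orthogonalPartner <- function(s) {
  s <- checkStateVector(s)
  n <- length(s)
  if (n %% 2L != 0L)
    stop("exact orthogonality of two +/-1 vectors is impossible for odd N (",
         n, "); use an even number of nodes", call. = FALSE)
  agree <- sample.int(n, n %/% 2L)
  r <- -s
  r[agree] <- s[agree]
  r
}

#' Draw random probe initial states
#'
#' Generates `count` independent uniform -1/+1 state vectors, returned as
#' the columns of an N x `count` matrix.  These are the random initial
#' configurations from which retention tests launch the network.
#'
#' @param nNodes Number of nodes N (at least 2).
#' @param count Number of states to draw (at least 1).
#' @return An integer matrix with `nNodes` rows and `count` columns, each
#'   column a -1/+1 state.
#' @examples
#' set.seed(1)
#' x0 <- randomInitialStates(6, 3)
#' @export
randomInitialStates <- function(nNodes, count) {
  nNodes <- checkNodeCount(nNodes)
  count <- checkCount(count, "count")
  matrix(sample(c(-1L, 1L), nNodes * count, replace = TRUE),
         nrow = nNodes, ncol = count)
}

#' Derive per-stage child seeds from a master seed
#'
#' Experiments have several independent sources of randomness (drawing the
#' attractor, bulk pruning, the sequential pruning order together with its
#' probe states, ...).  To make each stage independently reproducible, a
#' single master seed is expanded into named child seeds: the master seed
#' initialises the global stream once and one integer in `[1, 2^31 - 2]` is
#' drawn per stage, in the fixed order given by `purposes`.  Runners then
#' `set.seed()` the relevant child at the start of each stage.
#'
#' The caller's RNG state is restored on exit.
#'
#' @param masterSeed Single integer master seed.
#' @param purposes Character vector of stage names.
#' @return A named integer vector of child seeds.
#' @examples
#' deriveSeeds(17)
#' @export
deriveSeeds <- function(masterSeed,
                        purposes = c("attractor", "partner", "bulk",
                                     "prune", "probes", "trials")) {
  stopifnot(is.numeric(masterSeed), length(masterSeed) == 1L,
            is.finite(masterSeed))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(masterSeed))
  seeds <- sample.int(.Machine$integer.max - 1L, length(purposes))
  names(seeds) <- purposes
  seeds
}

# -- validation helpers -------------------------------------------------------

checkNodeCount <- function(nNodes) {
  if (!is.numeric(nNodes) || length(nNodes) != 1L || is.na(nNodes) ||
      nNodes != round(nNodes) || nNodes < 2)
    stop("'nNodes' must be a single integer >= 2", call. = FALSE)
  as.integer(nNodes)
}

checkCount <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      x != round(x) || x < 1)
    stop("'", name, "' must be a single integer >= 1", call. = FALSE)
  as.integer(x)
}

checkStateVector <- function(s, n = NULL) {
  if (is.matrix(s) && ncol(s) == 1L) s <- drop(s)
  if (!is.numeric(s) || length(s) < 2L || anyNA(s) || !all(s %in% c(-1, 1)))
    stop("a state vector must contain only -1 and +1 values (length >= 2)",
         call. = FALSE)
  if (!is.null(n) && length(s) != n)
    stop("state vector has length ", length(s), " but the network has ",
         n, " nodes", call. = FALSE)
  as.integer(s)
}

checkWeightMatrix <- function(w) {
  if (!is.matrix(w) || !is.numeric(w) || nrow(w) != ncol(w) || anyNA(w))
    stop("a weight matrix must be a square numeric matrix without NAs",
         call. = FALSE)
  w
}
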