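test_that("outer-product matrix is the symmetric rank-1 dyad with eigenvector s", {
  expect_identical(outerAttractorMatrix(c(1, 1)), matrix(1L, 2, 2))
  expect_identical(outerAttractorMatrix(c(1, -1)),
                   matrix(c(1L, -1L, -1L, 1L), 2, 2))
  set.seed(2)
  s <- randomAttractor(50)
  w <- outerAttractorMatrix(s)
  expect_identical(w, t(w))
  expect_true(all(w %*% s == 50 * s))          # T s = N s, exact integers
  ev <- eigen(w, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sort(abs(ev), decreasing = TRUE)[1], 50)
  expect_true(all(abs(ev[-which.max(abs(ev))]) < 1e-8))   # rank 1
})

test_that("synchronous update matches a loop-and-threshold oracle, ties to +1", {
  set.seed(4)
  for (k in 1:30) {
    n <- sample(3:12, 1)
    w <- matrix(sample(-2:2, n * n, replace = TRUE,
                       prob = c(1, 2, 3, 2, 1)), n, n)
    x <- randomAttractor(n)
    expect_identical(hopfieldStep(w, x), oracleStep(w, x))
  }
  # designated pattern and complement are fixed; orthogonal states hit the
  # all-zero input sums and resolve to the all-ones vector
  s <- c(1L, 1L, -1L, 1L, -1L, -1L)
  w <- outerAttractorMatrix(s)
  expect_identical(hopfieldStep(w, s), s)
  expect_identical(hopfieldStep(w, -s), -s)
  r <- orthogonalPartner(s)
  expect_identical(hopfieldStep(w, r), rep(1L, 6))
  expect_error(hopfieldStep(w, c(1, -1)), "length")
})

test_that("fixed-point predicate agrees with one-step identity", {
  s <- c(1L, -1L, 1L, 1L)
  w <- outerAttractorMatrix(s)
  expect_true(isFixedPoint(w, s))
  r <- orthogonalPartner(s)
  if (!all(r == 1L)) expect_false(isFixedPoint(w, r))
  expect_true(isFixedPoint(matrix(0, 4, 4), rep(1, 4)))   # zero input -> +1
  expect_false(isFixedPoint(matrix(0, 4, 4), c(1, -1, 1, 1)))
})

test_that("evolution classifies fixed points, short cycles and nonconvergence", {
  set.seed(6)
  s <- unbalancedAttractor(20)
  w <- outerAttractorMatrix(s)
  for (k in 1:10) {
    x0 <- randomAttractor(20)
    if (sum(x0 * s) == 0) next
    res <- evolveNetwork(w, x0)
    expect_identical(res$outcome, "fixed_point")
    expect_lte(res$iterations, 2)
    expect_true(all(res$terminalStates[, 1] == s) ||
                all(res$terminalStates[, 1] == -s))
  }

  # already at a fixed point: immediate repeat
  res <- evolveNetwork(w, s)
  expect_identical(res$outcome, "fixed_point")
  expect_identical(res$period, 1L)
  expect_lte(res$iterations, 1L)

  # constructed 2-cycle: mutual inhibition flips both nodes each step
  w2 <- matrix(c(0, -1, -1, 0), 2, 2)
  res2 <- evolveNetwork(w2, c(1, 1))
  expect_identical(res2$outcome, "limit_cycle")
  expect_identical(res2$period, 2L)
  expect_identical(ncol(res2$terminalStates), 2L)
  # the two cycle states alternate under the update rule
  expect_identical(hopfieldStep(w2, res2$terminalStates[, 1]),
                   as.integer(res2$terminalStates[, 2]))

  # a 5-cycle permutation exceeds the period-4 screen -> nonconvergent
  p5 <- matrix(0, 5, 5)
  p5[cbind(c(2:5, 1), 1:5)] <- 1
  res5 <- evolveNetwork(p5, c(1, -1, -1, -1, -1), maxIters = 50)
  expect_identical(res5$outcome, "nonconvergent")
  expect_true(is.na(res5$period))
})

test_that("evolution agrees with the full-history oracle on random sparse nets", {
  set.seed(8)
  for (k in 1:20) {
    n <- sample(4:10, 1)
    w <- matrix(sample(c(-1, 0, 0, 1), n * n, replace = TRUE), n, n)
    x0 <- randomAttractor(n)
    got <- evolveNetwork(w, x0, maxIters = 100)
    want <- oracleEvolve(w, x0, maxIters = 100)
    if (want$outcome == "limit_cycle" && want$period > 4) {
      expect_identical(got$outcome, "nonconvergent")
    } else {
      expect_identical(got$outcome, want$outcome)
      expect_identical(got$period, want$period)
      if (got$outcome == "fixed_point")
        expect_identical(as.integer(got$terminalStates[, 1]), want$state)
    }
  }
})

test_that("exhaustive enumeration finds exactly the designated pair on a full net", {
  set.seed(9)
  s <- unbalancedAttractor(8)
  w <- outerAttractorMatrix(s)
  cat8 <- enumerateAttractors(w)
  expect_identical(length(cat8$attractors), 2L)
  expect_identical(cat8$nNonconvergent, 0L)
  states <- lapply(cat8$attractors, function(a) as.integer(a$states[, 1]))
  expect_true(any(vapply(states, identical, logical(1), s)))
  expect_true(any(vapply(states, identical, logical(1), -s)))
  expect_identical(sum(vapply(cat8$attractors, `[[`, integer(1), "basinSize")),
                   256L)
  # ties resolve toward all-ones, so the +s basin is the larger of the two
  bigger <- cat8$attractors[[1]]
  expect_identical(as.integer(bigger$states[, 1]), if (sum(s) > 0) s else -s)
})

test_that("enumeration matches the naive census and refuses large N", {
  expect_error(enumerateAttractors(matrix(0, 6, 6), maxNodes = 5), "refused")

  catz <- enumerateAttractors(matrix(0, 4, 4))
  expect_identical(length(catz$attractors), 1L)
  expect_identical(catz$attractors[[1]]$basinSize, 16L)
  expect_identical(as.integer(catz$attractors[[1]]$states[, 1]), rep(1L, 4))

  set.seed(10)
  for (k in 1:3) {
    n <- 8
    w <- outerAttractorMatrix(unbalancedAttractor(n))
    w[sample(n * n, 40)] <- 0                  # random damage
    got <- enumerateAttractors(w, maxIters = 100)
    want <- oracleEnumerate(w, maxIters = 100)
    gotSizes <- sort(vapply(got$attractors, `[[`, integer(1), "basinSize"))
    wantSizes <- sort(as.integer(want[names(want) != "nonconvergent"]))
    # comparable only when neither side saw cycles beyond the period screen
    if (got$nNonconvergent == 0L && !"nonconvergent" %in% names(want))
      expect_identical(gotSizes, wantSizes)
    expect_identical(sum(gotSizes) + got$nNonconvergent, 256L)
  }
})

test_that("sampled basin fractions agree with exact basins within binomial error", {
  set.seed(12)
  s <- unbalancedAttractor(8)
  tr <- sequentialPrune(outerAttractorMatrix(s), s, nStarts = 50)
  w <- tr$finalNetwork
  exact <- enumerateAttractors(w)
  sFrac <- 0
  for (a in exact$attractors)
    if (identical(as.integer(a$states[, 1]), s))
      sFrac <- a$basinSize / exact$nStates
  probes <- randomInitialStates(8, 400)
  hits <- 0
  for (k in 1:400) {
    res <- evolveNetwork(w, probes[, k])
    if (res$outcome == "fixed_point" && all(res$terminalStates[, 1] == s))
      hits <- hits + 1
  }
  se <- sqrt(sFrac * (1 - sFrac) / 400)
  expect_lt(abs(hits / 400 - sFrac), 4 * se + 1e-9)
})

test_that("complement symmetry: x fixed iff -x fixed for the unpruned net", {
  set.seed(13)
  s <- randomAttractor(12)
  w <- outerAttractorMatrix(s)
  for (k in 1:20) {
    x <- randomAttractor(12)
    if (sum(x * s) == 0) next   # ties break antisymmetry by design
    expect_identical(isFixedPoint(w, x), isFixedPoint(w, -x))
  }
  expect_true(isFixedPoint(w, s) && isFixedPoint(w, -s))
})
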