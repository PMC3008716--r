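test_that("with no skeleton the dual matrix is the exact two-pattern Hebbian sum", {
  s <- c(1L, 1L, -1L, -1L, 1L, -1L)
  r <- c(1L, 1L, -1L, 1L, -1L, 1L)
  expect_identical(sum(r * s), 0L)
  u <- buildDualMatrix(matrix(0, 6, 6), s, r)
  expect_identical(matrix(u, 6, 6), outer(s, s) + outer(r, r))
  expect_true(all(u %in% c(-2L, 0L, 2L)))
  expect_identical(attr(u, "protectedSet"), integer(0))
  expect_true(isFixedPoint(u, s) && isFixedPoint(u, -s))
  expect_true(isFixedPoint(u, r) && isFixedPoint(u, -r))
})

test_that("dual construction keeps skeleton entries and both attractor pairs fixed", {
  set.seed(31)
  s <- randomAttractor(12)
  tr <- sequentialPrune(outerAttractorMatrix(s), s, nStarts = 50)
  r <- orthogonalPartner(s)
  u <- buildDualMatrix(tr$finalNetwork, s, r)
  prot <- attr(u, "protectedSet")
  expect_identical(prot, which(tr$finalNetwork != 0))
  expect_identical(u[prot], tr$finalNetwork[prot])
  free <- setdiff(seq_along(u), prot)
  two <- outer(s, s) + outer(r, r)
  expect_identical(as.vector(u[free]), as.vector(two[free]))
  expect_true(isFixedPoint(u, s) && isFixedPoint(u, r))
})

test_that("dual construction validates orthogonality and fixed points", {
  s <- c(1L, 1L, -1L, -1L)
  expect_error(buildDualMatrix(matrix(0, 4, 4), s, s), "orthogonal")
  # a skeleton that spans every entry forces U = T*, which cannot hold r
  r <- c(1L, -1L, 1L, -1L)
  expect_error(buildDualMatrix(3 * outer(s, s), s, r), "not a fixed point")
})

test_that("the symmetric two-pattern net splits probes about evenly", {
  set.seed(32)
  s <- randomAttractor(50)
  r <- orthogonalPartner(s)
  u <- buildDualMatrix(matrix(0, 50, 50), s, r)
  rt <- dualRetentionTest(u, s, r, nStarts = 400)
  expect_true(rt$retained)
  expect_equal(rt$fractionToFirst + rt$fractionToSecond, 1)
  expect_lt(abs(rt$fractionToSecond - 0.5), 0.12)
})

test_that("the bare minimal skeleton cannot hold the second attractor", {
  set.seed(33)
  s <- randomAttractor(20)
  tr <- sequentialPrune(outerAttractorMatrix(s), s, nStarts = 50)
  r <- orthogonalPartner(s)
  rt <- dualRetentionTest(tr$finalNetwork, s, r, nStarts = 50)
  expect_false(rt$secondIsFixedPoint)
  expect_false(rt$retained)
})

test_that("dual bulk pruning respects the protected set and the link budget", {
  set.seed(34)
  s <- randomAttractor(50)
  trs <- sequentialPrune(bulkPrune(outerAttractorMatrix(s), s, 10,
                                   nStarts = 50), s, nStarts = 50)
  r <- orthogonalPartner(s)
  u <- buildDualMatrix(trs$finalNetwork, s, r)
  prot <- attr(u, "protectedSet")
  ub <- dualBulkPrune(u, s, r, prot, targetLinksPerNode = 15, nStarts = 100)
  expect_identical(sum(ub != 0), 750L)
  expect_identical(ub[prot], u[prot])
  expect_true(attr(ub, "retention")$retained)
  expect_error(dualBulkPrune(u, s, r, prot,
                             targetLinksPerNode = length(prot) / 50 - 0.5),
               "protected")
})

test_that("dual sequential pruning protects the skeleton and tracks the second attractor", {
  set.seed(35)
  s <- randomAttractor(40)
  trs <- sequentialPrune(bulkPrune(outerAttractorMatrix(s), s, 10,
                                   nStarts = 60), s, nStarts = 60)
  tstar <- trs$finalNetwork
  r <- orthogonalPartner(s)
  u <- buildDualMatrix(tstar, s, r)
  prot <- attr(u, "protectedSet")
  ub <- dualBulkPrune(u, s, r, prot, targetLinksPerNode = 15, nStarts = 100)
  dt <- dualSequentialPrune(ub, s, r, prot, nStarts = 100)
  expect_s3_class(dt, "dualTrace")

  # protected entries are bit-identical throughout
  expect_identical(dt$finalNetwork[prot], tstar[prot])

  steps <- dt$steps
  acc <- steps[steps$accepted, ]
  expect_true(all(diff(acc$linksRemaining) == -1L))

  # accepted dual-phase steps keep both attractor pairs fixed
  dualAcc <- acc[acc$mode == "dual", ]
  expect_true(all(dualAcc$secondIsFixedPoint))
  expect_true(all(dualAcc$fractionToSecond >= 0 & dualAcc$fractionToSecond <= 1))

  # capture by the second attractor shrinks as links are pruned
  expect_gt(cor(dualAcc$linksRemaining, dualAcc$fractionToSecond), 0)

  # the run continues past the dual-minimal point into the single phase
  expect_false(is.na(dt$transitionStep))
  expect_true(any(acc$mode == "single"))

  # the second attractor dies no earlier than capture becoming negligible
  lossLpn <- dt$secondLossLinksPerNode
  expect_false(is.na(lossLpn))
  negligible <- acc$linksPerNode[acc$fractionToSecond < 2 / 100]
  expect_gte(max(negligible), lossLpn)

  # first attractor pair survives to the very end
  expect_true(isFixedPoint(dt$finalNetwork, s))
  expect_true(isFixedPoint(dt$finalNetwork, -s))
})
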