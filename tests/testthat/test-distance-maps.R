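test_that("single-voxel mask has unit distances to its face neighbours", {
  m <- array(FALSE, c(5, 5, 5))
  m[3, 3, 3] <- TRUE
  sdm <- signedDistance(BinaryMask(m))
  v <- distanceValues(sdm)
  expect_equal(v[3, 3, 3], -1)
  expect_equal(v[4, 3, 3], 1)
  expect_equal(v[2, 3, 3], 1)
  expect_equal(v[3, 4, 3], 1)
  expect_equal(v[3, 3, 2], 1)
  expect_equal(v[4, 4, 3], sqrt(2))
  expect_equal(v[4, 4, 4], sqrt(3))
})

test_that("a 10 mm digitized ball has centre depth 10 within one voxel", {
  b <- ballMask(c(24L, 24L, 24L), centerMm = c(11.5, 11.5, 11.5),
                radiusMm = 10)
  sdm <- signedDistance(b)
  centreVal <- min(distanceValues(sdm))
  expect_lt(centreVal, -9)
  expect_gt(centreVal, -11)
})

test_that("anisotropic spacing is respected in mm", {
  g <- GridGeometry(c(5L, 5L, 5L), spacing = c(1, 1, 2))
  m <- array(TRUE, c(5, 5, 5))
  m[, , c(1, 5)] <- FALSE  # slab: nearest background is along axis 3
  sdm <- signedDistance(BinaryMask(m, g))
  expect_equal(distanceValues(sdm)[3, 3, 2], -2)
  expect_equal(distanceValues(sdm)[3, 3, 3], -4)
  expect_equal(distanceValues(sdm)[3, 3, 1], 2)

  m2 <- array(FALSE, c(5, 5, 5))
  m2[3, 3, 3] <- TRUE
  sdm2 <- signedDistance(BinaryMask(m2, g))
  expect_equal(distanceValues(sdm2)[3, 3, 4], 2)
  expect_equal(distanceValues(sdm2)[4, 3, 3], 1)
})

test_that("signed distance matches the all-pairs brute-force oracle", {
  withr::local_seed(11)
  for (i in 1:25) {
    m <- randomProperMask()
    got <- distanceValues(signedDistance(m))
    want <- bruteSignedDistance(m)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("mask -> SDF -> mask is the identity, and exact zeros are background", {
  withr::local_seed(12)
  for (i in 1:20) {
    m <- randomProperMask()
    expect_identical(membership(maskFromDistance(signedDistance(m))),
                     membership(m))
  }
  v <- array(1, c(3, 3, 3))
  v[2, 2, 2] <- 0  # on the zero level set: strict rule puts it outside
  v[1, 1, 1] <- -1
  mk <- maskFromDistance(SignedDistanceMap(v))
  expect_false(membership(mk)[2, 2, 2])
  expect_true(membership(mk)[1, 1, 1])
})

test_that("degenerate masks are rejected and all-positive maps warn", {
  expect_error(signedDistance(BinaryMask(array(FALSE, c(3, 3, 3)))),
               "empty")
  expect_error(signedDistance(BinaryMask(array(TRUE, c(3, 3, 3)))),
               "all-foreground")
  expect_warning(m <- maskFromDistance(SignedDistanceMap(array(1, c(3, 3, 3)))),
                 "non-negative everywhere")
  expect_false(any(membership(m)))
  expect_error(maskFromDistance(SignedDistanceMap(array(NaN, c(3, 3, 3)))),
               "non-finite")
})

test_that("weighted superposition: identity, convexity fixed point, weight checks", {
  withr::local_seed(13)
  m <- randomProperMask()
  sdm <- signedDistance(m)
  expect_equal(distanceValues(weightedDistanceSum(list(sdm), 1)),
               distanceValues(sdm))
  expect_equal(distanceValues(weightedDistanceSum(list(sdm, sdm),
                                                  c(0.3, 0.7))),
               distanceValues(sdm))
  expect_error(weightedDistanceSum(list(sdm, sdm), c(0.3, 0.6)),
               "sum to 1")
  expect_error(weightedDistanceSum(list(sdm, sdm), c(1.3, -0.3)),
               "non-negative")
  other <- signedDistance(randomProperMask())
  expect_error(weightedDistanceSum(list(sdm, other), c(0.5, 0.5)),
               "grid mismatch")
})

test_that("one-hot weights reproduce the corresponding mask; fusion is permutation-invariant", {
  withr::local_seed(14)
  sh <- c(10L, 10L, 10L)
  masks <- lapply(1:4, function(i) {
    repeat {
      m <- array(runif(prod(sh)) < 0.4, sh)
      if (any(m) && !all(m)) break
    }
    BinaryMask(m)
  })
  fused1 <- fuseProposals(masks, c(0, 1, 0, 0))
  expect_identical(membership(fused1), membership(masks[[2]]))

  w <- c(0.4, 0.3, 0.2, 0.1)
  perm <- c(3, 1, 4, 2)
  a <- fuseProposals(masks, w)
  b <- fuseProposals(masks[perm], w[perm])
  expect_identical(membership(a), membership(b))
})
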