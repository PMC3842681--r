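test_that("k/s = 0 gives equal unbiased weights; equal scores are symmetric", {
  withr::local_seed(31)
  for (n in c(2, 5, 15)) {
    w <- computeWeights(runif(n), kOverS = 0)
    expect_equal(w, rep(1 / n, n), tolerance = 1e-12)
  }
  w <- computeWeights(rep(0.7, 6), kOverS = 37)
  expect_equal(w, rep(1 / 6, 6), tolerance = 1e-12)
  expect_identical(computeWeights(0.4, kOverS = 5), 1)
})

test_that("very large k/s selects the most similar registration", {
  w <- computeWeights(c(0.95, 0.90, 0.85), kOverS = 1e6)
  expect_equal(w, c(1, 0, 0), tolerance = 1e-6)
})

test_that("N = 2 weights match the closed form Phi(k/s * dm / sqrt(2))", {
  w <- computeWeights(c(0.9, 0.8), kOverS = 10)
  expect_equal(w[1], pnorm(10 * 0.1 / sqrt(2)), tolerance = 1e-9)
  expect_equal(w[1], 0.7602499, tolerance = 1e-6)
  for (dm in c(0.01, 0.05, 0.3)) {
    w <- computeWeights(c(0.5 + dm, 0.5), kOverS = 4)
    expect_equal(w[1], pnorm(4 * dm / sqrt(2)), tolerance = 1e-9)
  }
})

test_that("weights are monotone in similarity and shift-invariant", {
  withr::local_seed(32)
  for (i in 1:10) {
    m <- runif(8)
    w <- computeWeights(m, kOverS = 2)
    expect_identical(order(w), order(m))  # strictly monotone for k/s > 0
    wShift <- computeWeights(m + 3.7, kOverS = 2)
    expect_equal(w, wShift, tolerance = 1e-12)
  }
})

test_that("weights are continuous at k/s -> 0", {
  withr::local_seed(33)
  m <- runif(9)
  w <- computeWeights(m, kOverS = 1e-8)
  expect_lt(max(abs(w - 1 / 9)), 1e-6)
})

test_that("quadrature agrees with Monte-Carlo sampling of the latent model", {
  withr::local_seed(34)
  nSamp <- 2e5
  for (n in 2:4) {
    m <- runif(n)
    k <- 3
    w <- computeWeights(m, kOverS = k)
    q <- matrix(rnorm(nSamp * n, mean = rep(k * m, each = nSamp)),
                nSamp, n)
    best <- max.col(q)
    phat <- tabulate(best, n) / nSamp
    se <- sqrt(pmax(phat * (1 - phat), 1e-12) / nSamp)
    expect_true(all(abs(w - phat) <= 3 * se + 1e-9))
  }
})

test_that("fuseProposals identity cases", {
  withr::local_seed(35)
  m <- randomProperMask(maxDim = 10L)
  expect_identical(membership(fuseProposals(list(m), 1)), membership(m))
  expect_identical(membership(fuseProposals(list(m, m, m),
                                            c(0.2, 0.5, 0.3))),
                   membership(m))
})

test_that("pwfFuse with a single proposal returns its mask for any k/s", {
  ph <- makePhantom(smallPhantomSpec(seed = 41L))
  prop <- AtlasProposal("only", ph$image, ph$mask)
  for (k in c(0, 0.5, 20)) {
    res <- pwfFuse(ph$image, list(prop), PWFConfig(kOverS = k))
    expect_identical(membership(fusedMask(res)), membership(ph$mask))
    expect_equal(fusionWeights(res), 1)
  }
})

test_that("pwfFuse records similarities, weights and config coherently", {
  withr::local_seed(42)
  ens <- makeEnsemble(phantom = smallPhantomSpec(), nAtlases = 5L,
                      controlPointSpacingMm = 8, seed = 7L)
  cfg <- PWFConfig(kOverS = 0.5, marginMm = 5)
  res <- pwfFuse(ens$target, ens$proposals, cfg)
  expect_s4_class(res, "FusionResult")
  expect_equal(sum(fusionWeights(res)), 1, tolerance = 1e-9)
  expect_true(all(fusionWeights(res) >= 0))
  tab <- similarityTable(res)
  expect_identical(tab$atlas_id,
                   vapply(ens$proposals, atlasId, ""))
  expect_true(all(tab$ncc >= -1 & tab$ncc <= 1))
  expect_identical(kOverS(res), 0.5)
  # weights ranked like similarities
  expect_identical(order(fusionWeights(res)), order(tab$ncc))
})

test_that("permuting proposals permutes weights and leaves the fused mask unchanged", {
  withr::local_seed(43)
  ens <- makeEnsemble(phantom = smallPhantomSpec(), nAtlases = 4L,
                      controlPointSpacingMm = 8, seed = 11L)
  cfg <- PWFConfig(kOverS = 2, marginMm = 5)
  resA <- pwfFuse(ens$target, ens$proposals, cfg)
  perm <- c(3, 1, 4, 2)
  resB <- pwfFuse(ens$target, ens$proposals[perm], cfg)
  expect_equal(fusionWeights(resB), fusionWeights(resA)[perm],
               tolerance = 1e-12)
  expect_identical(membership(fusedMask(resB)), membership(fusedMask(resA)))
})

test_that("a degenerate-ROI proposal gets floor similarity (min - 0.1) with a warning", {
  ph <- makePhantom(smallPhantomSpec(seed = 44L))
  good <- AtlasProposal("good", ph$image, ph$mask)
  flat <- AtlasProposal("flat",
                        ImageVolume(array(0, dim(intensities(ph$image))),
                                    geometry(ph$image)),
                        ph$mask)
  expect_warning(
    res <- pwfFuse(ph$image, list(good, flat), PWFConfig(kOverS = 20)),
    "degenerate")
  tab <- similarityTable(res)
  expect_equal(tab$ncc[1], 1)
  expect_equal(tab$ncc[2], 0.9)  # min scoreable (1) minus 0.1
  expect_gt(fusionWeights(res)[1], fusionWeights(res)[2])
  # k/s = 0 still spreads weight uniformly over the failed registration
  expect_warning(
    res0 <- pwfFuse(ph$image, list(good, flat), PWFConfig(kOverS = 0)))
  expect_equal(fusionWeights(res0), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("invalid weighting inputs are rejected", {
  expect_error(computeWeights(numeric(0), 1), "no similarity")
  expect_error(computeWeights(c(0.1, NaN), 1), "finite")
  expect_error(computeWeights(c(0.1, 0.2), -1), ">= 0")
  expect_error(computeWeights(c(0.1, 0.2), 1, quadratureNodes = 8), ">= 32")
  expect_error(PWFConfig(kOverS = -2), "kOverS")
})
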