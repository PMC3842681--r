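test_that("phantoms are deterministic given a seed and distinct across seeds", {
  a <- makePhantom(smallPhantomSpec(seed = 61L))
  b <- makePhantom(smallPhantomSpec(seed = 61L))
  c <- makePhantom(smallPhantomSpec(seed = 62L))
  expect_identical(intensities(a$image), intensities(b$image))
  expect_identical(membership(a$mask), membership(b$mask))
  expect_false(identical(intensities(a$image), intensities(c$image)))
})

test_that("a noiseless, textureless phantom takes exactly two intensity values", {
  spec <- phantomSpec(textureAmplitude = 0, noiseSigma = 0, seed = 1L)
  ph <- makePhantom(spec)
  expect_identical(sort(unique(as.vector(intensities(ph$image)))),
                   c(0, 100))
  expect_identical(intensities(ph$image) == 100, membership(ph$mask))
})

test_that("a 10 mm ball phantom has the analytic ball volume within 5%", {
  spec <- phantomSpec(shape = c(48L, 48L, 48L),
                      ellipsoids = list(list(center = c(23, 23, 23),
                                             semiaxes = c(10, 10, 10))),
                      seed = 1L)
  ph <- makePhantom(spec)
  expect_equal(maskVolume(ph$mask), 4188.8, tolerance = 0.05)
})

test_that("structures clipped by the grid are rejected", {
  expect_error(
    phantomSpec(shape = c(24L, 24L, 24L),
                ellipsoids = list(list(center = c(12, 12, 12),
                                       semiaxes = c(10, 10, 10)))),
    "clearance")
})

test_that("displacement fields: zero sigma is zero, seeds differ, magnitude grows with sigma", {
  g <- GridGeometry(c(16L, 16L, 16L), spacing = c(2, 2, 2))
  f0 <- smoothDisplacementField(deformationSpec(0, seed = 1L), g)
  expect_true(all(f0@displacements == 0))
  f1 <- smoothDisplacementField(deformationSpec(2, seed = 1L), g)
  f2 <- smoothDisplacementField(deformationSpec(2, seed = 2L), g)
  expect_false(identical(f1@displacements, f2@displacements))
  expect_identical(
    f1@displacements,
    smoothDisplacementField(deformationSpec(2, seed = 1L), g)@displacements)

  magSd <- sapply(c(1, 2, 4), function(sig) {
    median(vapply(1:20, function(s) {
      f <- smoothDisplacementField(deformationSpec(sig, seed = 100L + s), g)
      sd(sqrt(rowSums(matrix(f@displacements, ncol = 3)^2)))
    }, numeric(1)))
  })
  expect_true(all(diff(magSd) > 0))
})

test_that("control-point spacing below twice the voxel spacing is rejected", {
  g <- GridGeometry(c(8L, 8L, 8L), spacing = c(2, 2, 4))
  expect_error(
    smoothDisplacementField(deformationSpec(1, controlPointSpacingMm = 6), g),
    "twice the voxel spacing")
})

test_that("warping with a zero field is the identity", {
  ph <- makePhantom(smallPhantomSpec(seed = 63L))
  f0 <- smoothDisplacementField(deformationSpec(0, seed = 1L),
                                geometry(ph$image))
  prop <- applyDeformation(ph$image, ph$mask, f0, atlasId = "id")
  expect_identical(membership(proposalMask(prop)), membership(ph$mask))
  expect_equal(intensities(proposalImage(prop)), intensities(ph$image),
               tolerance = 1e-12)
})

test_that("a pure one-voxel translation shifts the mask by one voxel", {
  ph <- makePhantom(smallPhantomSpec(seed = 64L))
  g <- geometry(ph$image)
  sh <- gridShape(g)
  d <- array(0, c(sh, 3L))
  d[, , , 1] <- spacing(g)[1]  # sample at x + 1 voxel: shift content by -1
  fld <- new("DisplacementField", geometry = g, displacements = d)
  prop <- applyDeformation(ph$image, ph$mask, fld)
  got <- membership(proposalMask(prop))
  want <- membership(ph$mask)
  interior <- 1:(sh[1] - 1)
  expect_identical(got[interior, , ], want[interior + 1L, , ])
})

test_that("mask fidelity degrades monotonically with displacement sigma", {
  ph <- makePhantom(smallPhantomSpec(seed = 65L))
  medDsc <- sapply(c(1, 2, 4), function(sig) {
    median(vapply(1:20, function(s) {
      f <- smoothDisplacementField(
        deformationSpec(sig, controlPointSpacingMm = 8, seed = 200L + s),
        geometry(ph$image))
      dice(proposalMask(applyDeformation(ph$image, ph$mask, f)), ph$mask)
    }, numeric(1)))
  })
  expect_true(all(diff(medDsc) < 0))
})

test_that("an undisplaced noiseless ensemble reproduces truth exactly through fusion", {
  ens <- makeEnsemble(phantom = smallPhantomSpec(), nAtlases = 3L,
                      qualitySpread = c(0, 0, 0),
                      noisePolicy = function(s) 0, seed = 5L)
  for (p in ens$proposals)
    expect_identical(membership(proposalMask(p)), membership(ens$truth))
  for (k in c(0, 20)) {
    res <- pwfFuse(ens$target, ens$proposals, PWFConfig(kOverS = k,
                                                        marginMm = 5))
    expect_identical(membership(fusedMask(res)), membership(ens$truth))
  }
})

test_that("ensembles are deterministic per seed and the manifest DSC is faithful", {
  a <- makeEnsemble(phantom = smallPhantomSpec(), nAtlases = 4L,
                    controlPointSpacingMm = 8, seed = 9L)
  b <- makeEnsemble(phantom = smallPhantomSpec(), nAtlases = 4L,
                    controlPointSpacingMm = 8, seed = 9L)
  c <- makeEnsemble(phantom = smallPhantomSpec(), nAtlases = 4L,
                    controlPointSpacingMm = 8, seed = 10L)
  expect_identical(a$manifest, b$manifest)
  expect_identical(intensities(a$target), intensities(b$target))
  expect_false(identical(a$manifest$dsc_to_truth, c$manifest$dsc_to_truth))
  recomputed <- vapply(a$proposals,
                       function(p) dice(proposalMask(p), a$truth),
                       numeric(1))
  expect_identical(a$manifest$dsc_to_truth, recomputed)
})

test_that("a grossly misregistered atlas gets below-uniform weight at k/s = 20", {
  outlierW <- vapply(1:20, function(s) {
    ens <- makeEnsemble(phantom = smallPhantomSpec(), nAtlases = 8L,
                        qualitySpread = c(rep(1, 7), 8),
                        controlPointSpacingMm = 8, seed = 300L + s)
    res <- pwfFuse(ens$target, ens$proposals,
                   PWFConfig(kOverS = 20, marginMm = 5))
    fusionWeights(res)[8]
  }, numeric(1))
  expect_lt(median(outlierW), 1 / 8)
})

test_that("NCC is informative about segmentation quality (positive Spearman)", {
  rhos <- vapply(1:10, function(s) {
    ens <- makeEnsemble(phantom = smallPhantomSpec(), nAtlases = 8L,
                        controlPointSpacingMm = 8, seed = 400L + s)
    res <- pwfFuse(ens$target, ens$proposals,
                   PWFConfig(kOverS = 0.5, marginMm = 5))
    cor(similarityTable(res)$ncc, ens$manifest$dsc_to_truth,
        method = "spearman")
  }, numeric(1))
  expect_gt(median(rhos), 0)
})

test_that("at default settings fusion beats the average atlas and shrinks the volume", {
  stats <- vapply(1:10, function(s) {
    ens <- makeEnsemble(phantom = smallPhantomSpec(), nAtlases = 8L,
                        controlPointSpacingMm = 8, seed = 500L + s)
    res <- pwfFuse(ens$target, ens$proposals, PWFConfig(marginMm = 5))
    c(dscGain = dice(fusedMask(res), ens$truth) -
        mean(ens$manifest$dsc_to_truth),
      volDiff = maskVolume(fusedMask(res)) -
        mean(vapply(ens$proposals,
                    function(p) maskVolume(proposalMask(p)), numeric(1))))
  }, numeric(2))
  expect_gte(sum(stats["dscGain", ] >= 0), 9)
  expect_gte(sum(stats["volDiff", ] <= 0), 9)
})
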