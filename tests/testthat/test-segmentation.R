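test_that("connected components match a reference flood fill", {
  set.seed(21)
  for (rep in 1:8) {
    m <- array(runif(6 * 6 * 6) < 0.35, c(6, 6, 6))
    for (conn in c(6L, 26L)) {
      lm <- labelComponents(maskFromArray(m), conn)
      ref <- refLabel3d(m, conn)
      expect_identical(max(ref), nLabels(lm))
      ## identical partition and identical label order (raster-scan)
      expect_identical(volData(lm), ref)
    }
  }
})

test_that("adjacency rules distinguish vertex contact from separation", {
  m <- array(FALSE, c(8, 8, 8))
  m[1:3, 1:3, 1:3] <- TRUE; m[6:8, 1:3, 1:3] <- TRUE  # 2-voxel gap
  expect_equal(nLabels(labelComponents(maskFromArray(m), 26L)), 2L)
  m2 <- array(FALSE, c(4, 4, 4))
  m2[1:2, 1:2, 1:2] <- TRUE; m2[3:4, 3:4, 3:4] <- TRUE  # share a vertex
  expect_equal(nLabels(labelComponents(maskFromArray(m2), 26L)), 1L)
  expect_equal(nLabels(labelComponents(maskFromArray(m2), 6L)), 2L)
  empty <- maskFromArray(array(FALSE, c(3, 3, 3)))
  expect_equal(nLabels(labelComponents(empty)), 0L)
  expect_error(labelComponents(maskFromArray(m2), 18L), "connectivity")
})

test_that("the threshold sweep separates touching blobs at the saddle", {
  vol0 <- 4 / 3 * pi * 6^3
  ## two overlapping blurred spheres: centre distance below one diameter
  sp <- rbind(c(15, 15, 10), c(15, 15, 21))
  v <- renderPhantom(sp, c(6, 6), c(30, 30, 31), c(1, 1, 1),
                     psfSigmaUm = 1.2, noiseSD = 0, bgGrey = 0, fgGrey = 200)
  pre <- preprocessVolume(v, threshold = 60, gaussianSigma = 1)
  lm <- iterativeThresholdSplit(pre$vol, pre$mask, vmin = 0.1 * vol0,
                                vmax = 2 * vol0)
  expect_equal(nLabels(lm), 2L)
  tb <- objectStats(lm)
  ## the split falls near the saddle plane between the two centres
  expect_lt(abs(tb$cxUm[1] - 10.5), 3)
  expect_lt(abs(tb$cxUm[2] - 20.5), 3)
})

test_that("disjoint objects need no splitting and bounds can reject", {
  vol0 <- 4 / 3 * pi * 6^3
  sp <- rbind(c(10, 10, 10), c(10, 10, 30))
  v <- renderPhantom(sp, c(6, 6), c(20, 20, 40), c(1, 1, 1),
                     psfSigmaUm = 0, noiseSD = 0, bgGrey = 0, fgGrey = 200)
  msk <- thresholdGrey(v, 100)
  for (crit in c("volume_stability", "max_count")) {
    lm <- iterativeThresholdSplit(v, msk, vmin = 0.5 * vol0, vmax = 2 * vol0,
                                  criterion = crit)
    expect_equal(nLabels(lm), 2L)
    ## agrees exactly with plain component labelling on separated objects
    expect_identical(volData(lm) > 0L, volData(labelComponents(msk)) > 0L)
  }
  ## a sphere whose volume exceeds vmax validates nowhere
  v1 <- renderPhantom(matrix(c(10, 10, 10), 1), 6, c(20, 20, 20), c(1, 1, 1),
                      psfSigmaUm = 0, noiseSD = 0, bgGrey = 0, fgGrey = 200)
  lm0 <- iterativeThresholdSplit(v1, thresholdGrey(v1, 100), vmin = 10,
                                 vmax = 0.3 * vol0)
  expect_equal(nLabels(lm0), 0L)
  expect_error(iterativeThresholdSplit(v1, thresholdGrey(v1, 100),
                                       vmin = 5, vmax = 2), "vmin < vmax")
})

test_that("the sweep is deterministic and labels stay inside the mask", {
  ph <- generatePollinium(phantomSpec(nObjects = 30, rMeanUm = 4,
                                      dim = c(72, 72, 72), seed = 12))
  pre <- preprocessVolume(ph$volume, threshold = 100)
  vb <- 4 / 3 * pi * 4^3
  a <- iterativeThresholdSplit(pre$vol, pre$mask, vmin = vb / 30, vmax = 2 * vb)
  b <- iterativeThresholdSplit(pre$vol, pre$mask, vmin = vb / 30, vmax = 2 * vb)
  expect_identical(volData(a), volData(b))
  expect_true(all(volData(pre$mask)[volData(a) > 0L]))
})

test_that("object statistics report counts, volumes and centroids", {
  a <- array(0L, c(4, 4, 4)); a[2:3, 2:3, 2:3] <- 1L
  lm1 <- new("LabelMap", data = a, spacing = c(1, 1, 1), nLabels = 1L)
  tb <- objectStats(lm1)
  expect_equal(tb$voxelCount, 8)
  expect_equal(tb$volumeUm3, 8)                   # spacing 1 -> 8 um^3
  expect_equal(c(tb$czUm, tb$cyUm, tb$cxUm), c(2, 2, 2))  # symmetric cube
  lmHalf <- new("LabelMap", data = a, spacing = c(0.5, 0.5, 0.5),
                nLabels = 1L)
  expect_equal(objectStats(lmHalf)$volumeUm3, 1)  # 8 * 0.125
  ## volume / voxel count identity per row
  expect_equal(tb$volumeUm3 / tb$voxelCount, prod(voxelSpacing(lm1)))
  expect_error(objectStats(lm1, volFromArray(array(0, c(2, 2, 2)))),
               "differ")
})

test_that("volume-window counting is a plain enumeration", {
  tb <- data.frame(volumeUm3 = c(1, 5, 10, 50))
  expect_equal(countObjects(tb), 4)
  expect_equal(countObjects(tb, 4, 20), 2)
  expect_equal(countObjects(tb, 100, Inf), 0)
  expect_error(countObjects(tb, 10, 4), "vmin <= vmax")
})
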