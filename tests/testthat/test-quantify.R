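makeLabelledSpheres <- function(centers, radii, dims, spacing = c(1, 1, 1)) {
  v <- renderPhantom(centers, radii, dims, spacing, psfSigmaUm = 0,
                     noiseSD = 0, bgGrey = 0, fgGrey = 200)
  labelComponents(thresholdGrey(v, 100))
}

test_that("subset edge rules agree for interior objects and differ at faces", {
  ## three interior spheres plus one straddling the low-x face of the window
  ctr <- rbind(c(10, 10, 12), c(10, 20, 20), c(20, 12, 25), c(15, 15, 6))
  lm <- makeLabelledSpheres(ctr, rep(2.2, 4), c(30, 30, 30))
  roi <- subsetROI(c(4, 4, 5), c(26, 26, 26))
  expect_equal(subsetCount(lm, roi, "centroid"), 4L)
  expect_equal(subsetCount(lm, roi, "all"), 4L)
  expect_equal(subsetCount(lm, roi, "counting_frame"), 3L)  # face toucher out
  ## strictly interior objects: all rules agree
  lmIn <- makeLabelledSpheres(ctr[1:3, ], rep(2.2, 3), c(30, 30, 30))
  for (rule in c("centroid", "counting_frame", "all"))
    expect_equal(subsetCount(lmIn, roi, rule), 3L)
  ## whole-volume window: centroid and `all` count everything
  whole <- subsetROI(c(0, 0, 0), c(30, 30, 30))
  expect_equal(subsetCount(lm, whole, "centroid"), nLabels(lm))
  expect_equal(subsetCount(lm, whole, "all"), nLabels(lm))
  expect_error(subsetCount(lm, roi, "middle"))
})

test_that("mean object volume and extrapolation follow the defining ratios", {
  expect_equal(meanObjectVolume(1000, 100), 10)
  expect_equal(meanObjectVolume(937, 7), 937 / 7)
  expect_error(meanObjectVolume(937, 0), ">= 1")
  expect_equal(extrapolateTotal(2000, 20), 100)
  expect_error(extrapolateTotal(100, 0), "positive")
  ## self-consistency and linearity
  expect_equal(extrapolateTotal(500, meanObjectVolume(500, 50)), 50)
  expect_equal(extrapolateTotal(1000, meanObjectVolume(500, 50)), 100)
})

test_that("whole-volume subsets reproduce the subset count exactly", {
  ## 20 random ovary-like phantoms; roi = everything => N_total == n_subset
  vb <- 4 / 3 * pi * 4^3
  for (seed in 1:20) {
    ph <- generateOvary(phantomSpec(nObjects = 25, rMeanUm = 4, rCV = 0.1,
                                    mode = "loose", dim = c(56, 56, 56),
                                    noiseSD = 8, seed = seed))
    est <- ovuleWorkflow(ph$volume, subsetROI(c(0, 0, 0), c(56, 56, 56)),
                         vmin = vb / 30, vmax = 2 * vb, threshold = 100)
    expect_identical(est@nTotal, est@nSubset)
  }
})

test_that("a manual landmark count overrides the automatic subset count", {
  vb <- 4 / 3 * pi * 4^3
  ph <- generateOvary(phantomSpec(nObjects = 30, rMeanUm = 4, rCV = 0.1,
                                  mode = "loose", dim = c(56, 56, 56),
                                  noiseSD = 8, seed = 3))
  roi <- subsetROI(c(0, 0, 0), c(28, 56, 56))
  auto <- ovuleWorkflow(ph$volume, roi, vmin = vb / 30, vmax = 2 * vb,
                        threshold = 100)
  manual <- ovuleWorkflow(ph$volume, roi, vmin = vb / 30, vmax = 2 * vb,
                          threshold = 100, manualN = auto@nSubset)
  expect_equal(manual@nTotalRaw, auto@nTotalRaw)
  bigger <- ovuleWorkflow(ph$volume, roi, vmin = vb / 30, vmax = 2 * vb,
                          threshold = 100, manualN = auto@nSubset + 5)
  expect_gt(bigger@nTotalRaw, auto@nTotalRaw)
})

test_that("rescaling the voxel spacing leaves the estimate unchanged", {
  vb <- 4 / 3 * pi * 4^3
  ph <- generateOvary(phantomSpec(nObjects = 25, rMeanUm = 4, rCV = 0.1,
                                  mode = "loose", dim = c(56, 56, 56),
                                  noiseSD = 0, seed = 5))
  roi <- subsetROI(c(0, 0, 0), c(28, 56, 56))
  base <- ovuleWorkflow(ph$volume, roi, vmin = vb / 30, vmax = 2 * vb,
                        threshold = 100)
  ## same data declared at 3x the spacing: volumes scale by 27 in both the
  ## numerator and denominator, counts are identical
  v3 <- Volume3D(volData(ph$volume), spacing = 3 * voxelSpacing(ph$volume))
  s3 <- ovuleWorkflow(v3, roi, vmin = 27 * vb / 30, vmax = 27 * 2 * vb,
                      threshold = 100)
  expect_equal(s3@nTotalRaw, base@nTotalRaw)
  expect_equal(s3@meanObjectVolume, 27 * base@meanObjectVolume)
})

test_that("degenerate pollen workflow reduces to a direct count", {
  ## overview doubling as the high-resolution scan with a full-volume roi
  vb <- 4 / 3 * pi * 4^3
  ph <- generateOvary(phantomSpec(nObjects = 20, rMeanUm = 4, rCV = 0.1,
                                  mode = "loose", dim = c(48, 48, 48),
                                  noiseSD = 0, seed = 9))
  est <- pollenWorkflow(ph$volume, ph$volume,
                        subsetROI(c(0, 0, 0), c(48, 48, 48)),
                        vmin = vb / 30, vmax = 2 * vb, threshold = 100)
  expect_identical(est@nTotal, est@nSubset)
  ## a blank overview is an explicit failure
  blank <- Volume3D(array(0, c(48, 48, 48)))
  expect_error(suppressMessages(
    pollenWorkflow(ph$volume, blank, subsetROI(c(0, 0, 0), c(48, 48, 48)),
                   vmin = vb / 30, vmax = 2 * vb, threshold = 100,
                   overviewThreshold = 100)), "zero segmented")
})

test_that("well-separated massulae equal the plain component count", {
  msp <- phantomSpec(nObjects = 60, rMeanUm = 3.5, rCV = 0.15,
                     mode = "massulae", massulaCount = 12,
                     dim = c(144, 144, 144), noiseSD = 8, seed = 6)
  ph <- generatePollinium(msp)
  truth <- length(unique(ph$truth$massula))
  got <- massulaeWorkflow(ph$volume, vmin = 500, vmax = Inf, threshold = 100)
  expect_equal(got, truth)
  pre <- preprocessVolume(ph$volume, threshold = 100)
  expect_equal(nLabels(labelComponents(pre$mask)), truth)
  ## bounds excluding everything yield zero
  expect_equal(massulaeWorkflow(ph$volume, vmin = 1e9, vmax = Inf,
                                threshold = 100), 0)
})

test_that("P:O is a per-flower ratio with guarded division", {
  expect_equal(pollenOvuleRatio(100000, 5000), 20)
  expect_equal(pollenOvuleRatio(215978, 3779), 57.15, tolerance = 1e-4)
  expect_error(pollenOvuleRatio(10, 0), "positive")
})
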