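test_that("phantom generation is a pure function of spec and seed", {
  spec <- phantomSpec(nObjects = 25, rMeanUm = 4, dim = c(72, 72, 72),
                      seed = 7)
  a <- generatePollinium(spec)
  b <- generatePollinium(spec)
  expect_identical(volData(a$volume), volData(b$volume))
  expect_identical(a$truth, b$truth)
  c <- generatePollinium(phantomSpec(nObjects = 25, rMeanUm = 4,
                                     dim = c(72, 72, 72), seed = 8))
  expect_false(identical(a$truth, c$truth))
})

test_that("two clean spheres are rendered disjoint and countable", {
  ph <- generatePollinium(phantomSpec(nObjects = 2, rMeanUm = 5, rCV = 0,
                                      mode = "loose", dim = c(64, 64, 64),
                                      psfSigmaUm = 0, noiseSD = 0, seed = 1))
  expect_equal(ph$count, 2L)
  lm <- labelComponents(thresholdGrey(ph$volume, 100))
  expect_equal(nLabels(lm), 2L)
})

test_that("rendered foreground matches the analytic sphere volume", {
  ## discretization error below 5% for radii of at least 4 voxels
  for (r in c(4, 6, 9)) {
    v <- renderPhantom(matrix(c(15, 15, 15), 1), r, c(30, 30, 30),
                       c(1, 1, 1), psfSigmaUm = 0, noiseSD = 0,
                       bgGrey = 0, fgGrey = 200)
    rendered <- sum(volData(v) > 0)
    expect_lt(abs(rendered - 4 / 3 * pi * r^3) / (4 / 3 * pi * r^3), 0.05)
  }
  ph <- generatePollinium(phantomSpec(nObjects = 40, rMeanUm = 5, rCV = 0.1,
                                      mode = "loose", dim = c(96, 96, 96),
                                      psfSigmaUm = 0, noiseSD = 0, seed = 3))
  rendered <- sum(volData(ph$volume) > 100)
  expect_lt(abs(rendered - ph$totalVolumeUm3) / ph$totalVolumeUm3, 0.05)
})

test_that("ground truth is independent of the imaging parameters", {
  s1 <- phantomSpec(nObjects = 20, rMeanUm = 4, dim = c(72, 72, 72),
                    noiseSD = 0, seed = 5)
  s2 <- phantomSpec(nObjects = 20, rMeanUm = 4, dim = c(72, 72, 72),
                    noiseSD = 30, psfSigmaUm = 2, seed = 5)
  expect_identical(generatePollinium(s1, render = FALSE)$truth,
                   generatePollinium(s2, render = FALSE)$truth)
})

test_that("ovary gaps exclude centres and gapless placement is uniform", {
  spec <- phantomSpec(nObjects = 80, rMeanUm = 4, rCV = 0.1, mode = "loose",
                      dim = c(128, 96, 96), seed = 2)
  gp <- generateOvary(spec, gapFraction = 0.5, render = FALSE)
  expect_false(is.null(gp$gap))
  expect_true(all(gp$truth$zUm < gp$gap[1] | gp$truth$zUm > gp$gap[2]))
  ## without a gap the axial positions pass a uniformity test
  ps <- vapply(1:6, function(s) {
    ph <- generateOvary(phantomSpec(nObjects = 80, rMeanUm = 4, rCV = 0.1,
                                    mode = "loose", dim = c(128, 96, 96),
                                    seed = s), render = FALSE)
    z <- ph$truth$zUm
    suppressWarnings(stats::ks.test(z, "punif", min(z), max(z))$p.value)
  }, numeric(1))
  expect_gt(max(ps), 0.01)        # not systematically rejected
  expect_gt(mean(ps > 0.01), 0.5)
})

test_that("massulae mode produces unequal, labelled sub-aggregates", {
  ph <- generatePollinium(phantomSpec(nObjects = 80, rMeanUm = 3.5,
                                      mode = "massulae", massulaCount = 10,
                                      dim = c(144, 144, 144), seed = 4),
                          render = FALSE)
  sizes <- table(ph$truth$massula)
  expect_equal(length(sizes), 10L)
  expect_gt(max(sizes) / min(sizes), 2)   # few large, many small
})

test_that("the dummy phantom has exact compartment means", {
  dm <- generateDummy(airGrey = 15, refGrey = 180, noiseSD = 0)
  g <- measureDummy(dm$volume, dm$airROI, dm$refROI)
  expect_equal(unname(g), c(15, 180))
  expect_error(generateDummy(50, 50), "distinct")
})

test_that("the flower table is reproducible with recorded effect sizes", {
  t1 <- generateFlowerTable(seed = 42)
  t2 <- generateFlowerTable(seed = 42)
  expect_identical(t1, t2)
  expect_named(t1, c("species", "individual", "position", "strategy",
                     "pollen", "ovule", "po"))
  expect_equal(nrow(t1), 8 * 3 * 3)
  expect_equal(attr(t1, "positionEffect"), 0.8)
  expect_true(all(t1$pollen > 0 & t1$ovule > 0))
  expect_equal(t1$po, t1$pollen / t1$ovule)
  ## the built-in ovule decline is visible in group means
  m <- tapply(t1$ovule, t1$position, mean)
  expect_gt(m["bottom"], m["top"])
})
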