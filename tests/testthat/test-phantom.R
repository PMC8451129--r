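test_that("annulus rasterisation matches the analytic area", {
  cfg <- phantomConfig(nSlices = 1L, gridSize = c(64L, 64L),
                       endoRadius = 20, epiRadius = 30, pixelSpacing = 2,
                       infarctSector = c(0, 0), infarctSlices = integer())
  gt <- buildPhantom(cfg)
  expected <- pi * (30^2 - 20^2) / 2^2
  expect_lt(abs(sum(myocardium(gt)) - expected) / expected, 0.05)
})

test_that("helix-angle field is a linear transmural ramp", {
  cfg <- smallConfig(haEndo = 60, haEpi = -60)
  gt <- buildPhantom(cfg)
  ha <- truthMap(gt, "HA")
  dep <- depthMap(gt)
  myo <- myocardium(gt)
  # midpoint of the ramp is zero, endpoints are the configured angles
  expect_equal(ha[myo], 60 - 1.2 * dep[myo])
  mid <- myo & abs(dep - 50) < 1e-9
  if (any(mid)) expect_true(all(abs(ha[mid]) < 1e-12))
  expect_true(all(abs(ha[myo]) <= 60 + 1e-12))
  # antisymmetry about mid-wall for a symmetric ramp:
  # HA(depth) + HA(100 - depth) = 0 at every voxel depth
  expect_lt(max(abs((60 - 1.2 * dep[myo]) +
                      (60 - 1.2 * (100 - dep[myo])))), 1e-12)
})

test_that("empty infarct sector yields a fully remote myocardium", {
  gt <- buildPhantom(smallConfig(cohort = "control"))
  expect_identical(sum(roiLabels(gt) == 2L), 0L)
  expect_identical(sum(roiLabels(gt) == 1L), sum(myocardium(gt)))
})

test_that("septal segments 8/9 exist and are disjoint from the infarct", {
  gt <- buildPhantom(defaultPhantomConfig("day6"))
  seg <- ahaSegments(gt)
  expect_gt(sum(seg == 8L | seg == 9L), 20)
  expect_identical(sum((seg == 8L | seg == 9L) &
                         roiLabels(gt) == 2L), 0L)
  # and an overlapping sector is rejected
  expect_error(buildPhantom(defaultPhantomConfig(
    "day6", infarctSector = c(60, 180))), "septal")
})

test_that("tensor construction inverts the MD/FA definitions", {
  # delta = FA / sqrt(3 - 2 FA^2): FA = 1/sqrt(6), MD = 4/3e-3
  # gives eigenvalues (2, 1, 1)e-3
  gt <- buildPhantom(smallConfig(regional = data.frame(
    region = c("remote", "infarct"), T1native = 1000, T1post = 500,
    T2 = 58, MD = 4 / 3, FA = 1 / sqrt(6), scar = FALSE)))
  tf <- makeTensorField(gt, includeBlood = FALSE)
  expect_equal(tf@evals[, 1], rep(2e-3, sum(myocardium(gt))),
               tolerance = 1e-12)
  expect_equal(tf@evals[, 2], rep(1e-3, sum(myocardium(gt))),
               tolerance = 1e-12)
  # round trip: recomputing MD/FA from the tensor returns the inputs
  met <- tensorMetrics(tf)
  myo <- myocardium(gt)
  expect_lt(max(abs(met$md[myo] - 4 / 3 * 1e-3)), 1e-12)
  expect_lt(max(abs(met$fa[myo] - 1 / sqrt(6))), 1e-12)
})

test_that("FA = 0 gives an isotropic tensor and FA >= 1 errors", {
  gt <- buildPhantom(smallConfig(regional = data.frame(
    region = c("remote", "infarct"), T1native = 1000, T1post = 500,
    T2 = 58, MD = 1.0, FA = 0, scar = FALSE)))
  tf <- makeTensorField(gt, includeBlood = FALSE)
  expect_equal(tf@d[, "xx"], rep(1e-3, nrow(tf@d)), tolerance = 1e-15)
  expect_equal(tf@d[, "xy"], rep(0, nrow(tf@d)), tolerance = 1e-18)
  gt@maps$FA[which(myocardium(gt))[1]] <- 1
  expect_error(makeTensorField(gt), "FA")
})

test_that("DWI forward model reproduces closed-form signals", {
  gt <- buildPhantom(smallConfig(regional = data.frame(
    region = c("remote", "infarct"), T1native = 1000, T1post = 500,
    T2 = 58, MD = 1.2, FA = 0, scar = FALSE)))
  tf <- makeTensorField(gt, includeBlood = FALSE)
  proto <- defaultDiffusionProtocol(averages = 1L)
  ser <- simulateDWI(tf, proto, s0 = 1000, noiseSigma = 0)
  dat <- imageData(ser)
  myo <- myocardium(gt)
  # isotropic D = d I: signal = s0 exp(-b d) for every direction
  for (j in c(1, 5, 10)) {
    expect_equal(dat[, , , j][myo],
                 rep(1000 * exp(-proto@bval[j] * 1.2e-3), sum(myo)),
                 tolerance = 1e-12)
  }
  # b = 0 synthetic check volume: signal = s0 everywhere in mask
  p0 <- diffusionProtocol(c(0, proto@bval), rbind(c(1, 0, 0), proto@bvec))
  s0ser <- simulateDWI(tf, p0, s0 = 1000, noiseSigma = 0)
  expect_equal(imageData(s0ser)[, , , 1][myo], rep(1000, sum(myo)))
})

test_that("background Rician noise has the Rayleigh mean", {
  set.seed(42)
  x <- riceNoise(rep(0, 1e4), sigma = 30)
  expect_equal(mean(x), 30 * sqrt(pi / 2), tolerance = 0.05)
})

test_that("MOLLI signal follows the inversion-recovery magnitude model", {
  t1 <- array(1100, c(1, 1, 1))
  TI <- c(200, 1100 * log(2), 20000, 24000)
  ser <- simulateMOLLI(t1, TI, noiseSigma = 0, A = 1000)
  s <- imageData(ser)[1, 1, 1, ]
  expect_equal(s[1], abs(1000 - 2000 * exp(-200 / 1100)), tolerance = 1e-12)
  expect_equal(s[2], 0, tolerance = 1e-9)          # null point TI = T1* ln 2
  expect_equal(s[3], 1000, tolerance = 1e-3)        # TI >> T1: signal -> A
  expect_error(simulateMOLLI(t1, c(100, 200, 300)), "4 inversion")
})

test_that("multi-echo signal decays mono-exponentially", {
  t2 <- array(60, c(1, 1, 1))
  ser <- simulateMultiEcho(t2, echoTimes = c(30, 60, 90), noiseSigma = 0,
                           s0 = 1000)
  expect_equal(imageData(ser)[1, 1, 1, 2], 1000 / exp(1),
               tolerance = 1e-12)
  expect_error(simulateMultiEcho(t2, echoTimes = c(0, 30)), "positive")
})

test_that("LGE places scar at the configured contrast above remote", {
  gt <- buildPhantom(smallConfig("day6"))
  lge <- simulateLGE(gt, remoteMean = 100, remoteSD = 10,
                     scarContrast = 15, seed = 5)
  img <- imageData(lge)[, , , 1]
  scar <- truthMap(gt, "scar")
  remote <- myocardium(gt) & !scar
  expect_equal(mean(img[scar]) - mean(img[remote]), 150, tolerance = 10)
  expect_error(simulateLGE(gt, remoteSD = 0), "positive")
})

test_that("contour motion applies the prescribed linear twist", {
  cfg <- smallConfig(torsionSlope = 0.2,
                     strainTargets = c(GRS = 0, GCS = 0, GLS = 0))
  gt <- buildPhantom(cfg)
  tc <- simulateContourMotion(gt, phases = 11L)
  tor <- torsionFromContours(tc)
  # z = {0, 8, 16, 24} mm at 0.2 deg/mm: peak rotations {0, 1.6, 3.2, 4.8}
  pk <- which.max(abs(tor$torsion))
  expect_equal(tor$rotation[pk, ], 0.2 * sliceZ(gt), tolerance = 1e-9)
  expect_equal(tor$peak, 0.2, tolerance = 1e-9)
  # zero slope: every phase has zero rotation
  tc0 <- simulateContourMotion(gt, torsionSlope = 0, phases = 5L)
  expect_true(all(abs(torsionFromContours(tc0)$rotation) < 1e-9))
  expect_error(simulateContourMotion(gt, phases = 1L), "phases")
})

test_that("seeded simulations are reproducible and seeds only move noise", {
  gt <- buildPhantom(smallConfig("day6"))
  a <- simulateMultiEcho(truthMap(gt, "T2"), seed = 9, noiseSigma = 30)
  b <- simulateMultiEcho(truthMap(gt, "T2"), seed = 9, noiseSigma = 30)
  expect_identical(imageData(a), imageData(b))
  c_ <- simulateMultiEcho(truthMap(gt, "T2"), seed = 10, noiseSigma = 30)
  expect_false(identical(imageData(a), imageData(c_)))
  roi <- roiLabels(gt) == 2L
  nroi <- sum(roi)
  d1 <- mean(imageData(a)[, , , 1][roi])
  d2 <- mean(imageData(c_)[, , , 1][roi])
  expect_lt(abs(d1 - d2), 3 * 30 / sqrt(nroi) * sqrt(2))
})
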