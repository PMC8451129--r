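test_that("protocol validation enforces identifiability", {
  expect_error(diffusionProtocol(rep(450, 12), .fibDirs12()),
               "2 distinct b-shells")
  expect_error(diffusionProtocol(c(100, 200), matrix(c(1, 0, 0, 0, 1, 0),
                                                     2, byrow = TRUE)),
               "6 unique")
  expect_error(diffusionProtocol(c(100, rep(450, 11)),
                                 rbind(c(2, 0, 0), .fibDirs12()[1:11, ])),
               "unit vectors")
  p <- defaultDiffusionProtocol()
  expect_identical(length(p@bval), 18L)
  expect_identical(sum(p@bval == 100), 3L)
  expect_identical(sum(p@bval == 200), 3L)
  expect_identical(sum(p@bval == 450), 12L)
  expect_identical(p@averages, 8L)
})

test_that("tensor fit recovers a known diagonal tensor exactly", {
  proto <- defaultDiffusionProtocol(averages = 1L)
  dTrue <- c(2e-3, 1e-3, 1e-3, 0, 0, 0)
  sig <- 1000 * exp(-(proto@bval) * (proto@bvec[, 1]^2 * dTrue[1] +
                                       proto@bvec[, 2]^2 * dTrue[2] +
                                       proto@bvec[, 3]^2 * dTrue[3]))
  stack <- array(rep(sig, each = 1), c(1, 1, 1, 18))
  ser <- seriesFromStack(stack, data.frame(b = proto@bval), "dwi")
  tf <- fitDiffusionTensor(ser, proto, array(TRUE, c(1, 1, 1)))
  expect_lt(max(abs(tf@d[1, ] - dTrue)), 1e-10)
  expect_equal(tf@md[1], 4 / 3 * 1e-3, tolerance = 1e-9)
  expect_equal(tf@fa[1], 1 / sqrt(6), tolerance = 1e-9)
})

test_that("flat signals fit to a zero tensor and isotropic data to FA 0", {
  proto <- defaultDiffusionProtocol(averages = 1L)
  flat <- seriesFromStack(array(1000, c(1, 1, 1, 18)),
                          data.frame(b = proto@bval), "dwi")
  tf <- fitDiffusionTensor(flat, proto, array(TRUE, c(1, 1, 1)))
  expect_lt(max(abs(tf@d)), 1e-12)
  expect_equal(tf@md[1], 0, tolerance = 1e-12)
  expect_equal(tf@fa[1], 0)
  iso <- seriesFromStack(
    array(1000 * exp(-proto@bval * 1.1e-3), c(1, 1, 1, 18)),
    data.frame(b = proto@bval), "dwi")
  tfi <- fitDiffusionTensor(iso, proto, array(TRUE, c(1, 1, 1)))
  expect_equal(tfi@md[1], 1.1e-3, tolerance = 1e-9)
  expect_equal(tfi@fa[1], 0, tolerance = 1e-6)
})

test_that("weighted linear fit agrees with brute-force nonlinear LS", {
  gt <- buildPhantom(smallConfig("week5"))
  tfTrue <- makeTensorField(gt, includeBlood = FALSE)
  proto <- defaultDiffusionProtocol(averages = 1L)
  ser <- simulateDWI(tfTrue, proto, s0 = 1000, noiseSigma = 0)
  tf <- fitDiffusionTensor(ser, proto, myocardium(gt))
  vox <- c(1L, 57L, 203L)
  dat <- imageData(ser)
  Y <- sapply(seq_len(18), function(j) dat[, , , j][myocardium(gt)])
  q <- cbind(proto@bvec[, 1]^2, proto@bvec[, 2]^2, proto@bvec[, 3]^2,
             2 * proto@bvec[, 1] * proto@bvec[, 2],
             2 * proto@bvec[, 1] * proto@bvec[, 3],
             2 * proto@bvec[, 2] * proto@bvec[, 3]) * proto@bval
  for (v in vox) {
    # tensor elements parameterised in 1e-3 mm^2/s so all unknowns are O(1)
    nls <- nlminb(c(log(1000), rep(1, 3), rep(0, 3)), function(p) {
      sum((Y[v, ] - exp(p[1] - (q * 1e-3) %*% p[2:7]))^2)
    }, control = list(rel.tol = 1e-15, abs.tol = 1e-30,
                      eval.max = 5000, iter.max = 2000))
    expect_lt(max(abs(nls$par[2:7] * 1e-3 - tfTrue@d[v, ])), 1e-9)
    expect_lt(max(abs(tf@d[v, ] - tfTrue@d[v, ])), 1e-9)
  }
})

test_that("MD and FA are invariant under tensor rotation", {
  set.seed(8)
  gt <- buildPhantom(smallConfig("week5"))
  tf <- makeTensorField(gt, includeBlood = FALSE)
  idx <- sample(nrow(tf@d), 30)
  for (rep in 1:3) {
    R <- randomRotation()
    for (i in idx) {
      D <- matrix(c(tf@d[i, "xx"], tf@d[i, "xy"], tf@d[i, "xz"],
                    tf@d[i, "xy"], tf@d[i, "yy"], tf@d[i, "yz"],
                    tf@d[i, "xz"], tf@d[i, "yz"], tf@d[i, "zz"]), 3)
      ev <- eigen(R %*% D %*% t(R), symmetric = TRUE)$values
      expect_equal(mean(ev), tf@md[i], tolerance = 1e-12)
      fa <- sqrt(0.5 * ((ev[1] - ev[2])^2 + (ev[2] - ev[3])^2 +
                          (ev[3] - ev[1])^2) / sum(ev^2))
      expect_equal(fa, tf@fa[i], tolerance = 1e-9)
    }
  }
})

test_that("FA limiting cases follow the eigenvalue formula", {
  mk <- function(evals) {
    new("TensorField", mask = array(TRUE, c(1, 1, 1)),
        d = matrix(c(evals, 0, 0, 0), 1,
                   dimnames = list(NULL, c("xx", "yy", "zz", "xy", "xz",
                                           "yz"))),
        evals = matrix(sort(evals, decreasing = TRUE), 1),
        evecs = array(diag(3), c(3, 3, 1)),
        md = mean(evals), fa = 0, flagged = FALSE)
  }
  expect_equal(tensorMetrics(mk(c(2e-3, 1e-3, 1e-3)))$fa[1], 1 / sqrt(6),
               tolerance = 1e-12)
  expect_equal(tensorMetrics(mk(c(1e-3, 1e-3, 1e-3)))$fa[1], 0)
  expect_equal(tensorMetrics(mk(c(1e-3, 0, 0)))$fa[1], 1,
               tolerance = 1e-12)
  expect_equal(tensorMetrics(mk(c(0, 0, 0)))$fa[1], 0)  # defined, not NaN
})

test_that("local frames have the right geometry and depth", {
  # odd grid with 1 mm pixels: a voxel centre sits exactly due east
  circ <- function(r, n = 180) cbind(r * cos(2 * pi * (1:n) / n),
                                     r * sin(2 * pi * (1:n) / n))
  g <- cmrphantom:::.gridCoords(c(49L, 49L), 1)
  r2d <- sqrt(g$x^2 + g$y^2)
  mask <- array(r2d >= 10 & r2d <= 15, c(49, 49, 1))
  contours <- list(list(endo = circ(10), epi = circ(15)))
  fr <- localCoordinateFrame(mask, contours, 1)
  vx <- g$x[mask[, , 1]]; vy <- g$y[mask[, , 1]]
  e <- which(vy == 0 & vx > 0)[1]
  expect_equal(fr@rhat[e, ], c(1, 0, 0), tolerance = 1e-9)
  expect_equal(fr@chat[e, ], c(0, 1, 0), tolerance = 1e-9)
  expect_equal(fr@lhat[e, ], c(0, 0, 1))
  # triad is right-handed and orthonormal
  cr <- cbind(fr@rhat[, 2] * fr@chat[, 3] - fr@rhat[, 3] * fr@chat[, 2],
              fr@rhat[, 3] * fr@chat[, 1] - fr@rhat[, 1] * fr@chat[, 3],
              fr@rhat[, 1] * fr@chat[, 2] - fr@rhat[, 2] * fr@chat[, 1])
  expect_lt(max(abs(cr - fr@lhat)), 1e-9)
  # depth is the normalized radial position: endo 0, mid-wall ring 50
  r <- sqrt(vx^2 + vy^2)
  expect_lt(max(abs(fr@depth - (r - 10) / 5 * 100)), 1)
  mid <- abs(r - 12.5) < 0.25
  expect_lt(max(abs(fr@depth[mid] - 50)), 5.5)
  expect_lt(min(fr@depth), 1)
  # open contour is rejected
  broken <- contours
  broken[[1]]$endo <- broken[[1]]$endo[1:40, ]
  expect_error(localCoordinateFrame(mask, broken, 1), "open")
})

test_that("helix angle respects the projection and sign conventions", {
  gt <- buildPhantom(smallConfig())
  fr <- lvFrames(gt)
  n <- sum(fr@mask)
  mkTf <- function(e1) {
    evecs <- array(0, c(3, 3, n))
    evecs[, 1, ] <- t(e1)
    new("TensorField", mask = fr@mask,
        d = matrix(0, n, 6, dimnames = list(NULL, c("xx", "yy", "zz",
                                                    "xy", "xz", "yz"))),
        evals = matrix(rep(c(2e-3, 1e-3, 1e-3), each = n), n),
        evecs = evecs, md = rep(1e-3, n), fa = rep(0.4, n),
        flagged = rep(FALSE, n))
  }
  expect_true(all(abs(helixAngleMap(mkTf(fr@chat), fr)[fr@mask]) < 1e-9))
  ha45 <- helixAngleMap(mkTf((fr@chat + fr@lhat) / sqrt(2)), fr)
  expect_equal(ha45[fr@mask], rep(45, n), tolerance = 1e-9)
  # antipodal eigenvector gives the same angle
  haNeg <- helixAngleMap(mkTf(-(fr@chat + fr@lhat) / sqrt(2)), fr)
  expect_equal(haNeg[fr@mask], rep(45, n), tolerance = 1e-9)
  # dominantly radial eigenvectors are masked invalid
  haRad <- helixAngleMap(mkTf(fr@rhat), fr)
  expect_true(all(is.na(haRad[fr@mask])))
})

test_that("phantom HA map round-trips through fit and projection", {
  gt <- buildPhantom(smallConfig("week5"))
  tfTrue <- makeTensorField(gt, includeBlood = FALSE)
  proto <- defaultDiffusionProtocol(averages = 1L)
  ser <- simulateDWI(tfTrue, proto, s0 = 1000, noiseSigma = 0)
  tf <- fitDiffusionTensor(ser, proto, myocardium(gt))
  fr <- lvFrames(gt)
  ha <- helixAngleMap(tf, fr)
  truth <- truthMap(gt, "HA")
  ok <- is.finite(ha) & is.finite(truth)
  expect_gt(sum(ok), 0.95 * sum(myocardium(gt)))
  expect_lt(sqrt(mean((ha[ok] - truth[ok])^2)), 3)
})

test_that("transmural gradient recovers linear fields and flags dearth", {
  gt <- buildPhantom(smallConfig(haEndo = 50, haEpi = -50))
  fr <- lvFrames(gt)
  grad <- transmuralHAGradient(truthMap(gt, "HA"), fr, ahaSegments(gt))
  expect_equal(grad$slope, -1.00, tolerance = 1e-9)
  expect_equal(grad$r2, 1, tolerance = 1e-12)
  # constant field: zero slope
  flat <- truthMap(gt, "HA") * 0 + 10
  expect_equal(transmuralHAGradient(flat, fr, ahaSegments(gt))$slope, 0,
               tolerance = 1e-12)
  expect_error(transmuralHAGradient(truthMap(gt, "HA"), fr,
                                    ahaSegments(gt),
                                    useSegments = 99L), "segment")
})

test_that("gradient estimate is unbiased across noisy replicates", {
  gt <- buildPhantom(smallConfig("week5", seed = 2L))
  tfTrue <- makeTensorField(gt)
  proto <- defaultDiffusionProtocol()
  fr <- lvFrames(gt)
  slopes <- vapply(1:6, function(s) {
    ser <- simulateDWI(tfTrue, proto, s0 = 1000, noiseFraction = 1 / 30,
                       seed = 100 + s)
    tf <- fitDiffusionTensor(ser, proto, myocardium(gt))
    transmuralHAGradient(helixAngleMap(tf, fr), fr, ahaSegments(gt))$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) - (-1.26)),
            max(2 * sd(slopes) / sqrt(length(slopes)), 0.02))
})
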