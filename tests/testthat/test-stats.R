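regionTableFixture <- function() {
  # 2 infarct subjects, 2 controls, parameter "p" at two timepoints
  rbind(
    data.frame(subject = "inf01", group = "infarct",
               timepoint = c("baseline", "baseline", "day6", "day6"),
               region = c("infarct", "remote", "infarct", "remote"),
               parameter = "p", value = c(1.2, 1.2, 1.5, 1.2),
               sd = 0, n = 10, units = NA),
    data.frame(subject = "inf02", group = "infarct",
               timepoint = c("baseline", "baseline", "day6", "day6"),
               region = c("infarct", "remote", "infarct", "remote"),
               parameter = "p", value = c(1.0, 1.0, 1.3, 1.0),
               sd = 0, n = 10, units = NA),
    data.frame(subject = c("ctl01", "ctl02"), group = "control",
               timepoint = "day6", region = "remote", parameter = "p",
               value = c(0.9, 1.1), sd = 0, n = 10, units = NA)
  )
}

test_that("regional summaries average ROIs and skip empty ones", {
  maps <- list(T2 = array(c(80, 86, 60, 60), c(4, 1, 1)))
  roi <- array(c(2L, 2L, 1L, 1L), c(4, 1, 1))
  tb <- summarizeRegions(maps, roi, "s1", "infarct", "day6")
  expect_equal(tb$value[tb$region == "infarct"], 83)
  expect_equal(tb$value[tb$region == "remote"], 60)
  expect_equal(tb$sd[tb$region == "remote"], 0)
  roiEmpty <- array(c(1L, 1L, 1L, 1L), c(4, 1, 1))
  expect_warning(summarizeRegions(maps, roiEmpty, "s1"), "empty ROI")
})

test_that("relative change follows both conventions and scales out units", {
  tb <- regionTableFixture()
  rcRem <- relativeChange(tb, "p", "day6", "infarct_vs_remote")
  expect_equal(unname(rcRem$perSubject),
               c(100 * 0.3 / 1.2, 100 * 0.3 / 1.0))
  rcBase <- relativeChange(tb, "p", "day6", "infarct_vs_baseline")
  expect_equal(unname(rcBase$perSubject), c(25, 30))
  # x_infarct = x_ref gives 0%
  rc0 <- relativeChange(tb, "p", "baseline", "infarct_vs_remote")
  expect_equal(unname(rc0$perSubject), c(0, 0))
  # global rescaling leaves the statistic unchanged
  tb2 <- tb; tb2$value <- tb2$value * 37.5
  rc2 <- relativeChange(tb2, "p", "day6", "infarct_vs_baseline")
  expect_equal(rc2$perSubject, rcBase$perSubject, tolerance = 1e-12)
})

test_that("control-remote bias enumerates all normalized pairs", {
  tb <- regionTableFixture()
  b <- controlRemoteBias(tb, "p", "day6")
  expect_identical(b$nPairs, 4L)  # 2 controls x 2 infarct subjects
  # remote 1.1 vs control 0.9: d = 0.2 / 1.0 = +20%
  tb3 <- tb[tb$subject %in% c("inf01", "ctl01"), ]
  tb3$value[tb3$subject == "inf01" & tb3$region == "remote" &
              tb3$timepoint == "day6"] <- 1.1
  tb3$value[tb3$subject == "ctl01"] <- 0.9
  expect_equal(controlRemoteBias(tb3, "p", "day6")$values, 0.2,
               tolerance = 1e-12)
  # identical groups: all differences zero
  tb4 <- tb; tb4$value <- 1
  expect_true(all(controlRemoteBias(tb4, "p", "day6")$values == 0))
  # scale invariance
  tb5 <- tb; tb5$value <- tb5$value * 1e3
  expect_equal(controlRemoteBias(tb5, "p", "day6")$values, b$values,
               tolerance = 1e-12)
})

test_that("t-test conventions cover degenerate inputs", {
  same <- c(1, 2, 3)
  r <- compareGroups(same, same, paired = TRUE)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  # constant paired shift: zero-variance differences, p below machine
  r2 <- compareGroups(c(2, 3, 4), c(1, 2, 3), paired = TRUE)
  expect_true(is.infinite(r2$statistic) && r2$statistic > 0)
  expect_equal(r2$p, 0)
  expect_true(r2$belowMachine)
  # ordinary case agrees with the classical pooled-variance test
  set.seed(5)
  a <- rnorm(8); b <- rnorm(8, 1)
  r3 <- compareGroups(a, b)
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(r3$statistic, unname(tt$statistic))
  expect_equal(r3$p, tt$p.value)
  expect_error(compareGroups(1, c(1, 2)), "n >= 2")
})

test_that("paired test power grows with shift size", {
  set.seed(11)
  pAt <- function(shift) {
    mean(replicate(200, {
      x <- rnorm(6)
      compareGroups(x + shift + rnorm(6, 0, 0.5), x, paired = TRUE)$p
    }) < 0.05)
  }
  expect_gt(pAt(2), 0.95)
  expect_lt(pAt(0), 0.15)
})

test_that("correlation reproduces the exact and null cases", {
  x <- 1:10
  r1 <- correlatePairs(x, 2 * x + 1)
  expect_equal(r1$r, 1, tolerance = 1e-12)
  expect_equal(r1$slope, 2, tolerance = 1e-12)
  expect_equal(r1$intercept, 1, tolerance = 1e-9)
  set.seed(7)
  xr <- rnorm(500); yr <- sample(xr)
  expect_lt(abs(correlatePairs(xr, yr)$r), 0.1)
  expect_error(correlatePairs(rep(1, 5), 1:5), "zero variance")
})

test_that("correlation p matches the t transform of r", {
  # r = 0.59 at n = 14 corresponds to t = 2.53, p ~ 0.026
  r <- 0.59; n <- 14
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  expect_equal(tstat, 2.53, tolerance = 0.01)
  expect_equal(2 * pt(-tstat, n - 2), 0.026, tolerance = 0.02)
  # and correlatePairs agrees with the closed form on real data
  set.seed(3)
  x <- rnorm(14); y <- 0.6 * x + rnorm(14, 0, 0.8)
  cp <- correlatePairs(x, y)
  tEmp <- cp$r * sqrt((cp$n - 2) / (1 - cp$r^2))
  expect_equal(cp$p, 2 * pt(-abs(tEmp), cp$n - 2), tolerance = 1e-12)
})

test_that("confidence band covers the fitted line and narrows mid-range", {
  set.seed(9)
  x <- seq(-2, 2, length.out = 30)
  y <- 1 + 0.5 * x + rnorm(30, 0, 0.3)
  cp <- correlatePairs(x, y)
  expect_true(all(cp$band$lwr <= cp$band$fit & cp$band$fit <= cp$band$upr))
  width <- cp$band$upr - cp$band$lwr
  expect_lt(width[15], width[1])
  expect_lt(width[15], width[30])
})
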