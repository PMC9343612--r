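test_that("background subtraction removes constant offsets and clips", {
  img <- matrix(4.2, 20, 20)
  expect_equal(max(abs(backgroundSubtract(img))), 0)
  # offset cancellation around a centered object
  obj <- matrix(0, 20, 20); obj[8:13, 9:12] <- 3
  expect_equal(backgroundSubtract(obj + 5), backgroundSubtract(obj),
               tolerance = 1e-9)
  set.seed(6)
  noisy <- matrix(rnorm(400), 20, 20)
  expect_gte(min(backgroundSubtract(noisy)), 0)
  expect_error(backgroundSubtract(img, 0.5), "validation error")
  expect_error(backgroundSubtract(matrix(1, 2, 2), 0.4), "validation error")
})

test_that("center of mass follows the weighted-mean formula", {
  expect_equal(centerOfMass1d(c(0, 0, 1, 0, 0)), 2)
  expect_equal(centerOfMass1d(c(1, 0, 3)), 1.5)
  sym <- c(1, 2, 5, 2, 1)
  expect_equal(centerOfMass1d(sym), 2)
  expect_error(centerOfMass1d(c(0, 0, 0)), "degenerate-profile")
})

test_that("com alignment recovers injected jitter on an isolated object", {
  ph <- centeredSphere(32, 7)
  ang <- seq(-60, 60, by = 4)
  sim <- simulateSeries(ph, ang, shiftSigmaPx = 2, seed = 11)
  t <- comAlign(sim$series)
  # x-shifts are fully identifiable; y only relative to the across-angle
  # mean (a rigid global y offset is unobservable from projections)
  truth <- sim$truth$trueShifts
  truth[, "dy"] <- truth[, "dy"] - mean(truth[, "dy"])
  err <- shiftTable(t) + truth
  expect_lt(sqrt(mean(err^2)), 0.5)
  # centered series needs (almost) no correction
  t0 <- comAlign(simulateSeries(ph, ang)$series)
  expect_lt(max(abs(shiftTable(t0))), 0.5)
  # single injected displacement is recovered with opposite sign
  dat <- seriesData(simulateSeries(ph, ang)$series)
  dat[5, , ] <- tomostream:::.shiftImage(dat[5, , ], 0, 3)
  t1 <- comAlign(tiltSeries(dat, ang))
  expect_lt(abs(shiftTable(t1)[5, "dx"] + 3), 0.5)
  # idempotence: applying the corrections leaves nothing to correct
  corrected <- applyTransform(sim$series, t)
  expect_lt(max(abs(shiftTable(comAlign(corrected)))), 0.1)
})

test_that("com alignment is invariant to a modest constant background", {
  ph <- centeredSphere(32, 7)
  ang <- seq(-50, 50, by = 10)
  ser <- simulateSeries(ph, ang)$series
  bg <- 0.2 * max(seriesData(ser))
  withBg <- tiltSeries(seriesData(ser) + bg, ang)
  expect_lt(max(abs(shiftTable(comAlign(withBg)) -
                    shiftTable(comAlign(ser)))), 0.05)
})

test_that("cross-correlation recovers integer translations exactly", {
  ph <- centeredSphere(32, 7)
  img <- seriesData(simulateSeries(ph, 0)$series)[1, , ]
  dat <- array(0, c(2, 32, 32))
  dat[1, , ] <- img
  dat[2, , ] <- tomostream:::.shiftImage(img, 5, -2)
  t <- xcorrAlign(tiltSeries(dat, c(0, 10)))
  # reference is the 0-degree frame; correction undoes the (5, -2) shift
  expect_equal(shiftTable(t)[1, ], c(dy = 0, dx = 0))
  expect_equal(shiftTable(t)[2, ], c(dy = -5, dx = 2))
  # identical consecutive images: zero shifts
  dat[2, , ] <- img
  t0 <- xcorrAlign(tiltSeries(dat, c(0, 10)))
  expect_equal(max(abs(shiftTable(t0))), 0)
  expect_error(xcorrAlign(tiltSeries(dat[1, , , drop = FALSE], 0)),
               "validation error")
})

test_that("cross-correlation accumulates a drift ramp", {
  ph <- centeredSphere(32, 7)
  ang <- seq(-20, 20, by = 5)
  base <- seriesData(simulateSeries(ph, ang)$series)
  drift <- array(0, dim(base))
  for (a in seq_along(ang)) # cumulative (1, 0) px drift per projection
    drift[a, , ] <- tomostream:::.shiftImage(base[a, , ], a - 1, 0)
  t <- xcorrAlign(tiltSeries(drift, ang))
  ref <- which.min(abs(ang))
  expected <- -((seq_along(ang) - 1) - (ref - 1))
  expect_lt(max(abs(shiftTable(t)[, "dy"] - expected)), 0.5)
})

test_that("axis offset is recovered to sub-pixel accuracy across +-8 px", {
  ph <- centeredSphere(32, 7)
  ang <- seq(-60, 60, by = 8)
  for (off in c(-8, -4, 0, 4, 8)) {
    est <- findAxisOffset(simulateSeries(ph, ang, axisOffsetPx = off)$series)
    expect_lt(abs(est - off), 0.5)
  }
  # translation covariance of the estimator
  ser <- simulateSeries(ph, ang)$series
  shifted <- applyTransform(ser, alignmentTransform(
    cbind(rep(0, nAngles(ser)), rep(2, nAngles(ser))), tiltAngles(ser)))
  expect_lt(abs(findAxisOffset(shifted) - findAxisOffset(ser) - 2), 0.1)
})

test_that("applying transforms translates, inverts and round-trips", {
  dat <- array(0, c(1, 16, 16))
  dat[1, 8, 8] <- 1
  ser <- tiltSeries(dat, 0)
  # zero transform: bitwise identity
  t0 <- alignmentTransform(matrix(0, 1, 2), 0)
  expect_identical(seriesData(applyTransform(ser, t0)), seriesData(ser))
  expect_true(isAligned(applyTransform(ser, t0)))
  # integer shift moves the impulse peak exactly
  t1 <- alignmentTransform(matrix(c(3, -2), 1, 2), 0)
  moved <- seriesData(applyTransform(ser, t1))[1, , ]
  expect_equal(which(moved == 1, arr.ind = TRUE)[1, ], c(row = 11, col = 6))
  # applying t then -t restores the original (integer shifts)
  tm1 <- alignmentTransform(matrix(c(-3, 2), 1, 2), 0)
  back <- applyTransform(applyTransform(ser, t1), tm1)
  expect_lt(max(abs(seriesData(back) - seriesData(ser))), 1e-6)
  # axis offset is an extra x correction
  tox <- alignmentTransform(matrix(0, 1, 2), 0, axisOffsetPx = -2)
  expect_identical(seriesData(applyTransform(ser, tox)),
                   seriesData(applyTransform(ser, alignmentTransform(
                     matrix(c(0, 2), 1, 2), 0))))
  expect_error(applyTransform(ser, alignmentTransform(matrix(0, 3, 2),
                                                      c(0, 1, 2))),
               "validation error")
})

test_that("alignment transforms round-trip through the text table", {
  set.seed(7)
  t <- alignmentTransform(matrix(rnorm(14), 7, 2), seq(-30, 30, 10),
                          axisOffsetPx = pi, method = "com")
  f <- tempfile(fileext = ".txt")
  writeTransform(t, f)
  t2 <- readTransform(f)
  expect_identical(shiftTable(t2), shiftTable(t))
  expect_identical(axisOffset(t2), axisOffset(t))
  expect_identical(t2@anglesDeg, t@anglesDeg)
  expect_identical(t2@method, "com")
})
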