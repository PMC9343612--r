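test_that("power method matches analytic and dense Lipschitz constants", {
  # single angle at 0 with nearest weights: every detector bin sums a full
  # column of 8 unit weights, so ||AtA||_2 = 8 exactly
  opn <- projectionOperator(0, c(8, 8), interpolation = "nearest")
  expect_equal(estimateLipschitz(opn, nIters = 100), 8, tolerance = 1e-9)
  # two angles: agree with the dense eigendecomposition within 1%
  for (interp in c("nearest", "linear")) {
    op2 <- projectionOperator(c(0, 90), c(8, 8), interpolation = interp)
    lam <- max(eigen(crossprod(denseOperator(op2)), symmetric = TRUE,
                     only.values = TRUE)$values)
    expect_lt(abs(estimateLipschitz(op2, nIters = 200) / lam - 1), 0.01)
  }
  # 20-angle system, 400 unknowns
  op3 <- projectionOperator(seq(-70, 70, length.out = 20), c(20, 20))
  lam3 <- max(eigen(crossprod(denseOperator(op3)), symmetric = TRUE,
                    only.values = TRUE)$values)
  expect_lt(abs(estimateLipschitz(op3, nIters = 200) / lam3 - 1), 0.01)
})

test_that("dampening envelope decays linearly between its endpoints", {
  expect_equal(dampeningEnvelope(0, 0.3, 100, 0.05), 0.3)
  expect_equal(dampeningEnvelope(100, 0.3, 100, 0.05), 0.05)
  expect_equal(dampeningEnvelope(50, 0.3, 100, 0.05), (0.3 + 0.05) / 2)
  expect_equal(dampeningEnvelope(250, 0.3, 100, 0.05), 0.05) # clamped
  expect_error(dampeningEnvelope(-1, 0.3, 100, 0), "validation error")
})

test_that("ramp filter nulls DC, is symmetric and linear", {
  cst <- matrix(7, 3, 33)
  f <- rampFilter(cst)
  expect_lt(max(abs(rowMeans(f))), 1e-10 * 7)
  # centered impulse: response symmetric about the impulse
  d <- matrix(0, 1, 33); d[1, 17] <- 1
  fd <- rampFilter(d)[1, ]
  expect_lt(max(abs(fd - rev(fd))), 1e-10)
  # linearity
  set.seed(3)
  a <- matrix(rnorm(2 * 32), 2, 32)
  b <- matrix(rnorm(2 * 32), 2, 32)
  expect_lt(max(abs(rampFilter(a + b) - rampFilter(a) - rampFilter(b))),
            1e-10 * max(abs(rampFilter(a))))
  expect_error(rampFilter(matrix(c(1, NA), 1, 2)), "validation error")
})

test_that("wbp localizes an impulse and is linear", {
  imp <- makePhantom("impulse", 32)
  s <- forwardProject(imp, seq(-89.5, 89.5, by = 1))
  rec <- wbp(s)
  expect_equal(which.max(tomoData(rec)), which.max(tomoData(imp)))
  # zero series reconstructs to zero
  z <- wbp(tiltSeries(array(0, c(4, 2, 16)), c(-30, -10, 10, 30)))
  expect_equal(max(abs(tomoData(z))), 0)
  # linearity
  set.seed(4)
  d1 <- array(rnorm(4 * 2 * 16), c(4, 2, 16))
  d2 <- array(rnorm(4 * 2 * 16), c(4, 2, 16))
  ang <- c(-30, -10, 10, 30)
  w1 <- tomoData(wbp(tiltSeries(d1, ang)))
  w2 <- tomoData(wbp(tiltSeries(d2, ang)))
  w12 <- tomoData(wbp(tiltSeries(d1 + d2, ang)))
  expect_lt(max(abs(w12 - w1 - w2)), 1e-8 * max(abs(w1)))
  # slices are published in increasing y order
  seen <- integer(0)
  wbp(tiltSeries(d1, ang), sliceCallback = function(y, sl)
    seen <<- c(seen, y))
  expect_identical(seen, 1:2)
})

test_that("sirt leaves zero data at the zero fixed point", {
  ser <- tiltSeries(array(0, c(3, 2, 12)), c(-20, 0, 20))
  st <- sirtRun(ser, solverConfig("sirt", maxIters = 10))
  expect_equal(max(abs(tomoData(reconVolume(st)))), 0)
  expect_equal(residualHistory(st), rep(0, 10))
  expect_equal(st@iteration, 10L)
})

test_that("sirt residuals are non-increasing and converge toward the
           minimum-norm least-squares solution", {
  n <- 16
  op <- projectionOperator(seq(-70, 70, length.out = 8), c(n, n))
  set.seed(1)
  xt <- matrix(runif(n * n), n, n)
  ser <- sliceSeries(op, xt)
  A <- denseOperator(op)
  xmn <- as.numeric(MASS::ginv(A) %*% (A %*% as.numeric(xt)))
  relErr <- function(st) {
    xs <- as.numeric(tomoData(reconVolume(st)))
    sqrt(sum((xs - xmn)^2) / sum(xmn^2))
  }
  st150 <- sirtRun(ser, solverConfig("sirt", maxIters = 150))
  st600 <- sirtRun(ser, solverConfig("sirt", maxIters = 450), st150)
  expect_true(all(diff(residualHistory(st600)) <= 1e-12))
  expect_lt(relErr(st600), relErr(st150))
  expect_lt(relErr(st600), 0.1)
  # resuming 150 + 450 equals a single 600-iteration run bitwise
  stOnce <- sirtRun(ser, solverConfig("sirt", maxIters = 600))
  expect_identical(tomoData(reconVolume(st600)), tomoData(reconVolume(stOnce)))
  # state bookkeeping
  expect_equal(st600@iteration, 600L)
  expect_equal(length(residualHistory(st600)), 600L)
  expect_equal(st600@nProjectionsUsed, 8L)
  expect_lte(st600@stepSize, st600@stepSafety / st600@lipschitzL + 1e-15)
})

test_that("sirt rejects a state resumed against mismatched geometry", {
  op <- projectionOperator(seq(-60, 60, length.out = 6), c(12, 12))
  ser <- sliceSeries(op, matrix(1, 12, 12))
  st <- sirtRun(ser, solverConfig("sirt", maxIters = 2))
  other <- tiltSeries(seriesData(ser), tiltAngles(ser) + 5)
  expect_error(sirtRun(other, solverConfig("sirt", maxIters = 2), st),
               "state error")
})

test_that("tv norm is exact on analytic cases and 1-homogeneous", {
  expect_equal(tvNorm(tomogram(array(3.7, c(5, 5, 5)))), 0)
  # unit step across the z = 2 plane of a 4x4x4 volume: 16 unit gradients
  v <- array(0, c(4, 4, 4))
  v[, , 3:4] <- 1
  expect_equal(tvNorm(tomogram(v)), 16)
  set.seed(5)
  r <- tomogram(array(runif(6^3), c(6, 6, 6)))
  expect_equal(tvNorm(tomogram(2 * tomoData(r))), 2 * tvNorm(r),
               tolerance = 1e-10)
})

test_that("tvmin with a zero envelope is bitwise-identical to sirt", {
  ph <- makePhantom("spheres", 16)
  ser <- forwardProject(ph, seq(-60, 60, length.out = 10))
  cfg <- solverConfig("tvmin", maxIters = 15, tvStepAlpha0 = 0, nonneg = TRUE)
  a <- tvminRun(ser, cfg)
  b <- sirtRun(ser, cfg)
  expect_identical(tomoData(reconVolume(a)), tomoData(reconVolume(b)))
  expect_identical(residualHistory(a), residualHistory(b))
})

test_that("tv regularization lowers total variation at matched residual", {
  ph <- makePhantom("spheres", 16)
  ser <- forwardProject(ph, seq(-70, 70, length.out = 20))
  stS <- sirtRun(ser, solverConfig("sirt", maxIters = 120, nonneg = TRUE))
  stT <- tvminRun(ser, solverConfig("tvmin", maxIters = 120,
                                    tvStepAlpha0 = 0.2))
  rS <- tail(residualHistory(stS), 1)
  rT <- tail(residualHistory(stT), 1)
  expect_lt(rS, 0.05)
  expect_lt(rT, 0.05)
  expect_lte(tvNorm(reconVolume(stT)), tvNorm(reconVolume(stS)))
  expect_equal(length(tvHistory(stT)), 120L)
  expect_true(all(is.finite(tvHistory(stT))))
  # nonnegativity is enforced after each data step; the subsequent TV
  # descent may introduce at most tiny negative excursions
  expect_gte(min(tomoData(reconVolume(stT))), -1e-3)
})

test_that("normalized residual has the right scale behavior", {
  ph <- makePhantom("spheres", 16)
  ser <- forwardProject(ph, seq(-50, 50, length.out = 7))
  z <- tomogram(array(0, c(16, 16, 16)))
  expect_equal(normalizedResidual(z, ser), 1)
  expect_lt(normalizedResidual(ph, ser), 1e-10)
  # scale invariance
  c3 <- tiltSeries(3 * seriesData(ser), tiltAngles(ser))
  x3 <- tomogram(3 * tomoData(ph))
  expect_equal(normalizedResidual(x3, c3), normalizedResidual(ph, ser),
               tolerance = 1e-12)
  expect_error(normalizedResidual(tomogram(array(0, c(2, 16, 16))), ser),
               "geometry error")
})

test_that("extending a state rescales the descent machinery consistently", {
  ph <- makePhantom("spheres", 16)
  full <- forwardProject(ph, seq(-60, 60, length.out = 12))
  sub <- tiltSeries(seriesData(full)[1:10, , ], tiltAngles(full)[1:10])
  st <- sirtRun(sub, solverConfig("sirt", maxIters = 5))
  L0 <- st@lipschitzL
  st2 <- extendState(st, full)
  expect_equal(st2@nProjectionsUsed, 12L)
  # appending operator rows cannot decrease ||AtA||_2
  expect_gte(st2@lipschitzL, L0)
  expect_equal(st2@stepSize, st2@stepSafety / st2@lipschitzL)
  # warm start retained
  expect_identical(tomoData(reconVolume(st2)), tomoData(reconVolume(st)))
  # removing a previously used projection is a consistency error
  expect_error(extendState(st, tiltSeries(seriesData(full)[3:12, , ],
                                          tiltAngles(full)[3:12])),
               "consistency error")
  # wbp mode: extension equals batch recomputation bitwise
  stw <- sirtRun(sub, solverConfig("sirt", maxIters = 1))
  stw@config <- solverConfig("wbp")
  stw2 <- extendState(stw, full)
  expect_identical(tomoData(reconVolume(stw2)), tomoData(wbp(full)))
})

test_that("history export writes the expected CSV columns", {
  ph <- makePhantom("spheres", 16)
  ser <- forwardProject(ph, seq(-30, 30, length.out = 5))
  st <- tvminRun(ser, solverConfig("tvmin", maxIters = 4))
  f <- tempfile(fileext = ".csv")
  writeHistoryCsv(st, f)
  df <- read.csv(f)
  expect_identical(names(df), c("iteration", "n_projections",
                                "normalized_residual", "tv"))
  expect_equal(nrow(df), 4L)
  expect_equal(df$normalized_residual, residualHistory(st))
})
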