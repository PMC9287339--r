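mese <- paperProtocols()$MESE_T2
tm <- timingAxis(mese)

test_that("noise floor is the mean background magnitude of the last frame", {
  img <- array(0, dim = c(32, 32, 3))
  img[, , 3] <- 3
  s <- seriesFromArray(img, sequenceProtocol("MESE_T2", 3,
                                             timingAxis = tm[1:3]))
  mask <- matrix(TRUE, 32, 32)
  expect_equal(sigmaFloor(estimateNoiseFloor(s, mask)), 3)
  # Rayleigh background: mean converges to sigma * sqrt(pi/2)
  set.seed(11)
  sigma <- 2
  ray <- sqrt(stats::rnorm(1e4, 0, sigma)^2 + stats::rnorm(1e4, 0, sigma)^2)
  img2 <- array(0, dim = c(100, 100, 3))
  img2[, , 3] <- ray
  s2 <- seriesFromArray(img2, sequenceProtocol("MESE_T2", 3,
                                               timingAxis = tm[1:3]))
  est <- estimateNoiseFloor(s2, matrix(TRUE, 100, 100))
  expect_equal(sigmaFloor(est), sigma * sqrt(pi / 2), tolerance = 0.02)
  # default: four 8x8 corner patches; all-zero corners give 0
  zs <- seriesFromArray(array(0, dim = c(32, 32, 3)),
                        sequenceProtocol("MESE_T2", 3, timingAxis = tm[1:3]))
  e0 <- estimateNoiseFloor(zs)
  expect_equal(sigmaFloor(e0), 0)
  expect_equal(e0@source, "corner_patches")
  # too-small masks are rejected with the voxel count
  small <- matrix(FALSE, 32, 32); small[1:7, 1] <- TRUE
  expect_error(estimateNoiseFloor(s, small), "7 voxels")
})

test_that("noise-floor subtraction is quadrature with clamping at zero", {
  expect_equal(subtractNoiseFloor(5, 3), 4)
  expect_equal(subtractNoiseFloor(2, 3), 0)
  x <- matrix(runif(20, 0, 10), 4, 5)
  expect_equal(subtractNoiseFloor(x, 0), x)
  expect_equal(subtractNoiseFloor(x, zeroNoise()), x)
  expect_error(subtractNoiseFloor(-1, 2), "non-negative")
})

test_that("noiseless data refit to the generating parameters", {
  y <- monoexpDecay(tm, 100, 0.05)
  fit <- fitVoxel(tm, y, "MESE_T2")
  expect_true(fit@valid)
  expect_equal(relaxationTime(fit), 0.05, tolerance = 1e-6)
  expect_equal(fitParams(fit)@amplitude, 100, tolerance = 1e-6)

  ir <- paperProtocols()$IR_T1
  yIR <- irMagnitude(timingAxis(ir), 80, 1.4)
  fitIR <- fitVoxel(timingAxis(ir), yIR, "IR_T1")
  expect_equal(relaxationTime(fitIR), 1.4, tolerance = 1e-6)

  tr <- timingAxis(paperProtocols()$RAFF2)
  yR <- abs(raffSignal(tr, 100, 0.08, 30))
  yRi <- abs(raffSignal(tr, 100, 0.08, 30, -95, inverted = TRUE))
  fitR <- fitVoxel(tr, yR, "RAFF2", tInv = tr, yInv = yRi)
  expect_equal(relaxationTime(fitR), 0.08, tolerance = 1e-6)
  expect_equal(fitParams(fitR)@steadyState, 30, tolerance = 1e-5)
  expect_equal(fitParams(fitR)@invertedAmplitude, -95, tolerance = 1e-5)
})

test_that("fits are invariant under uniform signal scaling", {
  set.seed(5)
  y <- monoexpDecay(tm, 100, 0.04) + stats::rnorm(10, 0, 1)
  y <- pmax(y, 0)
  f1 <- fitVoxel(tm, y, "MESE_T2")
  for (c in c(0.01, 3, 1000)) {
    fc <- fitVoxel(tm, c * y, "MESE_T2")
    expect_equal(relaxationTime(fc), relaxationTime(f1), tolerance = 1e-6)
    expect_equal(fitParams(fc)@amplitude, c * fitParams(f1)@amplitude,
                 tolerance = 1e-6)
  }
})

test_that("degenerate voxels yield valid = FALSE, never an error", {
  f <- fitVoxel(tm, rep(0, 10), "MESE_T2")
  expect_false(f@valid)
  f2 <- fitVoxel(tm, c(rep(0, 9), NA), "MESE_T2")
  expect_false(f2@valid)
  expect_error(fitVoxel(tm[1:2], c(1, 2), "MESE_T2"), ">= 3 samples")
  expect_error(fitVoxel(tm, monoexpDecay(tm, 1, 0.05), "RAFF2"),
               "companion")
})

test_that("map fitting recovers the layered phantom (noiseless and SNR 50)", {
  spec0 <- defaultPhantom(noiseSigma = 0)
  s0 <- simulateSeries(spec0, mese, 0)
  m0 <- fitMap(s0, noise = zeroNoise())
  truth <- phantomTruth(spec0, mese, 0)
  ok <- validityMask(m0)
  expect_gt(sum(ok), 1000)
  expect_lt(max(abs(relaxationTime(m0)[ok] - truth[ok]) / truth[ok]), 1e-8)

  # per-layer median within 3% of the generating values at SNR 50
  spec <- defaultPhantom(seed = 3)
  m <- fitMap(simulateSeries(spec, mese, 0))
  lab <- phantomLabels(spec, 0)
  for (i in which(attr(lab, "layers") != "bone")) {
    sel <- lab == i & validityMask(m)
    expect_gt(sum(sel), 50)
    expect_equal(stats::median(relaxationTime(m)[sel]),
                 stats::median(phantomTruth(spec, mese, 0)[sel]),
                 tolerance = 0.03)
  }
})

test_that("an all-noise series produces an essentially empty map", {
  empty <- phantomSpec(grid = c(48, 48), layers = list(), noiseSigma = 2,
                       seed = 9)
  s <- simulateSeries(empty, mese, 0)
  m <- fitMap(s)
  # foreground threshold 3 * sigma_floor keeps pure-noise voxels out
  expect_lt(sum(validityMask(m)) / prod(dim(validityMask(m))), 0.005)
})

test_that("RAFF map fitting requires a geometry-matched companion", {
  spec0 <- defaultPhantom(noiseSigma = 0)
  raff <- paperProtocols()$RAFF2
  s <- simulateSeries(spec0, raff, 0)
  expect_error(fitMap(s, noise = zeroNoise()), "companion")
  small <- phantomSpec(grid = c(32, 32), layers = spec0@layers,
                       noiseSigma = 0, seed = 1)
  cBad <- simulateSeries(small, withInversion(raff), 0)
  expect_error(fitMap(s, noise = zeroNoise(), companion = cBad),
               "geometry")
  cOk <- simulateSeries(spec0, withInversion(raff), 0)
  m <- fitMap(s, noise = zeroNoise(), companion = cOk)
  truth <- phantomTruth(spec0, raff, 0)
  ok <- validityMask(m)
  expect_lt(max(abs(relaxationTime(m)[ok] - truth[ok]) / truth[ok]), 1e-6)
  expect_equal(dim(steadyStateMap(m)), dim(relaxationTime(m)))
})

test_that("quadrature subtraction shrinks the low-SNR T2 bias", {
  set.seed(17)
  T2 <- 0.05; s0 <- 100; sigma <- 10  # SNR 10
  fitT <- function(y) relaxationTime(fitVoxel(tm, y, "MESE_T2"))
  tSub <- tRaw <- numeric(400)
  for (i in seq_len(400)) {
    m <- sqrt((monoexpDecay(tm, s0, T2) + stats::rnorm(10, 0, sigma))^2 +
                stats::rnorm(10, 0, sigma)^2)
    tRaw[i] <- fitT(m)
    tSub[i] <- fitT(subtractNoiseFloor(m, sigma * sqrt(pi / 2)))
  }
  expect_lt(abs(mean(tSub) - T2), abs(mean(tRaw) - T2))
})
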