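spec0 <- defaultPhantom(noiseSigma = 0)
mese <- paperProtocols()$MESE_T2

test_that("rigid transforms normalize, invert and compose correctly", {
  tf <- rigidTransform2D(200, 1, -2, center = c(32.5, 32.5))
  expect_equal(tf@rotationDeg, -160)
  tf2 <- rigidTransform2D(30, 3, -2, center = c(32.5, 32.5))
  inv <- invertTransform(tf2)
  pts <- cbind(c(10, 40, 32.5), c(20, 50, 32.5))
  expect_equal(applyTransform(inv, applyTransform(tf2, pts)), pts,
               tolerance = 1e-6)
  # pure rotation fixes the center
  tf3 <- rigidTransform2D(77, center = c(10, 12))
  expect_equal(drop(applyTransform(tf3, c(10, 12))), c(10, 12))
})

test_that("resampling through the identity reproduces the map bitwise", {
  m <- truthParameterMap(spec0, mese, 0)
  ctr <- c(32.5, 32.5)
  r <- resampleMap(m, rigidTransform2D(0, center = ctr))
  expect_identical(relaxationTime(r), relaxationTime(m))
  expect_identical(validityMask(r), validityMask(m))
})

test_that("a 90-degree rotation preserves values and the mask only shrinks", {
  img <- matrix(0, 64, 64); img[25:40, 25:40] <- 7
  rot <- rotateImage(img, 90)
  inner <- rot[27:38, 27:38]
  expect_equal(inner, matrix(7, 12, 12), tolerance = 1e-6)
  m <- truthParameterMap(spec0, mese, 0)
  for (deg in c(20, 90, 135)) {
    r <- resampleMap(m, rigidTransform2D(deg, center = c(32.5, 32.5)))
    expect_lte(sum(validityMask(r)), sum(validityMask(m)))
  }
})

test_that("resample round trip returns interior voxels unchanged", {
  # smooth map: interpolation error vanishes away from discontinuities
  g <- outer(1:64, 1:64, function(y, x)
    0.05 + 0.03 * exp(-((x - 32.5)^2 + (y - 32.5)^2) / 300))
  m <- new("ParameterMap", relaxationTime = g, amplitude = g * 0 + 1,
           validityMask = matrix(TRUE, 64, 64),
           protocol = mese, orientationDeg = 0)
  tf <- rigidTransform2D(25, 2.5, -1.5, center = c(32.5, 32.5))
  back <- resampleMap(resampleMap(m, tf), invertTransform(tf))
  interior <- matrix(FALSE, 64, 64); interior[16:48, 16:48] <- TRUE
  ok <- validityMask(back) & interior
  expect_equal(sum(ok), sum(interior))  # interior survives the round trip
  expect_equal(relaxationTime(back)[ok], relaxationTime(m)[ok],
               tolerance = 1e-3)

  # on the layered phantom the round trip is exact away from layer edges:
  # the median absolute deviation over jointly valid voxels is tiny
  mp <- truthParameterMap(spec0, mese, 0)
  back2 <- resampleMap(resampleMap(mp, tf), invertTransform(tf))
  ok2 <- validityMask(back2) & validityMask(mp)
  expect_gt(sum(ok2), 0.7 * sum(validityMask(mp)))
  dev <- abs(relaxationTime(back2)[ok2] - relaxationTime(mp)[ok2])
  expect_lt(stats::median(dev), 1e-6)
})

test_that("registration recovers identity, pure rotations and translations", {
  fixed <- firstEcho(defaultPhantom(noiseSigma = 0), 0)
  tfI <- estimateRigid(fixed, fixed)
  expect_lt(abs(tfI@rotationDeg), 0.1)
  expect_lt(max(abs(tfI@translation)), 0.1)

  mov <- rotateImage(fixed, 30); mov[is.na(mov)] <- 0
  tfR <- estimateRigid(mov, fixed)
  expect_lt(abs(tfR@rotationDeg - (-30)), 0.5)

  ctr <- c(32.5, 32.5)
  movT <- resampleImage(fixed, rigidTransform2D(0, 3, -2, ctr))
  movT[is.na(movT)] <- 0
  tfT <- estimateRigid(movT, fixed)
  expect_lt(max(abs(tfT@translation - c(-3, 2))), 0.25)
  expect_lt(abs(tfT@rotationDeg), 0.25)

  expect_error(estimateRigid(matrix(1, 64, 64), fixed), "flat")
})

test_that("physical phantom rotations are recovered within 0.5 deg / 0.5 vox", {
  spec <- defaultPhantom(seed = 2)  # SNR 50 >= the SNR 20 working range
  fixed <- firstEcho(spec, 0)
  for (ang in c(30, 60, 90, 120)) {
    tf <- estimateRigid(firstEcho(spec, ang), fixed)
    expect_lt(abs(tf@rotationDeg - (-ang)), 0.5)
    expect_lt(max(abs(tf@translation)), 0.5)
  }
})

test_that("orientation stacks align maps and propagate validity", {
  # duplicated single orientation: identity transforms, mask preserved
  s0 <- simulateSeries(spec0, mese, 0)
  m0 <- truthParameterMap(spec0, mese, 0)
  st <- buildOrientationStack(rep(list(s0), 3), rep(list(m0), 3))
  for (tf in transforms(st)) {
    expect_lt(abs(tf@rotationDeg), 1e-6)
    expect_lt(max(abs(tf@translation)), 1e-6)
  }
  expect_identical(jointValidity(st), validityMask(m0))

  # missing MESE series is reported by orientation
  sIR <- simulateSeries(spec0, paperProtocols()$IR_T1, 30)
  expect_error(buildOrientationStack(list(s0, sIR), list(m0, m0)),
               "orientation index 2")
  # an empty-foreground orientation cannot be registered
  blank <- seriesFromArray(array(0, dim = c(64, 64, 10)), mese)
  expect_error(buildOrientationStack(list(s0, blank), list(m0, m0)),
               "flat")
})

test_that("co-registered phantom layers agree with the reference labels", {
  spec <- defaultPhantom(seed = 4)
  orients <- orientationsDeg <- c(0, 30, 60, 90, 120)
  series <- lapply(orients, function(o) simulateSeries(spec, mese, o))
  tmaps <- lapply(orients, function(o) truthParameterMap(spec, mese, o))
  st <- buildOrientationStack(series, tmaps)
  lab0 <- phantomLabels(spec, 0)
  agree <- 0; total <- 0
  for (i in 2:5) {
    li <- resampleImage(phantomLabels(spec, orients[i]),
                        transforms(st)[[i]], "nearest")
    jv <- jointValidity(st) & !is.na(li)
    agree <- agree + sum(li[jv] == lab0[jv])
    total <- total + sum(jv)
  }
  expect_gt(agree / total, 0.98)
})
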