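test_that("Michelson contrast identities hold", {
  expect_equal(michelson(c(50, 50, 50, 50, 50)), 0)
  expect_equal(michelson(c(2, 1, 1.5, 1.2, 1.8)), 1 / 3)
  set.seed(21)
  for (i in 1:20) {
    v <- stats::runif(5, 0.01, 3)
    a <- michelson(v)
    expect_gte(a, 0); expect_lte(a, 1)
    # scale invariance
    expect_equal(michelson(17.3 * v), a)
    expect_equal(michelson(1e-4 * v), a)
    # time/rate equivalence (exact algebraic identity)
    expect_equal(michelson(1 / v), a)
  }
  expect_equal(michelson(c(0.025, 0.0955)), michelson(c(40, 1 / 0.0955)))
  expect_equal(michelson(c(0.025, 0.0955)), 0.585062, tolerance = 1e-6)
  # A = 1 only when the minimum is zero
  expect_equal(michelson(c(0, 1, 2)), 1)
  expect_lt(michelson(c(0.001, 1)), 1)
  m0 <- michelson(c(0, 0))
  expect_equal(as.numeric(m0), 0)
  expect_false(attr(m0, "valid"))
  expect_error(michelson(c(-1, 2)), "non-negative")
  expect_error(michelson(3), ">= 2")
  # adding an orientation can only widen the contrast
  v <- c(1.2, 0.9, 1.05)
  expect_gte(michelson(c(v, 1.4)), michelson(v))
  expect_gte(michelson(c(v, 1.0)), michelson(v))
})

test_that("the range-noise bias of A is positive and shrinks with SNR", {
  # equal true values + noise: A is a range statistic, E[A] > 0, and the
  # bias decreases as the noise shrinks relative to the mean
  set.seed(33)
  meanA <- vapply(c(0.1, 0.02, 0.005), function(relSigma)
    mean(vapply(seq_len(400), function(i)
      michelson(pmax(1 + stats::rnorm(5, 0, relSigma), 1e-6)), 0)), 0)
  expect_true(all(meanA > 0))
  expect_true(all(diff(meanA) < 0))
})

test_that("anisotropy maps are zero for identical stacks and mask-aware", {
  t0 <- matrix(0.05, 24, 24)
  valid <- matrix(TRUE, 24, 24); valid[1:4, ] <- FALSE
  st <- stackFromMatrices(rep(list(t0), 5), valid)
  a <- anisotropyMap(st)
  expect_equal(anisoValues(a)[validityMask(a)], rep(0, sum(valid)))
  expect_identical(validityMask(a), valid)
  expect_equal(a@nOrientations, 5)

  # a voxel invalid in any orientation is excluded entirely
  v2 <- valid; v2[10, 10] <- FALSE
  maps2 <- rep(list(t0), 5)
  st2 <- stackFromMatrices(maps2, valid)
  st2@maps[[3]]@validityMask[10, 10] <- FALSE
  st2@jointValidity <- st2@jointValidity & st2@maps[[3]]@validityMask
  expect_false(validityMask(anisotropyMap(st2))[10, 10])
})

test_that("ROI statistics summarize times and anisotropy per label", {
  tmats <- lapply(c(0.05, 0.05, 0.075, 0.05, 0.05), function(v)
    matrix(v, 16, 16))
  st <- stackFromMatrices(tmats)
  a <- anisotropyMap(st)
  expect_equal(anisoValues(a)[1], 0.2)  # (0.075-0.05)/(0.125)
  roi <- matrix(0L, 16, 16); roi[3:8, 3:8] <- 1L; roi[10:14, 10:14] <- 2L
  stats <- roiStats(st, a, roi, labelNames = c("zoneA", "zoneB"))
  expect_equal(nrow(stats), 2)
  expect_equal(stats$roi, c("zoneA", "zoneB"))
  expect_equal(stats$meanAnisotropy, c(0.2, 0.2))
  expect_equal(stats$sdAnisotropy, c(0, 0))
  expect_equal(stats$meanTime_0, c(0.05, 0.05))
  expect_equal(stats$meanTime_60, c(0.075, 0.075))
  expect_equal(stats$anisotropyOfMeans, c(0.2, 0.2))
  expect_equal(stats$nVoxels, c(36, 25))

  # a label with no valid voxels is reported empty, with a warning
  st2 <- st; st2@jointValidity[10:14, 10:14] <- FALSE
  a2 <- anisotropyMap(st2)
  expect_warning(s2 <- roiStats(st2, a2, roi), "label 2")
  expect_equal(s2$nVoxels[2], 0)
  expect_true(is.na(s2$meanAnisotropy[2]))
})

test_that("the anisotropy table aggregates samples in percent", {
  one <- data.frame(quantity = "MESE_T2", roi = "RZ",
                    meanAnisotropy = 0.711)
  t1 <- anisotropyTable(list(one))
  expect_equal(colnames(t1), c("quantity", "roi",
                               "mean_anisotropy_percent", "sd", "n_samples"))
  expect_equal(t1$mean_anisotropy_percent, 71.1)
  expect_equal(t1$n_samples, 1L)

  two <- list(data.frame(quantity = "MESE_T2", roi = "RZ",
                         meanAnisotropy = 0.2),
              data.frame(quantity = "MESE_T2", roi = "RZ",
                         meanAnisotropy = 0.4))
  t2 <- anisotropyTable(two)
  expect_equal(t2$mean_anisotropy_percent, 30.0)
  expect_equal(t2$n_samples, 2L)

  expect_error(anisotropyTable(list()), "empty")
  bad <- list(one, data.frame(quantity = "MESE_T2", roi = "SZ",
                              meanAnisotropy = 0.1))
  expect_error(anisotropyTable(bad), "inconsistent")

  csv <- tempfile(fileext = ".csv")
  anisotropyTable(list(one), file = csv)
  expect_equal(readLines(csv)[1],
               "quantity,roi,mean_anisotropy_percent,sd,n_samples")
  expect_match(readLines(csv)[2], "71.1")
})
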