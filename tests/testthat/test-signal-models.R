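test_that("monoexponential decay evaluates correctly and scales linearly", {
  expect_equal(monoexpDecay(0, 100, 0.05), 100)
  expect_equal(monoexpDecay(0.05, 100, 0.05), 100 * exp(-1))
  expect_lt(monoexpDecay(10, 100, 0.05), 1e-10)
  expect_error(monoexpDecay(0.1, 100, -0.05), "positive")
  expect_error(monoexpDecay(0.1, 100, 0), "positive")
  # linearity in amplitude
  t <- seq(0, 0.2, by = 0.01)
  for (s0 in c(0.5, 7, 300))
    expect_equal(monoexpDecay(t, s0, 0.04),
                 s0 * monoexpDecay(t, 1, 0.04))
  # non-increasing in t
  expect_true(all(diff(monoexpDecay(t, 100, 0.04)) <= 0))
})

test_that("magnitude inversion recovery has its null at TI = T1 ln 2", {
  expect_equal(irMagnitude(1.4 * log(2), 123, 1.4), 0)
  expect_equal(irMagnitude(0, 50, 1.4), 50)
  # direct evaluation of |S0 (1 - 2 exp(-TI/T1))| at TI = 3, T1 = 1.4
  expect_equal(irMagnitude(3, 100, 1.4), 100 * (1 - 2 * exp(-3 / 1.4)))
  expect_equal(irMagnitude(3, 100, 1.4), 76.536, tolerance = 1e-5)
  expect_error(irMagnitude(0.5, 100, -1), "positive")
})

test_that("RAFF signal decays to the shared steady state", {
  expect_equal(raffSignal(100, 100, 0.05, 40), 40)
  expect_equal(raffSignal(100, 100, 0.05, 40, -95, inverted = TRUE), 40)
  expect_equal(raffSignal(0, 100, 0.05, 40), 100)
  expect_equal(raffSignal(0, 100, 0.05, 40, -95, inverted = TRUE), -95)
  expect_equal(raffSignal(0.05, 100, 0.05, 40), 40 + 60 * exp(-1))
  # reduces to monoexponential when Sss = 0, non-inverted
  t <- seq(0, 0.3, by = 0.02)
  expect_equal(raffSignal(t, 80, 0.06, 0), monoexpDecay(t, 80, 0.06))
  expect_error(raffSignal(0.1, 100, 0.05, NA_real_), "steadyState")
  expect_error(raffSignal(0.1, 100, 0.05, 40, inverted = TRUE),
               "invertedAmplitude")
})

test_that("pulse-train durations are n times tau_p", {
  expect_equal(trainDuration(0, 0.0045), 0)
  expect_equal(trainDuration(8, 0.0045), 0.036)
  expect_equal(trainDuration(64, 0.0045), 0.288)
  expect_equal(trainDuration(c(0, 2, 4), 0.0045), c(0, 0.009, 0.018))
  expect_error(trainDuration(-1, 0.0045), ">= 0")
  expect_error(trainDuration(4, 0), "positive")
})

test_that("protocol invariants are enforced", {
  expect_error(sequenceProtocol("MESE_T2", 3, timingAxis = c(0.02, 0.01)),
               "increasing")
  expect_error(sequenceProtocol("CW_T1RHO", 5, timingAxis = c(0, 0.1)),
               "spinLockHz")
  expect_error(sequenceProtocol("MESE_T2", 3, timingAxis = c(0.01, 0.02),
                                spinLockHz = 500), "spinLockHz")
  expect_error(sequenceProtocol("AD_T1RHO", 5, timingAxis = c(0, 0.018),
                                pulseDuration = 0.0045,
                                pulseCounts = c(0, 3)),
               "pulseCounts")
  # timing axis derived from pulse counts
  p <- sequenceProtocol("RAFF2", 5, pulseDuration = 0.0045,
                        pulseCounts = c(0, 2, 4, 8))
  expect_equal(timingAxis(p), c(0, 2, 4, 8) * 0.0045)
  expect_error(withInversion(paperProtocols()$MESE_T2), "RAFF")
  expect_true(withInversion(paperProtocols()$RAFF2)@inversionPrepared)
})

test_that("the protocol set matches the study's printed timing axes", {
  p <- paperProtocols()
  expect_equal(timingAxis(p$IR_T1), c(0.2, 0.5, 0.8, 1.1, 1.4, 3))
  expect_equal(timingAxis(p$MESE_T2)[1], 0.0074)
  expect_length(timingAxis(p$MESE_T2), 10)
  expect_equal(timingAxis(p$CW_T1RHO_200HZ), c(0, 8, 16, 32, 64, 128) / 1000)
  expect_equal(p$AD_T1RHO@pulseCounts, c(0, 4, 8, 12, 24, 36))
  expect_equal(p$RAFF3@pulseCounts, c(0, 2, 4, 8, 16, 32, 64))
  expect_equal(quantityLabel(p$CW_T1RHO_1000HZ), "CW_T1RHO_1000HZ")
})

test_that("predictSignal dispatches on the sequence kind", {
  p <- paperProtocols()
  par2 <- new("ModelParameters", amplitude = 100, relaxationTime = 0.05)
  expect_equal(predictSignal(p$MESE_T2, params = par2),
               monoexpDecay(timingAxis(p$MESE_T2), 100, 0.05))
  parIR <- new("ModelParameters", amplitude = 100, relaxationTime = 1.4)
  expect_equal(predictSignal(p$IR_T1, params = parIR),
               irMagnitude(timingAxis(p$IR_T1), 100, 1.4))
  parR <- new("ModelParameters", amplitude = 100, relaxationTime = 0.08,
              steadyState = 30, invertedAmplitude = -95)
  expect_equal(predictSignal(withInversion(p$RAFF2), params = parR),
               abs(raffSignal(timingAxis(p$RAFF2), 100, 0.08, 30, -95,
                              inverted = TRUE)))
})
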