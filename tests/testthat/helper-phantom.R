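# Shared fixtures: everything is generated in code from the phantom module.

# A ParameterMap holding the analytic ground truth of the phantom at one
# orientation (no fitting involved) -- lets registration/anisotropy tests run
# without the cost of voxel-wise fits.
truthParameterMap <- function(spec, proto, orientationDeg) {
  tt <- phantomTruth(spec, proto, orientationDeg)
  valid <- !is.na(tt)
  amp <- matrix(0, nrow(tt), ncol(tt))
  amp[valid] <- 100
  new("ParameterMap", relaxationTime = tt, amplitude = amp,
      validityMask = valid, protocol = proto,
      orientationDeg = orientationDeg)
}

# An OrientationStack assembled from bare relaxation-time matrices with
# identity transforms (for anisotropy unit tests).
stackFromMatrices <- function(tmats, valid = NULL,
                              proto = paperProtocols()$MESE_T2) {
  d <- dim(tmats[[1]])
  if (is.null(valid)) valid <- matrix(TRUE, d[1], d[2])
  ctr <- c((d[2] + 1) / 2, (d[1] + 1) / 2)
  n <- length(tmats)
  maps <- lapply(seq_len(n), function(i) {
    tt <- tmats[[i]]
    tt[!valid] <- NA_real_
    amp <- matrix(0, d[1], d[2]); amp[valid] <- 1
    new("ParameterMap", relaxationTime = tt, amplitude = amp,
        validityMask = valid, protocol = proto,
        orientationDeg = (i - 1) * 30)
  })
  new("OrientationStack", maps = maps,
      transforms = lapply(seq_len(n),
                          function(i) rigidTransform2D(0, center = ctr)),
      orientationsDeg = (seq_len(n) - 1) * 30, jointValidity = valid)
}

# A minimal RelaxationSeries around a given image stack.
seriesFromArray <- function(img, proto = paperProtocols()$MESE_T2) {
  new("RelaxationSeries", images = img, protocol = proto,
      orientationDeg = 0, pixelSize = 0.09, sampleId = "test")
}

zeroNoise <- function()
  new("NoiseEstimate", sigmaFloor = 0, source = "user_supplied")

# Simulate the first MESE echo image of the phantom at one orientation.
firstEcho <- function(spec, orientationDeg)
  images(simulateSeries(spec, paperProtocols()$MESE_T2,
                        orientationDeg))[, , 1]
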