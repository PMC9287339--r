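#' @include AllClasses.R
NULL

setMethod("show", "SequenceProtocol", function(object) {
  cat("SequenceProtocol:", object@kind)
  if (object@kind == "CW_T1RHO")
    cat(sprintf(" (spin-lock %g Hz)", object@spinLockHz))
  if (object@inversionPrepared) cat(" [inversion-prepared]")
  cat(sprintf("\n  TR = %g s, %d points: %s s\n", object@repetitionTime,
              length(object@timingAxis),
              paste(signif(object@timingAxis, 4), collapse = ", ")))
  invisible(NULL)
})

setMethod("show", "RelaxationSeries", function(object) {
  d <- dim(object@images)
  cat(sprintf("RelaxationSeries '%s': %s at %g deg, %d x %d x %d frames\n",
              object@sampleId, quantityLabel(object@protocol),
              object@orientationDeg, d[1], d[2], d[3]))
  invisible(NULL)
})

setMethod("show", "NoiseEstimate", function(object) {
  cat(sprintf("NoiseEstimate: sigma_floor = %.4g (%s)\n",
              object@sigmaFloor, object@source))
  invisible(NULL)
})

setMethod("show", "FitResult", function(object) {
  p <- object@params
  cat(sprintf("FitResult: T = %.4g s, S0 = %.4g%s (RSS %.3g, %s)\n",
              p@relaxationTime, p@amplitude,
              if (is.finite(p@steadyState))
                sprintf(", Sss = %.4g", p@steadyState) else "",
              object@residualSS,
              if (object@valid) "valid" else "invalid"))
  invisible(NULL)
})

setMethod("show", "ParameterMap", function(object) {
  d <- dim(object@relaxationTime)
  v <- object@relaxationTime[object@validityMask]
  cat(sprintf("ParameterMap: %s at %g deg, %d x %d, %d valid voxels",
              quantityLabel(object@protocol), object@orientationDeg,
              d[1], d[2], sum(object@validityMask)))
  if (length(v))
    cat(sprintf(", median T = %.4g s", stats::median(v)))
  cat("\n")
  invisible(NULL)
})

setMethod("show", "RigidTransform2D", function(object) {
  cat(sprintf(
    "RigidTransform2D: rotation %.3f deg, translation (%.3f, %.3f) vox, center (%.1f, %.1f)\n",
    object@rotationDeg, object@translation[1], object@translation[2],
    object@center[1], object@center[2]))
  invisible(NULL)
})

setMethod("show", "OrientationStack", function(object) {
  cat(sprintf(
    "OrientationStack: %s over %d orientations (%s deg), %d jointly valid voxels\n",
    quantityLabel(object@maps[[1]]@protocol), length(object@maps),
    paste(object@orientationsDeg, collapse = ", "),
    sum(object@jointValidity)))
  invisible(NULL)
})

setMethod("show", "AnisotropyMap", function(object) {
  a <- object@values[object@validityMask]
  cat(sprintf(
    "AnisotropyMap: %s over %d orientations, %d valid voxels, mean A = %.3f\n",
    object@quantity, object@nOrientations, sum(object@validityMask),
    if (length(a)) mean(a) else NA_real_))
  invisible(NULL)
})

setMethod("show", "TissueModel", function(object) {
  cat(sprintf(
    "TissueModel: T1 = %g s, R2_iso = %g 1/s, R2_aniso = %g 1/s, tau_disp = %g s, PD = %g\n",
    object@t1, object@r2Iso, object@r2Aniso, object@tauDisp,
    object@protonDensity))
  invisible(NULL)
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec: %d x %d grid, %d layers (%s), orientations %s deg, sigma = %g, seed = %d\n",
    object@grid[1], object@grid[2], length(object@layers),
    paste(vapply(object@layers, `[[`, "", "name"), collapse = ", "),
    paste(object@orientationsDeg, collapse = ", "),
    object@noiseSigma, as.integer(object@seed)))
  invisible(NULL)
})

setMethod("show", "PipelineConfig", function(object) {
  cat(sprintf(
    "PipelineConfig: sample '%s', quantities %s\n  output: %s, seed %d\n",
    object@sampleId, paste(object@quantities, collapse = ", "),
    object@outputDir, as.integer(object@seed)))
  invisible(NULL)
})
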