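#' @import methods
NULL

## Sequence kinds understood by the pipeline. CW_T1RHO additionally carries a
## spin-lock amplitude; RAFF kinds come in inverted / non-inverted pairs.
.SEQ_KINDS <- c("IR_T1", "MESE_T2", "CW_T1RHO", "AD_T1RHO", "AD_T2RHO",
                "RAFF2", "RAFF3", "RAFF4")
.TRAIN_KINDS <- c("AD_T1RHO", "AD_T2RHO", "RAFF2", "RAFF3", "RAFF4")
.RAFF_KINDS <- c("RAFF2", "RAFF3", "RAFF4")

#' SequenceProtocol: acquisition timing and preparation metadata
#'
#' Describes one relaxometry acquisition: the sequence kind, repetition time,
#' the timing axis (echo times, inversion times, spin-lock durations, or pulse
#' train durations in seconds), and — where applicable — the spin-lock
#' amplitude, the adiabatic pulse duration with the pulse counts, and the
#' inversion-preparation flag (RAFF only).
#'
#' @slot kind character, one of `IR_T1`, `MESE_T2`, `CW_T1RHO`, `AD_T1RHO`,
#'   `AD_T2RHO`, `RAFF2`, `RAFF3`, `RAFF4`.
#' @slot repetitionTime repetition time in seconds.
#' @slot timingAxis strictly increasing, non-negative times in seconds.
#' @slot spinLockHz spin-lock amplitude (gamma B1 / 2 pi) in Hz; `NA` except
#'   for `CW_T1RHO`.
#' @slot pulseDuration adiabatic/RAFF pulse duration tau_p in seconds; `NA`
#'   for non-train kinds.
#' @slot pulseCounts integer pulse counts, one per timing-axis entry, for
#'   pulse-train kinds; `timingAxis == pulseCounts * pulseDuration`.
#' @slot inversionPrepared logical; RAFF series are acquired with and without
#'   an inversion preparation.
#' @export
setClass("SequenceProtocol",
  representation(kind = "character", repetitionTime = "numeric",
                 timingAxis = "numeric", spinLockHz = "numeric",
                 pulseDuration = "numeric", pulseCounts = "numeric",
                 inversionPrepared = "logical"),
  prototype(spinLockHz = NA_real_, pulseDuration = NA_real_,
            pulseCounts = numeric(0), inversionPrepared = FALSE))

setValidity("SequenceProtocol", function(object) {
  msg <- character(0)
  if (length(object@kind) != 1L || !object@kind %in% .SEQ_KINDS)
    msg <- c(msg, paste0("kind must be one of: ",
                         paste(.SEQ_KINDS, collapse = ", ")))
  tx <- object@timingAxis
  if (length(tx) < 1L || any(!is.finite(tx)) || any(tx < 0))
    msg <- c(msg, "timingAxis must be finite and non-negative")
  if (length(tx) > 1L && any(diff(tx) <= 0))
    msg <- c(msg, "timingAxis must be strictly increasing")
  if (length(msg) == 0 && object@kind %in% .TRAIN_KINDS) {
    if (!is.finite(object@pulseDuration) || object@pulseDuration <= 0)
      msg <- c(msg, "pulse-train kinds require pulseDuration > 0")
    else if (length(object@pulseCounts) != length(tx) ||
             any(abs(tx - object@pulseCounts * object@pulseDuration) >
                 1e-9 * max(1, object@pulseDuration)))
      msg <- c(msg, "timingAxis must equal pulseCounts * pulseDuration")
  }
  if (length(msg) == 0 && object@kind == "CW_T1RHO" &&
      (!is.finite(object@spinLockHz) || object@spinLockHz <= 0))
    msg <- c(msg, "CW_T1RHO requires spinLockHz > 0")
  if (length(msg) == 0 && object@kind != "CW_T1RHO" &&
      is.finite(object@spinLockHz))
    msg <- c(msg, "spinLockHz is only meaningful for CW_T1RHO")
  if (length(msg) == 0 && object@inversionPrepared &&
      !object@kind %in% .RAFF_KINDS)
    msg <- c(msg, "inversionPrepared applies to RAFF kinds only")
  if (length(msg)) msg else TRUE
})

#' ModelParameters: parameters of a relaxation signal model
#'
#' @slot amplitude signal amplitude S0 (signal units, >= 0).
#' @slot relaxationTime relaxation time constant in seconds (> 0).
#' @slot steadyState steady-state signal (RAFF only, `NA` otherwise).
#' @slot invertedAmplitude amplitude of the inversion-prepared curve
#'   (RAFF only, `NA` otherwise; may be negative).
#' @export
setClass("ModelParameters",
  representation(amplitude = "numeric", relaxationTime = "numeric",
                 steadyState = "numeric", invertedAmplitude = "numeric"),
  prototype(amplitude = NA_real_, relaxationTime = NA_real_,
            steadyState = NA_real_, invertedAmplitude = NA_real_))

setValidity("ModelParameters", function(object) {
  msg <- character(0)
  if (isTRUE(object@relaxationTime <= 0))
    msg <- c(msg, "relaxationTime must be positive")
  if (isTRUE(object@amplitude < 0))
    msg <- c(msg, "amplitude must be non-negative")
  if (length(msg)) msg else TRUE
})

#' RelaxationSeries: one acquisition at one physical orientation
#'
#' A stack of 2D magnitude frames, one per timing-axis entry, together with
#' the protocol, the nominal physical orientation of the specimen with respect
#' to B0, the pixel size and a sample identifier. Frames are stored as an
#' `nrow x ncol x nframe` array; columns are the x axis, rows the y axis.
#'
#' @slot images numeric 3D array of non-negative magnitudes.
#' @slot protocol a [SequenceProtocol-class].
#' @slot orientationDeg nominal specimen rotation in degrees.
#' @slot pixelSize in-plane pixel size in mm.
#' @slot sampleId sample identifier.
#' @export
setClass("RelaxationSeries",
  representation(images = "array", protocol = "SequenceProtocol",
                 orientationDeg = "numeric", pixelSize = "numeric",
                 sampleId = "character"),
  prototype(orientationDeg = 0, pixelSize = 0.09, sampleId = "sample"))

setValidity("RelaxationSeries", function(object) {
  d <- dim(object@images)
  if (length(d) != 3L)
    return("images must be a 3D array (rows x cols x frames)")
  if (d[3] != length(object@protocol@timingAxis))
    return("number of frames must match the protocol timing axis")
  if (any(object@images < 0, na.rm = TRUE))
    return("magnitude images must be non-negative")
  TRUE
})

#' NoiseEstimate: background noise level of a magnitude series
#'
#' @slot sigmaFloor mean background magnitude of the lowest-SNR frame
#'   (signal units, >= 0). For pure Rician noise of Gaussian width sigma this
#'   converges to the Rayleigh mean sigma * sqrt(pi/2).
#' @slot source one of `background_mask`, `corner_patches`, `user_supplied`.
#' @export
setClass("NoiseEstimate",
  representation(sigmaFloor = "numeric", source = "character"))

setValidity("NoiseEstimate", function(object) {
  if (!is.finite(object@sigmaFloor) || object@sigmaFloor < 0)
    return("sigmaFloor must be finite and non-negative")
  if (!object@source %in% c("background_mask", "corner_patches",
                            "user_supplied"))
    return("unknown noise source")
  TRUE
})

#' FitResult: outcome of a single-voxel model fit
#'
#' @slot params fitted [ModelParameters-class].
#' @slot residualSS residual sum of squares (signal units squared).
#' @slot converged logical, solver convergence flag.
#' @slot valid logical; `TRUE` only if converged with parameters strictly
#'   inside the fitting bounds.
#' @export
setClass("FitResult",
  representation(params = "ModelParameters", residualSS = "numeric",
                 converged = "logical", valid = "logical"))

setValidity("FitResult", function(object) {
  if (isTRUE(object@residualSS < 0)) return("residualSS must be >= 0")
  if (object@valid && !object@converged)
    return("a valid fit must have converged")
  TRUE
})

#' ParameterMap: a fitted relaxation-time map
#'
#' Voxel-wise fitted relaxation time and amplitude (plus steady state for
#' RAFF), with a validity mask recording which voxels were in the foreground
#' and fitted successfully.
#'
#' @slot relaxationTime 2D map in seconds (`NA` where invalid).
#' @slot amplitude 2D amplitude map.
#' @slot steadyState 2D steady-state map (RAFF) or a 0 x 0 matrix.
#' @slot validityMask 2D logical.
#' @slot protocol the generating [SequenceProtocol-class].
#' @slot orientationDeg nominal specimen orientation in degrees.
#' @export
setClass("ParameterMap",
  representation(relaxationTime = "matrix", amplitude = "matrix",
                 steadyState = "matrix", validityMask = "matrix",
                 protocol = "SequenceProtocol", orientationDeg = "numeric"),
  prototype(steadyState = matrix(numeric(0), 0, 0)))

setValidity("ParameterMap", function(object) {
  d <- dim(object@relaxationTime)
  if (!identical(dim(object@amplitude), d) ||
      !identical(dim(object@validityMask), d))
    return("relaxationTime, amplitude and validityMask must share dimensions")
  if (!is.logical(object@validityMask))
    return("validityMask must be logical")
  tt <- object@relaxationTime[object@validityMask]
  if (any(!is.finite(tt)) || any(tt <= 0))
    return("relaxationTime must be positive and finite wherever valid")
  TRUE
})

#' RigidTransform2D: in-plane rigid transform
#'
#' Forward mapping of a point p (x, y, in voxel coordinates) is
#' `q = R(theta) (p - center) + center + translation`, with `R` the 2D
#' rotation matrix. Applying the transform to a moving image resamples it
#' onto the fixed grid.
#'
#' @slot rotationDeg rotation angle in degrees, normalized to (-180, 180].
#' @slot translation numeric length 2, (dx, dy) in voxels.
#' @slot center numeric length 2, rotation center (cx, cy) in voxels.
#' @export
setClass("RigidTransform2D",
  representation(rotationDeg = "numeric", translation = "numeric",
                 center = "numeric"))

setValidity("RigidTransform2D", function(object) {
  if (length(object@translation) != 2L || length(object@center) != 2L)
    return("translation and center must have length 2")
  if (!is.finite(object@rotationDeg) ||
      object@rotationDeg <= -180 || object@rotationDeg > 180)
    return("rotationDeg must be normalized to (-180, 180]")
  TRUE
})

#' OrientationStack: co-registered maps of one quantity across orientations
#'
#' @slot maps list of [ParameterMap-class], one per orientation, all
#'   resampled onto the grid of the first (reference) orientation.
#' @slot transforms list of [RigidTransform2D-class], one per orientation
#'   (identity for the reference).
#' @slot orientationsDeg nominal orientations in degrees.
#' @slot jointValidity logical 2D mask: voxels valid in every resampled map
#'   and inside the field of view of every orientation.
#' @export
setClass("OrientationStack",
  representation(maps = "list", transforms = "list",
                 orientationsDeg = "numeric", jointValidity = "matrix"))

setValidity("OrientationStack", function(object) {
  n <- length(object@maps)
  if (n < 2L) return("an OrientationStack needs >= 2 orientations")
  if (length(object@transforms) != n || length(object@orientationsDeg) != n)
    return("maps, transforms and orientationsDeg must have equal length")
  d <- dim(object@maps[[1]]@relaxationTime)
  for (m in object@maps)
    if (!identical(dim(m@relaxationTime), d))
      return("all maps must share the reference grid")
  if (!identical(dim(object@jointValidity), d))
    return("jointValidity must match the map grid")
  TRUE
})

#' AnisotropyMap: voxel-wise Michelson relaxation anisotropy
#'
#' @slot values 2D map of Michelson contrast A in \[0, 1\] (`NA` invalid).
#' @slot validityMask 2D logical.
#' @slot quantity label of the relaxation quantity (e.g. `MESE_T2`).
#' @slot nOrientations number of orientations the contrast was taken over.
#' @export
setClass("AnisotropyMap",
  representation(values = "matrix", validityMask = "matrix",
                 quantity = "character", nOrientations = "numeric"))

setValidity("AnisotropyMap", function(object) {
  if (!identical(dim(object@values), dim(object@validityMask)))
    return("values and validityMask must share dimensions")
  a <- object@values[object@validityMask]
  if (any(!is.finite(a)) || any(a < 0) || any(a > 1))
    return("anisotropy must lie in [0, 1] wherever valid")
  if (object@nOrientations < 2) return("nOrientations must be >= 2")
  TRUE
})

#' TissueModel: dipolar relaxation parameters of one tissue layer
#'
#' Encodes the magic-angle relaxation model driving the phantom generator:
#' transverse-family relaxation rates are
#' `R2(theta) = r2Iso + familyScale[quantity] * r2Aniso * P2(cos theta)^2`
#' with `P2(x) = (3 x^2 - 1) / 2` and theta the fiber-to-B0 angle, so the
#' anisotropic contribution vanishes at the magic angle (54.7 degrees).
#' Under a continuous-wave spin lock of amplitude f (Hz) the anisotropic term
#' is additionally attenuated by a Lorentzian factor
#' `1 / (1 + (2 * omega1 * tauDisp)^2)`, `omega1 = 2 pi f`. T1 (and the
#' adiabatic T1rho family, `familyScale = 0`) are orientation-independent.
#'
#' @slot t1 longitudinal relaxation time, seconds.
#' @slot r2Iso isotropic transverse rate, 1/s.
#' @slot r2Aniso maximal anisotropic transverse rate contribution, 1/s.
#' @slot tauDisp spin-lock dispersion time constant, seconds.
#' @slot familyScale named fractions in \[0, 1\] scaling `r2Aniso` per
#'   quantity (`MESE_T2`, `AD_T2RHO`, `RAFF2`, `RAFF3`, `RAFF4`, `AD_T1RHO`).
#' @slot protonDensity equilibrium signal amplitude (arbitrary units).
#' @slot raffSssFraction RAFF steady-state signal as a fraction of S0.
#' @export
setClass("TissueModel",
  representation(t1 = "numeric", r2Iso = "numeric", r2Aniso = "numeric",
                 tauDisp = "numeric", familyScale = "numeric",
                 protonDensity = "numeric", raffSssFraction = "numeric"))

setValidity("TissueModel", function(object) {
  if (object@t1 <= 0 || object@r2Iso <= 0 || object@r2Aniso < 0 ||
      object@tauDisp < 0 || object@protonDensity < 0)
    return("rates and times must be positive (r2Aniso, protonDensity >= 0)")
  fs <- object@familyScale
  if (is.null(names(fs)) || any(!is.finite(fs)) || any(fs < 0 | fs > 1))
    return("familyScale must be a named vector of fractions in [0, 1]")
  if (object@raffSssFraction < 0 || object@raffSssFraction >= 1)
    return("raffSssFraction must be in [0, 1)")
  TRUE
})

#' PhantomSpec: layered rotating-phantom description
#'
#' Layered 2D geometry (axis-aligned rectangles and discs in the reference
#' frame) with a fiber angle and a [TissueModel-class] per layer, the set of
#' physical orientations to simulate, the Rician noise level, and the global
#' seed. Layers are applied in order; the first matching layer claims a voxel.
#'
#' @slot grid integer (nx, ny) grid size in voxels.
#' @slot layers list; each element a list with `name`, `shape` ("rect" with
#'   `x0,x1,y0,y1` or "disc" with `cx,cy,r`), `fiberDeg`, `tissue`.
#' @slot orientationsDeg physical orientations to simulate, degrees.
#' @slot noiseSigma Gaussian width of the complex noise (signal units).
#' @slot seed integer master seed; per-series sub-seeds are derived from it.
#' @export
setClass("PhantomSpec",
  representation(grid = "numeric", layers = "list",
                 orientationsDeg = "numeric", noiseSigma = "numeric",
                 seed = "numeric"))

setValidity("PhantomSpec", function(object) {
  if (length(object@grid) != 2L || any(object@grid < 8))
    return("grid must be (nx, ny), each >= 8")
  if (length(object@orientationsDeg) < 2L)
    return("at least 2 orientations are required")
  if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
  for (ly in object@layers) {
    if (!all(c("name", "shape", "fiberDeg", "tissue") %in% names(ly)))
      return("each layer needs name, shape, fiberDeg, tissue")
    if (!ly$shape %in% c("rect", "disc"))
      return("layer shape must be 'rect' or 'disc'")
    if (!is(ly$tissue, "TissueModel"))
      return("layer tissue must be a TissueModel")
  }
  TRUE
})

#' PipelineConfig: configuration of the simulate-fit-register-report pipeline
#'
#' @slot outputDir output directory (created on run).
#' @slot sampleId sample identifier used in the directory layout.
#' @slot quantities quantity labels to process (must include `MESE_T2`,
#'   whose first echo drives the registration).
#' @slot phantom the [PhantomSpec-class] to simulate.
#' @slot foregroundK foreground threshold factor: voxels with first-frame
#'   signal > k * sigma_floor are fitted.
#' @slot roiMargin erosion margin (voxels) of the ground-truth ROI labels.
#' @slot rotationGrid coarse rotation search grid for registration, degrees.
#' @slot seed integer master seed for the simulation stage.
#' @export
setClass("PipelineConfig",
  representation(outputDir = "character", sampleId = "character",
                 quantities = "character", phantom = "PhantomSpec",
                 foregroundK = "numeric", roiMargin = "numeric",
                 rotationGrid = "numeric", seed = "numeric"))

setValidity("PipelineConfig", function(object) {
  known <- names(paperProtocols())
  bad <- setdiff(object@quantities, known)
  if (length(bad))
    return(paste0("unknown quantities: ", paste(bad, collapse = ", ")))
  if (!"MESE_T2" %in% object@quantities)
    return("registration uses the first MESE echo: quantities must include MESE_T2")
  if (object@foregroundK < 0) return("foregroundK must be >= 0")
  TRUE
})
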