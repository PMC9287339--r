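#' @include AllClasses.R protocols.R signal-models.R
NULL

## Second Legendre polynomial, the angular factor of the residual dipolar
## interaction; vanishes at the magic angle acos(1/sqrt(3)) = 54.7356 deg.
.p2 <- function(x) (3 * x * x - 1) / 2

#' Construct a TissueModel
#'
#' Defaults describe a cartilage-like tissue at 9.4 T: T1 = 1.4 s, an
#' isotropic transverse rate of 10 1/s and a maximal anisotropic (dipolar)
#' contribution of 30 1/s, spin-lock dispersion time constant 0.3 ms, and
#' per-quantity scales mirroring the observed ordering of transverse-family
#' anisotropies (T2 and adiabatic T2rho fully anisotropic, RAFF2-4
#' progressively less, adiabatic T1rho orientation-independent).
#'
#' @param t1 longitudinal relaxation time, s.
#' @param r2Iso isotropic transverse rate, 1/s.
#' @param r2Aniso anisotropic transverse rate at theta = 0, 1/s.
#' @param tauDisp spin-lock dispersion time constant, s.
#' @param familyScale named fractions scaling `r2Aniso` per quantity.
#' @param protonDensity signal amplitude, arbitrary units.
#' @param raffSssFraction RAFF steady state as a fraction of S0.
#' @return a [TissueModel-class].
#' @export
tissueModel <- function(t1 = 1.4, r2Iso = 10, r2Aniso = 30, tauDisp = 3e-4,
                        familyScale = c(MESE_T2 = 1, AD_T2RHO = 1,
                                        RAFF2 = 0.75, RAFF3 = 0.70,
                                        RAFF4 = 0.50, AD_T1RHO = 0),
                        protonDensity = 100, raffSssFraction = 0.3) {
  new("TissueModel", t1 = t1, r2Iso = r2Iso, r2Aniso = r2Aniso,
      tauDisp = tauDisp, familyScale = familyScale,
      protonDensity = protonDensity, raffSssFraction = raffSssFraction)
}

.rectLayer <- function(name, x0, x1, y0, y1, fiberDeg, tissue)
  list(name = name, shape = "rect", x0 = x0, x1 = x1, y0 = y0, y1 = y1,
       fiberDeg = fiberDeg, tissue = tissue)

.discLayer <- function(name, cx, cy, r, fiberDeg, tissue)
  list(name = name, shape = "disc", cx = cx, cy = cy, r = r,
       fiberDeg = fiberDeg, tissue = tissue)

#' Construct a PhantomSpec
#'
#' @param grid (nx, ny) in voxels.
#' @param layers list of layer descriptions (see [PhantomSpec-class]).
#' @param orientationsDeg physical orientations, degrees.
#' @param noiseSigma Gaussian width of the complex noise.
#' @param seed master seed.
#' @return a [PhantomSpec-class].
#' @export
phantomSpec <- function(grid, layers, orientationsDeg = c(0, 30, 60, 90, 120),
                        noiseSigma = 2, seed = 1) {
  new("PhantomSpec", grid = as.numeric(grid), layers = layers,
      orientationsDeg = as.numeric(orientationsDeg),
      noiseSigma = noiseSigma, seed = as.numeric(seed))
}

#' The default layered cartilage-like phantom
#'
#' A 64 x 64 phantom emulating an osteochondral plug imaged across five
#' physical orientations: depth-wise cartilage zones with the canonical
#' collagen arrangement — superficial (fibers parallel to the surface, 90
#' degrees to the sample axis), transitional (oblique, 45 degrees) and
#' radial (along the sample axis, 0 degrees) — backed by a signal-free bone
#' band, plus an isotropic reference disc (no anisotropic rate; R2 = 20 1/s
#' so its T2 of 50 ms sits mid-range of the MESE echo axis). At the nominal
#' zero orientation the radial-zone fibers are parallel to B0. The default
#' noise level (sigma = 2 against a proton density of 100) corresponds to
#' SNR 50.
#'
#' @param noiseSigma Rician noise level (signal units).
#' @param seed master seed for the noise streams.
#' @param orientationsDeg physical orientations, degrees.
#' @return a [PhantomSpec-class].
#' @examples
#' defaultPhantom()
#' @export
defaultPhantom <- function(noiseSigma = 2, seed = 1,
                           orientationsDeg = c(0, 30, 60, 90, 120)) {
  cart <- tissueModel()
  iso <- tissueModel(r2Iso = 20, r2Aniso = 0)
  bone <- tissueModel(protonDensity = 0)
  phantomSpec(grid = c(64, 64),
              layers = list(
                .rectLayer("superficial", 12, 40, 10, 20, 90, cart),
                .rectLayer("transitional", 12, 40, 21, 31, 45, cart),
                .rectLayer("radial", 12, 40, 32, 45, 0, cart),
                .rectLayer("bone", 12, 40, 46, 52, 0, bone),
                .discLayer("isotropic", 50, 22, 6, 0, iso)),
              orientationsDeg = orientationsDeg,
              noiseSigma = noiseSigma, seed = seed)
}

#' Effective fiber-to-field angle
#'
#' Folds the sum of the physical sample rotation and the layer fiber offset
#' into \[0, 90\] degrees, exploiting the 180-degree symmetry of the dipolar
#' interaction (the angle enters only through `P2(cos theta)^2`).
#'
#' @param sampleRotationDeg physical rotation of the sample, degrees.
#' @param layerFiberDeg fiber angle relative to the sample axis, degrees.
#' @return angle in \[0, 90\] degrees (vectorized).
#' @examples
#' effectiveFiberAngle(120, 0)  # 60
#' @export
effectiveFiberAngle <- function(sampleRotationDeg, layerFiberDeg) {
  a <- (sampleRotationDeg + layerFiberDeg) %% 180
  ifelse(a > 90, 180 - a, a)
}

#' Orientation-dependent transverse relaxation rate
#'
#' The residual-dipolar magic-angle model:
#' `R2(theta) = R2_iso + familyScale[quantity] * R2_aniso * P2(cos theta)^2`
#' with `P2(x) = (3 x^2 - 1)/2`. The anisotropic term vanishes at the magic
#' angle (54.7356 degrees) and is maximal for fibers along B0.
#'
#' @param thetaDeg fiber-to-field angle in \[0, 90\] degrees (vectorized).
#' @param model a [TissueModel-class].
#' @param quantity a name of `model`'s `familyScale` (e.g. `MESE_T2`).
#' @return rate in 1/s.
#' @export
dipolarR2 <- function(thetaDeg, model, quantity) {
  stopifnot(all(thetaDeg >= 0 & thetaDeg <= 90))
  fs <- model@familyScale
  if (!quantity %in% names(fs))
    stop("unknown quantity '", quantity, "'; familyScale defines: ",
         paste(names(fs), collapse = ", "))
  model@r2Iso +
    fs[[quantity]] * model@r2Aniso * .p2(cos(thetaDeg * pi / 180))^2
}

#' Spin-lock-dispersed rotating-frame relaxation rate
#'
#' Continuous-wave T1rho: the anisotropic (dipolar) contribution is
#' attenuated by a single Lorentzian in the spin-lock amplitude,
#' `R(theta, f) = R2_iso + R2_aniso * P2(cos theta)^2 /
#' (1 + (2 * omega1 * tau)^2)` with `omega1 = 2 pi f`; it reduces to
#' [dipolarR2()] (full scale) at zero amplitude and to the isotropic rate as
#' the amplitude grows, reproducing the observed monotone reduction of
#' orientation dependence with spin-lock power.
#'
#' @param thetaDeg fiber-to-field angle in \[0, 90\] degrees.
#' @param spinLockHz spin-lock amplitude in Hz (>= 0).
#' @param model a [TissueModel-class].
#' @return rate in 1/s.
#' @export
dispersedR1rho <- function(thetaDeg, spinLockHz, model) {
  stopifnot(all(thetaDeg >= 0 & thetaDeg <= 90), all(spinLockHz >= 0))
  lor <- 1 / (1 + (4 * pi * spinLockHz * model@tauDisp)^2)
  model@r2Iso + model@r2Aniso * .p2(cos(thetaDeg * pi / 180))^2 * lor
}

## Deterministic per-series sub-seed: a 31-bit polynomial hash of
## sample/quantity/orientation/inversion folded with the master seed, so
## every series draws an independent reproducible noise stream.
.subSeed <- function(seed, sampleId, quantity, orientationDeg,
                     inverted = FALSE) {
  key <- paste(sampleId, quantity, format(orientationDeg, digits = 10),
               if (inverted) "inv" else "std", sep = "/")
  h <- 0
  for (code in utf8ToInt(key)) h <- (h * 31 + code) %% 2147483629
  as.integer((h + round(seed)) %% 2147483629)
}

## Voxel-wise ground-truth fields of the phantom at one orientation:
## layer label, relaxation time, amplitude (and RAFF steady state /
## inverted amplitude). The geometry is rotated analytically (labels are
## evaluated on back-rotated coordinates), so no interpolation enters.
.phantomFields <- function(spec, protocol, orientationDeg) {
  nx <- spec@grid[1]; ny <- spec@grid[2]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  qx <- rep(seq_len(nx), each = ny)
  qy <- rep(seq_len(ny), times = nx)
  th <- -orientationDeg * pi / 180
  sx <- cos(th) * (qx - cx) - sin(th) * (qy - cy) + cx
  sy <- sin(th) * (qx - cx) + cos(th) * (qy - cy) + cy
  label <- integer(nx * ny)
  for (i in seq_along(spec@layers)) {
    ly <- spec@layers[[i]]
    inside <- if (ly$shape == "rect")
      sx >= ly$x0 & sx <= ly$x1 & sy >= ly$y0 & sy <= ly$y1
    else (sx - ly$cx)^2 + (sy - ly$cy)^2 <= ly$r^2
    label[label == 0L & inside] <- i
  }
  qlab <- quantityLabel(protocol)
  kind <- protocol@kind
  tMap <- rep(NA_real_, nx * ny)
  amp <- numeric(nx * ny)
  sss <- rep(NA_real_, nx * ny)
  s0inv <- rep(NA_real_, nx * ny)
  for (i in seq_along(spec@layers)) {
    ly <- spec@layers[[i]]
    ts <- ly$tissue
    sel <- label == i
    if (!any(sel)) next
    theta <- effectiveFiberAngle(orientationDeg, ly$fiberDeg)
    rate <- switch(kind,
      IR_T1 = 1 / ts@t1,
      CW_T1RHO = dispersedR1rho(theta, protocol@spinLockHz, ts),
      dipolarR2(theta, ts, kind))
    tMap[sel] <- 1 / rate
    amp[sel] <- ts@protonDensity
    if (kind %in% .RAFF_KINDS) {
      sss[sel] <- ts@raffSssFraction * ts@protonDensity
      s0inv[sel] <- -0.95 * ts@protonDensity
    }
  }
  list(label = matrix(label, ny, nx), relaxationTime = matrix(tMap, ny, nx),
       amplitude = matrix(amp, ny, nx), steadyState = matrix(sss, ny, nx),
       invertedAmplitude = matrix(s0inv, ny, nx))
}

#' Ground-truth layer labels of the phantom
#'
#' @param spec a [PhantomSpec-class].
#' @param orientationDeg physical orientation (geometry is rotated
#'   analytically about the grid center).
#' @return integer matrix; 0 = background, i = i-th layer. Layer names are
#'   attached as attribute `layers`.
#' @export
phantomLabels <- function(spec, orientationDeg = 0) {
  f <- .phantomFields(spec, paperProtocols()$MESE_T2, orientationDeg)
  structure(f$label, layers = vapply(spec@layers, `[[`, "", "name"))
}

#' Ground-truth relaxation-time map of the phantom
#'
#' The analytic (noise-free) relaxation time per voxel for a given protocol
#' and orientation — the reference the fitted maps are compared against.
#'
#' @inheritParams phantomLabels
#' @param protocol a [SequenceProtocol-class].
#' @return numeric matrix in seconds (`NA` in signal-free regions).
#' @export
phantomTruth <- function(spec, protocol, orientationDeg = 0) {
  f <- .phantomFields(spec, protocol, orientationDeg)
  tt <- f$relaxationTime
  tt[f$amplitude <= 0] <- NA_real_
  tt
}

#' Interior ROI labels for the phantom
#'
#' The analog of manually drawn ROIs: each signal-bearing layer shrunk by a
#' margin so that ROI voxels sit clear of layer boundaries (where partial
#' voluming from registration resampling mixes tissues), on the reference
#' (unrotated) grid. Signal-free layers get no ROI.
#'
#' @param spec a [PhantomSpec-class].
#' @param margin erosion margin in voxels.
#' @return integer label matrix with attribute `layers` naming the labels.
#' @export
phantomRoiMask <- function(spec, margin = 2) {
  shrunk <- spec
  keep <- logical(length(spec@layers))
  shrunk@layers <- lapply(seq_along(spec@layers), function(i) {
    ly <- spec@layers[[i]]
    keep[i] <<- ly$tissue@protonDensity > 0
    if (ly$shape == "rect") {
      ly$x0 <- ly$x0 + margin; ly$x1 <- ly$x1 - margin
      ly$y0 <- ly$y0 + margin; ly$y1 <- ly$y1 - margin
    } else ly$r <- max(ly$r - margin, 0)
    ly
  })
  lab <- phantomLabels(shrunk, 0)
  lab[!keep[pmax(lab, 1)]] <- 0L
  structure(lab, layers = vapply(spec@layers, `[[`, "", "name"))
}

#' Simulate one relaxometry series of the rotating phantom
#'
#' Evaluates the forward signal model of the protocol voxel by voxel, with
#' relaxation rates from the dipolar magic-angle model ([dipolarR2()] /
#' [dispersedR1rho()]; T1 and the adiabatic-T1rho family are
#' orientation-independent), the geometry rotated by the physical
#' orientation about the grid center, and Rician magnitude noise
#' `M = sqrt((S + n1)^2 + n2^2)` with `n1, n2 ~ N(0, noiseSigma^2)`. The
#' noise stream is reproducible: the seed of each series is derived
#' deterministically from the master seed and the series identity.
#'
#' @param spec a [PhantomSpec-class].
#' @param protocol a [SequenceProtocol-class] (RAFF protocols with
#'   `inversionPrepared = TRUE` simulate the inverted curve).
#' @param orientationDeg physical orientation in degrees.
#' @param sampleId sample identifier stamped on the series.
#' @param seed master seed override; defaults to the spec's seed.
#' @return a [RelaxationSeries-class].
#' @export
simulateSeries <- function(spec, protocol, orientationDeg,
                           sampleId = "phantom", seed = NULL) {
  stopifnot(is(spec, "PhantomSpec"), is(protocol, "SequenceProtocol"))
  f <- .phantomFields(spec, protocol, orientationDeg)
  kind <- protocol@kind
  tvec <- protocol@timingAxis
  ny <- nrow(f$label); nx <- ncol(f$label)
  clean <- array(0, dim = c(ny, nx, length(tvec)))
  sig <- f$amplitude > 0
  for (j in seq_along(tvec)) {
    fr <- matrix(0, ny, nx)
    if (kind == "IR_T1") {
      fr[sig] <- irMagnitude(tvec[j], f$amplitude[sig],
                             f$relaxationTime[sig])
    } else if (kind %in% .RAFF_KINDS) {
      fr[sig] <- raffSignal(tvec[j],
                            f$amplitude[sig], f$relaxationTime[sig],
                            f$steadyState[sig], f$invertedAmplitude[sig],
                            inverted = protocol@inversionPrepared)
    } else {
      fr[sig] <- monoexpDecay(tvec[j], f$amplitude[sig],
                              f$relaxationTime[sig])
    }
    clean[, , j] <- fr
  }
  if (spec@noiseSigma > 0) {
    if (is.null(seed)) seed <- spec@seed
    set.seed(.subSeed(seed, sampleId, quantityLabel(protocol),
                      orientationDeg, protocol@inversionPrepared))
    n <- length(clean)
    img <- sqrt((clean + stats::rnorm(n, 0, spec@noiseSigma))^2 +
                stats::rnorm(n, 0, spec@noiseSigma)^2)
    dim(img) <- dim(clean)
  } else {
    img <- abs(clean)
  }
  new("RelaxationSeries", images = img, protocol = protocol,
      orientationDeg = orientationDeg, pixelSize = 0.09,
      sampleId = sampleId)
}

#' Closed-form anisotropy of the generator model
#'
#' The analytic oracle for end-to-end tests: the Michelson contrast of
#' `T(theta_eff) = 1 / rate(theta_eff)` over the sampled orientations, with
#' the rate from [dipolarR2()] (or [dispersedR1rho()] for `CW_T1RHO`, or
#' `1/T1` for `IR_T1`).
#'
#' @param model a [TissueModel-class].
#' @param layerFiberDeg fiber angle of the layer relative to the sample
#'   axis, degrees.
#' @param orientationsDeg sampled physical orientations, degrees.
#' @param quantity quantity label (`familyScale` name, `CW_T1RHO`, or
#'   `IR_T1`).
#' @param spinLockHz spin-lock amplitude (required for `CW_T1RHO`).
#' @return anisotropy fraction in \[0, 1\].
#' @examples
#' analyticAnisotropy(tissueModel(), 0, c(0, 30, 60, 90, 120), "MESE_T2")
#' @export
analyticAnisotropy <- function(model, layerFiberDeg, orientationsDeg,
                               quantity, spinLockHz = NA_real_) {
  theta <- effectiveFiberAngle(orientationsDeg, layerFiberDeg)
  rate <- if (quantity == "IR_T1") rep(1 / model@t1, length(theta))
    else if (quantity == "CW_T1RHO") {
      stopifnot(is.finite(spinLockHz))
      dispersedR1rho(theta, spinLockHz, model)
    } else dipolarR2(theta, model, quantity)
  as.numeric(michelson(1 / rate))
}
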