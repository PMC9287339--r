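#' @include AllClasses.R signal-models.R protocols.R
NULL

#' Estimate the magnitude noise floor of a series
#'
#' The noise floor is the mean background magnitude of the last (lowest-SNR)
#' frame. With no background mask supplied, the four 8 x 8 image corners are
#' used, assuming the specimen sits centrally in the field of view. For pure
#' complex Gaussian noise of width sigma the magnitude background is
#' Rayleigh-distributed and the estimate converges to sigma * sqrt(pi / 2).
#'
#' @param series a [RelaxationSeries-class].
#' @param backgroundMask optional logical matrix selecting at least 50
#'   background voxels.
#' @return a [NoiseEstimate-class].
#' @export
estimateNoiseFloor <- function(series, backgroundMask = NULL) {
  stopifnot(is(series, "RelaxationSeries"))
  img <- series@images
  last <- img[, , dim(img)[3]]
  if (!is.null(backgroundMask)) {
    stopifnot(identical(dim(backgroundMask), dim(last)))
    n <- sum(backgroundMask)
    if (n < 50L)
      stop("background mask selects only ", n, " voxels; >= 50 required")
    vals <- last[backgroundMask]
    src <- "background_mask"
  } else {
    k <- pmin(8L, dim(last) %/% 2L)
    nr <- nrow(last); nc <- ncol(last)
    ri <- c(seq_len(k[1]), seq.int(nr - k[1] + 1L, nr))
    ci <- c(seq_len(k[2]), seq.int(nc - k[2] + 1L, nc))
    vals <- last[ri, ci]
    src <- "corner_patches"
  }
  new("NoiseEstimate", sigmaFloor = mean(vals), source = src)
}

#' Quadrature noise-floor subtraction
#'
#' Corrects magnitude data for the Rician noise floor before fitting:
#' `S_corr = sqrt(max(S^2 - sigma_floor^2, 0))`. Subtraction in quadrature is
#' the first-order bias correction for magnitude data, since for a Rician
#' magnitude `E[S^2] = S_true^2 + 2 sigma^2`; the result is clamped at zero.
#'
#' @param signal non-negative magnitudes (any shape).
#' @param noise a [NoiseEstimate-class], or a bare numeric noise-floor value.
#' @return corrected magnitudes, same shape as `signal`.
#' @examples
#' subtractNoiseFloor(5, 3)  # 3-4-5: returns 4
#' @export
subtractNoiseFloor <- function(signal, noise) {
  sigma <- if (is(noise, "NoiseEstimate")) noise@sigmaFloor else noise
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma >= 0)
  if (any(signal < 0, na.rm = TRUE))
    stop("subtractNoiseFloor expects non-negative magnitudes")
  out <- sqrt(pmax(signal * signal - sigma * sigma, 0))
  if (!is.null(dim(signal))) dim(out) <- dim(signal)
  out
}

## Solver control shared by all voxel fits: tight cost tolerance so that
## noiseless data refit to the generating parameters to ~1e-8 relative.
.fitControl <- function()
  minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-13, gtol = 0,
                             maxiter = 200)

## Initial relaxation time from the first/last sample ratio, clamped.
.initialT <- function(t, y, offset = 0) {
  n <- length(y)
  span <- t[n] - t[1]
  a <- y[1] - offset; b <- y[n] - offset
  t0 <- if (a > 0 && b > 0 && a > b) span / log(a / b) else span / 3
  min(max(t0, 1e-3), 10)
}

.lmFit <- function(par, lower, upper, resFun) {
  fit <- tryCatch(
    minpack.lm::nls.lm(par = par, lower = lower, upper = upper, fn = resFun,
                       control = .fitControl()),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(par = par * NA_real_, rss = NA_real_, converged = FALSE))
  ## info 1-3: ftol/ptol convergence; info 4 with gtol = 0 only occurs for
  ## an exactly-zero residual (perfect fit), so it counts as converged too.
  list(par = fit$par, rss = fit$deviance, converged = fit$info %in% 1:4)
}

## Core per-voxel fit; returns a plain list (S4 wrapping happens in
## fitVoxel) so that map-level loops stay cheap.
.fitVoxelCore <- function(t, y, kind, tInv = NULL, yInv = NULL) {
  bad <- list(amplitude = NA_real_, relaxationTime = NA_real_,
              steadyState = NA_real_, invertedAmplitude = NA_real_,
              rss = NA_real_, converged = FALSE, valid = FALSE)
  if (any(!is.finite(y)) || max(y) <= 0) return(bad)
  tLo <- 1e-4; tHi <- 20
  if (kind %in% .RAFF_KINDS) {
    if (any(!is.finite(yInv))) return(bad)
    m <- max(y, yInv)
    sss0 <- mean(c(y[length(y)], yInv[length(yInv)]))
    par <- c(s0 = max(y), s0inv = -yInv[1], sss = sss0,
             T = .initialT(t, y, offset = sss0))
    res <- function(p)
      c(y - abs(p[3] + (p[1] - p[3]) * exp(-t / p[4])),
        yInv - abs(p[3] + (p[2] - p[3]) * exp(-tInv / p[4])))
    fit <- .lmFit(par, lower = c(0, -10 * m, 0, tLo),
                  upper = c(10 * m, 10 * m, 10 * m, tHi), res)
  } else if (kind == "IR_T1") {
    s0 <- max(y)
    t1 <- min(max(t[which.min(y)] / log(2), 1e-3), 10)
    res <- function(p) y - abs(p[1] * (1 - 2 * exp(-t / p[2])))
    fit <- .lmFit(c(s0 = s0, T = t1), lower = c(0, tLo),
                  upper = c(10 * s0, tHi), res)
  } else {
    s0 <- max(y)
    res <- function(p) y - p[1] * exp(-t / p[2])
    fit <- .lmFit(c(s0 = s0, T = .initialT(t, y)), lower = c(0, tLo),
                  upper = c(10 * s0, tHi), res)
  }
  p <- fit$par
  tc <- unname(p[length(p)])
  valid <- fit$converged && is.finite(fit$rss) &&
    is.finite(tc) && tc > tLo * 1.001 && tc < tHi * 0.999
  list(amplitude = unname(p[1]), relaxationTime = tc,
       steadyState = if (kind %in% .RAFF_KINDS) unname(p[3]) else NA_real_,
       invertedAmplitude = if (kind %in% .RAFF_KINDS) unname(p[2])
                           else NA_real_,
       rss = fit$rss, converged = fit$converged, valid = valid)
}

#' Fit the relaxation model to a single voxel
#'
#' Least-squares estimation (Levenberg-Marquardt with box bounds) of the
#' signal model matching the sequence kind: the square sum between model and
#' data is minimized. Two parameters (S0, T) for the monoexponential and
#' magnitude-IR kinds; RAFF is a joint four-parameter fit (S0, S0inv, Sss, T)
#' over the non-inverted and inverted curves, which share T and Sss.
#' Initialization: S0 from the maximum sample, T from the first/last sample
#' log-ratio clamped to \[1 ms, 10 s\]; bounds T in \[0.1 ms, 20 s\],
#' amplitudes within 10x the maximum sample. A degenerate voxel (all-zero or
#' non-finite signal, or a fit pinned at the bounds) yields `valid = FALSE`
#' and never an error.
#'
#' @param t sample times in seconds (>= 3 samples).
#' @param y noise-floor-corrected magnitudes at `t`.
#' @param kind sequence kind (see [SequenceProtocol-class]).
#' @param tInv,yInv times and magnitudes of the inversion-prepared companion
#'   curve (RAFF kinds; >= 5 samples combined).
#' @return a [FitResult-class].
#' @export
fitVoxel <- function(t, y, kind, tInv = NULL, yInv = NULL) {
  stopifnot(kind %in% .SEQ_KINDS, length(t) == length(y))
  if (kind %in% .RAFF_KINDS) {
    if (is.null(tInv) || is.null(yInv) || length(tInv) != length(yInv))
      stop("RAFF fits require the inversion-prepared companion curve")
    if (length(t) + length(tInv) < 5L)
      stop("RAFF joint fit requires >= 5 samples in total")
  } else if (length(t) < 3L) {
    stop("2-parameter fits require >= 3 samples")
  }
  r <- .fitVoxelCore(t, y, kind, tInv, yInv)
  new("FitResult",
      params = new("ModelParameters", amplitude = r$amplitude,
                   relaxationTime = r$relaxationTime,
                   steadyState = r$steadyState,
                   invertedAmplitude = r$invertedAmplitude),
      residualSS = if (is.finite(r$rss)) r$rss else 0,
      converged = r$converged, valid = r$valid)
}

#' Fit a voxel-wise relaxation-time map
#'
#' Applies [fitVoxel()] over the foreground of a series after quadrature
#' noise-floor subtraction. The foreground is defined on the first frame as
#' `signal > foregroundK * sigma_floor` (default k = 3); background voxels
#' are excluded from all downstream maps. RAFF kinds require the
#' inversion-prepared companion series on an identical grid.
#'
#' @param series a [RelaxationSeries-class].
#' @param noise a [NoiseEstimate-class]; estimated with
#'   [estimateNoiseFloor()] when omitted.
#' @param companion the inversion-prepared companion
#'   [RelaxationSeries-class] (RAFF kinds only).
#' @param foregroundK foreground threshold factor.
#' @return a [ParameterMap-class].
#' @export
fitMap <- function(series, noise = NULL, companion = NULL, foregroundK = 3) {
  stopifnot(is(series, "RelaxationSeries"))
  kind <- series@protocol@kind
  if (kind %in% .RAFF_KINDS) {
    if (is.null(companion))
      stop("RAFF kinds require the inversion-prepared companion series")
    stopifnot(is(companion, "RelaxationSeries"))
    if (!identical(dim(companion@images)[1:2], dim(series@images)[1:2]))
      stop("companion series geometry does not match: ",
           paste(dim(series@images)[1:2], collapse = "x"), " vs ",
           paste(dim(companion@images)[1:2], collapse = "x"))
    if (!companion@protocol@inversionPrepared)
      stop("companion series must be inversion-prepared")
  }
  if (is.null(noise)) noise <- estimateNoiseFloor(series)
  sigma <- sigmaFloor(noise)
  img <- subtractNoiseFloor(series@images, sigma)
  t <- series@protocol@timingAxis
  d <- dim(img)
  fg <- series@images[, , 1] > foregroundK * sigma
  tInv <- NULL; imgInv <- NULL
  if (kind %in% .RAFF_KINDS) {
    imgInv <- subtractNoiseFloor(companion@images, sigma)
    tInv <- companion@protocol@timingAxis
  }
  tcMap <- matrix(NA_real_, d[1], d[2])
  ampMap <- matrix(NA_real_, d[1], d[2])
  sssMap <- matrix(NA_real_, d[1], d[2])
  valid <- matrix(FALSE, d[1], d[2])
  nvox <- d[1] * d[2]
  ymat <- matrix(img, nvox, d[3])
  yinvmat <- if (!is.null(imgInv)) matrix(imgInv, nvox, dim(imgInv)[3])
  for (i in which(fg)) {
    r <- .fitVoxelCore(t, ymat[i, ], kind, tInv,
                       if (!is.null(yinvmat)) yinvmat[i, ])
    if (r$valid) {
      tcMap[i] <- r$relaxationTime
      ampMap[i] <- r$amplitude
      sssMap[i] <- r$steadyState
      valid[i] <- TRUE
    }
  }
  new("ParameterMap", relaxationTime = tcMap, amplitude = ampMap,
      steadyState = if (kind %in% .RAFF_KINDS) sssMap
                    else matrix(numeric(0), 0, 0),
      validityMask = valid, protocol = series@protocol,
      orientationDeg = series@orientationDeg)
}
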