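#' @include AllClasses.R
NULL

#' Construct an in-plane rigid transform
#'
#' @param rotationDeg rotation in degrees (normalized to (-180, 180]).
#' @param dx,dy translation in voxels.
#' @param center rotation center (cx, cy) in voxel coordinates; defaults to
#'   the image center when applied via [resampleImage()]/[resampleMap()]
#'   must be given explicitly here.
#' @return a [RigidTransform2D-class].
#' @export
rigidTransform2D <- function(rotationDeg, dx = 0, dy = 0, center) {
  rot <- ((rotationDeg + 180) %% 360) - 180
  if (rot == -180) rot <- 180
  new("RigidTransform2D", rotationDeg = rot,
      translation = c(dx, dy), center = as.numeric(center))
}

.gridCenter <- function(img) c((ncol(img) + 1) / 2, (nrow(img) + 1) / 2)

#' Apply a rigid transform to points
#'
#' Forward mapping `q = R(theta) (p - center) + center + translation`;
#' points are (x, y) rows.
#'
#' @param transform a [RigidTransform2D-class].
#' @param points numeric matrix with columns x, y (or a length-2 vector).
#' @return transformed points, same shape.
#' @export
applyTransform <- function(transform, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  th <- transform@rotationDeg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  ctr <- matrix(transform@center, nrow(points), 2, byrow = TRUE)
  tr <- matrix(transform@translation, nrow(points), 2, byrow = TRUE)
  (points - ctr) %*% t(R) + ctr + tr
}

#' Invert a rigid transform
#'
#' @param transform a [RigidTransform2D-class].
#' @return the inverse transform (same center); composing the two is the
#'   identity to numerical precision.
#' @export
invertTransform <- function(transform) {
  th <- -transform@rotationDeg * pi / 180
  tx <- transform@translation
  rigidTransform2D(-transform@rotationDeg,
                   dx = -(cos(th) * tx[1] - sin(th) * tx[2]),
                   dy = -(sin(th) * tx[1] + cos(th) * tx[2]),
                   center = transform@center)
}

## Bilinear interpolation at fractional coordinates (sx, sy); NA outside the
## field. Zero-weight neighbors are skipped so that exact-integer sampling
## (e.g. the identity transform) reproduces values -- and NAs -- bitwise.
.bilinear <- function(img, sx, sy) {
  nr <- nrow(img); nc <- ncol(img)
  inside <- sx >= 1 & sx <= nc & sy >= 1 & sy <= nr
  x0 <- pmin(pmax(floor(sx), 1), nc - 1)
  y0 <- pmin(pmax(floor(sy), 1), nr - 1)
  fx <- sx - x0; fy <- sy - y0
  i00 <- y0 + (x0 - 1) * nr
  w <- function(wt, idx) ifelse(wt > 0, wt * img[idx], 0)
  v <- w((1 - fx) * (1 - fy), i00) + w(fx * (1 - fy), i00 + nr) +
       w((1 - fx) * fy, i00 + 1) + w(fx * fy, i00 + nr + 1)
  v[!inside] <- NA_real_
  v
}

.nearest <- function(img, sx, sy) {
  nr <- nrow(img); nc <- ncol(img)
  xi <- round(sx); yi <- round(sy)
  inside <- xi >= 1 & xi <= nc & yi >= 1 & yi <= nr
  v <- rep(NA_real_, length(sx))
  v[inside] <- img[yi[inside] + (xi[inside] - 1) * nr]
  v
}

#' Resample an image through a rigid transform
#'
#' Pulls the moving image onto the fixed grid: output voxel q takes the value
#' of the moving image at `R(-theta) (q - center - translation) + center`.
#' Voxels mapped from outside the field are `NA`.
#'
#' @param img numeric matrix.
#' @param transform a [RigidTransform2D-class].
#' @param interpolation `"bilinear"` (values) or `"nearest"` (labels/masks).
#' @return numeric matrix, same dimensions as `img`.
#' @export
resampleImage <- function(img, transform,
                          interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  nr <- nrow(img); nc <- ncol(img)
  qx <- rep(seq_len(nc), each = nr)
  qy <- rep(seq_len(nr), times = nc)
  th <- -transform@rotationDeg * pi / 180
  cx <- transform@center[1]; cy <- transform@center[2]
  ux <- qx - cx - transform@translation[1]
  uy <- qy - cy - transform@translation[2]
  sx <- cos(th) * ux - sin(th) * uy + cx
  sy <- sin(th) * ux + cos(th) * uy + cy
  v <- if (interpolation == "bilinear") .bilinear(img, sx, sy)
       else .nearest(img, sx, sy)
  matrix(v, nr, nc)
}

#' Rotate an image about its center
#'
#' Convenience wrapper around [resampleImage()] with a pure rotation.
#'
#' @param img numeric matrix.
#' @param degrees rotation angle.
#' @param interpolation see [resampleImage()].
#' @return rotated matrix (`NA` outside the field).
#' @export
rotateImage <- function(img, degrees, interpolation = "bilinear") {
  resampleImage(img, rigidTransform2D(degrees, center = .gridCenter(img)),
                interpolation = interpolation)
}

.ncc <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 32) return(-Inf)
  av <- a[ok]; bv <- b[ok]
  if (stats::sd(av) == 0 || stats::sd(bv) == 0) return(-Inf)
  stats::cor(av, bv)
}

## Integer translation aligning `moving` to `fixed` by phase correlation
## (peak of the inverse FFT of the normalized cross-power spectrum).
.phaseShift <- function(fixed, moving) {
  f <- fixed; f[!is.finite(f)] <- 0
  m <- moving; m[!is.finite(m)] <- 0
  R <- stats::fft(f) * Conj(stats::fft(m))
  R <- R / (Mod(R) + 1e-12)
  r <- Re(stats::fft(R, inverse = TRUE))
  pk <- which(r == max(r), arr.ind = TRUE)[1, ] - 1L
  d <- ifelse(pk > dim(fixed) / 2, pk - dim(fixed), pk)
  c(dx = unname(d[2]), dy = unname(d[1]))
}

#' Estimate the rigid transform aligning two images
#'
#' Finds the in-plane rigid transform maximizing the normalized
#' cross-correlation between the transformed moving image and the fixed
#' image. Search strategy: a coarse rotation grid (default -150 to +150
#' degrees in 5-degree steps) with the translation at each rotation resolved
#' by phase correlation, followed by a local continuous Nelder-Mead
#' refinement of (rotation, dx, dy).
#'
#' @param moving,fixed numeric matrices of equal dimensions, both with
#'   non-constant foreground.
#' @param rotationGrid candidate rotations in degrees.
#' @param refine logical; run the continuous refinement (default `TRUE`).
#' @return a [RigidTransform2D-class] such that
#'   `resampleImage(moving, transform)` aligns with `fixed`.
#' @export
estimateRigid <- function(moving, fixed,
                          rotationGrid = seq(-150, 150, by = 5),
                          refine = TRUE) {
  stopifnot(identical(dim(moving), dim(fixed)))
  if (stats::sd(as.vector(fixed)) == 0 || stats::sd(as.vector(moving)) == 0)
    stop("estimateRigid: flat (zero-variance) image")
  ctr <- .gridCenter(fixed)
  best <- NULL; bestScore <- -Inf
  for (th in rotationGrid) {
    mrot <- resampleImage(moving, rigidTransform2D(th, center = ctr))
    d <- .phaseShift(fixed, mrot)
    cand <- rigidTransform2D(th, d[1], d[2], ctr)
    s <- .ncc(resampleImage(moving, cand), fixed)
    if (s > bestScore) { bestScore <- s; best <- cand }
  }
  if (refine) {
    obj <- function(p)
      -.ncc(resampleImage(moving,
                          rigidTransform2D(p[1], p[2], p[3], ctr)), fixed)
    o <- stats::optim(c(best@rotationDeg, best@translation), obj,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-10, maxit = 500))
    if (is.finite(o$value) && -o$value >= bestScore)
      best <- rigidTransform2D(o$par[1], o$par[2], o$par[3], ctr)
  }
  best
}

#' Resample a parameter map through a rigid transform
#'
#' Relaxation-time, amplitude and steady-state maps are interpolated
#' bilinearly; the validity mask is resampled nearest-neighbor. Voxels
#' mapped from outside the field, or whose interpolation support includes an
#' invalid voxel, are marked invalid; the valid fraction can therefore only
#' shrink.
#'
#' @param map a [ParameterMap-class].
#' @param transform a [RigidTransform2D-class].
#' @return the resampled [ParameterMap-class].
#' @export
resampleMap <- function(map, transform) {
  stopifnot(is(map, "ParameterMap"), is(transform, "RigidTransform2D"))
  tt <- resampleImage(map@relaxationTime, transform)
  amp <- resampleImage(map@amplitude, transform)
  mk <- resampleImage(map@validityMask * 1, transform, "nearest")
  valid <- !is.na(mk) & mk > 0.5 & is.finite(tt) & tt > 0
  tt[!valid] <- NA_real_
  amp[!valid] <- NA_real_
  sss <- map@steadyState
  if (length(sss)) {
    sss <- resampleImage(sss, transform)
    sss[!valid] <- NA_real_
  }
  new("ParameterMap", relaxationTime = tt, amplitude = amp,
      steadyState = sss, validityMask = valid, protocol = map@protocol,
      orientationDeg = map@orientationDeg)
}

#' Co-register parameter maps across orientations
#'
#' The rigid transform of each orientation is estimated once from the first
#' echo of its multi-echo spin-echo (MESE T2) series against the first
#' orientation, then applied to every parameter map of that orientation, so
#' all quantities stay mutually consistent. The joint validity mask is the
#' AND of the resampled validity masks (out-of-field voxels excluded).
#'
#' @param series list of MESE [RelaxationSeries-class], one per orientation
#'   (the first is the reference).
#' @param maps per-orientation maps: a list (one element per orientation) of
#'   either a single [ParameterMap-class] or a named list of them (one per
#'   quantity).
#' @param rotationGrid,refine passed to [estimateRigid()].
#' @return an [OrientationStack-class] if a single map per orientation was
#'   given, otherwise a named list of stacks (one per quantity) sharing the
#'   same transforms.
#' @export
buildOrientationStack <- function(series, maps,
                                  rotationGrid = seq(-150, 150, by = 5),
                                  refine = TRUE) {
  n <- length(series)
  stopifnot(n >= 2L, length(maps) == n)
  for (i in seq_len(n)) {
    s <- series[[i]]
    if (is.null(s) || !is(s, "RelaxationSeries") ||
        s@protocol@kind != "MESE_T2")
      stop("missing MESE_T2 series for orientation index ", i,
           " (registration uses the first MESE echo)")
  }
  single <- is(maps[[1]], "ParameterMap")
  mapsL <- if (single) lapply(maps, function(m) list(map = m)) else maps
  qn <- names(mapsL[[1]])
  if (is.null(qn))
    qn <- vapply(mapsL[[1]], function(m) quantityLabel(m@protocol), "")
  ref <- series[[1]]@images[, , 1]
  ctr <- .gridCenter(ref)
  tfs <- vector("list", n)
  tfs[[1]] <- rigidTransform2D(0, center = ctr)
  for (i in seq.int(2L, n))
    tfs[[i]] <- estimateRigid(series[[i]]@images[, , 1], ref,
                              rotationGrid = rotationGrid, refine = refine)
  orients <- vapply(series, orientationDeg, 0)
  stacks <- lapply(seq_along(qn), function(j) {
    rm <- lapply(seq_len(n), function(i) resampleMap(mapsL[[i]][[j]],
                                                     tfs[[i]]))
    jv <- Reduce(`&`, lapply(rm, validityMask))
    new("OrientationStack", maps = rm, transforms = tfs,
        orientationsDeg = orients, jointValidity = jv)
  })
  names(stacks) <- qn
  if (single) stacks[[1]] else stacks
}
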