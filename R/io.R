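#' @include AllClasses.R protocols.R
NULL

.seriesDir <- function(root, sampleId, qlab, orientationDeg)
  file.path(root, sampleId, qlab, sprintf("orient_%g", orientationDeg))

#' Write a relaxation series as NIfTI + JSON sidecar
#'
#' Layout: `<root>/<sample>/<quantity>/orient_<deg>/series[_inv].nii` with a
#' matching `.json` sidecar carrying the protocol (`kind`, `tr_s`,
#' `times_s`, `spin_lock_hz`, `tau_p_s`, `pulse_counts`,
#' `inversion_prepared`), `orientation_deg`, `sample_id` and
#' `pixel_size_mm`. Images use R's column-major voxel convention (rows = y,
#' columns = x), as noted in the sidecar.
#'
#' @param series a [RelaxationSeries-class].
#' @param root output root directory (created as needed).
#' @return invisibly, the NIfTI path.
#' @export
writeSeries <- function(series, root) {
  stopifnot(is(series, "RelaxationSeries"))
  p <- series@protocol
  dir <- .seriesDir(root, series@sampleId, quantityLabel(p),
                    series@orientationDeg)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base <- if (p@inversionPrepared) "series_inv" else "series"
  nii <- file.path(dir, paste0(base, ".nii"))
  img <- RNifti::asNifti(series@images)
  RNifti::pixdim(img) <- c(series@pixelSize, series@pixelSize, 1)
  RNifti::writeNifti(img, nii)
  side <- protocolToSidecar(p)
  side$orientation_deg <- series@orientationDeg
  side$sample_id <- series@sampleId
  side$pixel_size_mm <- series@pixelSize
  side$voxel_order <- "column-major (rows = y, cols = x), 1-based in R"
  jsonlite::write_json(side, file.path(dir, paste0(base, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(nii)
}

.requireField <- function(fields, name, file) {
  if (is.null(fields[[name]]))
    stop("sidecar ", file, " is missing required field '", name, "'")
  fields[[name]]
}

#' Read relaxation series from a directory tree
#'
#' Scans for `.json` sidecars (recursively), validates them, and loads the
#' matching NIfTI volumes. A sidecar whose `times_s` length differs from the
#' frame count, or with missing required fields, raises an error naming the
#' file and field.
#'
#' @param root directory holding NIfTI volumes + JSON sidecars (the layout
#'   produced by [writeSeries()], but any tree of sidecar/volume pairs
#'   works).
#' @return named list of [RelaxationSeries-class]; names are
#'   `sample/quantity/orientation[/inv]`. Empty directory: empty list with
#'   a warning.
#' @export
readSeries <- function(root) {
  sidecars <- list.files(root, pattern = "\\.json$", recursive = TRUE,
                         full.names = TRUE)
  sidecars <- sidecars[!grepl("(_map|_aniso|_transform)\\.json$", sidecars)]
  if (!length(sidecars)) {
    warning("no series sidecars found under ", root)
    return(list())
  }
  out <- list()
  for (sc in sidecars) {
    fields <- jsonlite::read_json(sc, simplifyVector = TRUE)
    for (req in c("kind", "tr_s", "times_s", "orientation_deg"))
      .requireField(fields, req, sc)
    proto <- protocolFromSidecar(fields)
    nii <- sub("\\.json$", ".nii", sc)
    if (!file.exists(nii)) nii <- paste0(nii, ".gz")
    if (!file.exists(nii))
      stop("no NIfTI volume found next to sidecar ", sc)
    vol <- RNifti::readNifti(nii)
    img <- array(as.vector(vol), dim = dim(vol))
    if (length(dim(img)) == 2L) dim(img) <- c(dim(img), 1L)
    if (dim(img)[3] != length(proto@timingAxis))
      stop("sidecar ", sc, ": times_s has ", length(proto@timingAxis),
           " entries but the volume has ", dim(img)[3], " frames")
    sid <- if (is.null(fields$sample_id)) "sample" else fields$sample_id
    px <- if (is.null(fields$pixel_size_mm)) 0.09 else fields$pixel_size_mm
    series <- new("RelaxationSeries", images = img, protocol = proto,
                  orientationDeg = fields$orientation_deg,
                  pixelSize = px, sampleId = sid)
    key <- paste0(sid, "/", quantityLabel(proto), "/",
                  format(fields$orientation_deg),
                  if (proto@inversionPrepared) "/inv" else "")
    out[[key]] <- series
  }
  out[order(names(out))]
}

#' Write a fitted parameter map
#'
#' Relaxation time as float32 NIfTI (seconds), validity mask as uint8
#' NIfTI, amplitude (and steady state where present) as float32, plus a
#' JSON sidecar with the quantity, orientation, protocol and fit
#' configuration.
#'
#' @param map a [ParameterMap-class].
#' @param prefix output path prefix (directories created as needed).
#' @param fitConfig optional named list recorded in the sidecar.
#' @return invisibly, the relaxation-time NIfTI path.
#' @export
writeParameterMap <- function(map, prefix, fitConfig = list()) {
  stopifnot(is(map, "ParameterMap"))
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  RNifti::writeNifti(map@relaxationTime, paste0(prefix, ".nii"),
                     datatype = "float")
  RNifti::writeNifti(map@amplitude, paste0(prefix, "_amplitude.nii"),
                     datatype = "float")
  if (length(map@steadyState))
    RNifti::writeNifti(map@steadyState, paste0(prefix, "_sss.nii"),
                       datatype = "float")
  RNifti::writeNifti(map@validityMask * 1L, paste0(prefix, "_validity.nii"),
                     datatype = "uint8")
  side <- list(quantity = quantityLabel(map@protocol),
               orientation_deg = map@orientationDeg,
               protocol = protocolToSidecar(map@protocol),
               fit_config = fitConfig)
  jsonlite::write_json(side, paste0(prefix, "_map.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(paste0(prefix, ".nii"))
}

#' Write an anisotropy map
#'
#' Float32 NIfTI of A in \[0, 1\] plus uint8 validity mask and a JSON
#' sidecar with the quantity and orientation count.
#'
#' @param aniso an [AnisotropyMap-class].
#' @param prefix output path prefix.
#' @return invisibly, the NIfTI path.
#' @export
writeAnisotropyMap <- function(aniso, prefix) {
  stopifnot(is(aniso, "AnisotropyMap"))
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  RNifti::writeNifti(aniso@values, paste0(prefix, ".nii"),
                     datatype = "float")
  RNifti::writeNifti(aniso@validityMask * 1L,
                     paste0(prefix, "_validity.nii"), datatype = "uint8")
  jsonlite::write_json(list(quantity = aniso@quantity,
                            n_orientations = aniso@nOrientations),
                       paste0(prefix, "_aniso.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(paste0(prefix, ".nii"))
}

#' Serialize rigid transforms to/from JSON
#'
#' Schema: `{rotation_deg, dx, dy, cx, cy}`.
#'
#' @param transform a [RigidTransform2D-class].
#' @param file JSON path.
#' @return `writeTransform`: invisibly the path; `readTransform`: a
#'   [RigidTransform2D-class].
#' @export
writeTransform <- function(transform, file) {
  jsonlite::write_json(list(rotation_deg = transform@rotationDeg,
                            dx = transform@translation[1],
                            dy = transform@translation[2],
                            cx = transform@center[1],
                            cy = transform@center[2]),
                       file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname writeTransform
#' @export
readTransform <- function(file) {
  f <- jsonlite::read_json(file, simplifyVector = TRUE)
  rigidTransform2D(f$rotation_deg, f$dx, f$dy, c(f$cx, f$cy))
}
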