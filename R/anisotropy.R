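#' @include AllClasses.R
NULL

#' Michelson contrast over orientations
#'
#' `A = (max - min) / (max + min)` of a positive quantity measured under
#' several conditions — here a relaxation time observed at the physical
#' orientations of the specimen. A is scale-invariant and, for positive
#' values, identical whether computed on relaxation times or on their
#' reciprocal rates (the min/max swap while the sum term rescales), so the
#' choice of times as the working quantity is immaterial.
#'
#' @param values >= 2 finite, non-negative values.
#' @return the contrast in \[0, 1\]; if `max + min == 0`, returns 0 with
#'   attribute `valid = FALSE`.
#' @examples
#' michelson(c(2, 1, 1.5, 1.2, 1.8))  # 1/3
#' @export
michelson <- function(values) {
  if (length(values) < 2L || any(!is.finite(values)))
    stop("michelson requires >= 2 finite values")
  if (any(values < 0))
    stop("michelson is defined for non-negative quantities ",
         "(relaxation times are positive)")
  mx <- max(values); mn <- min(values)
  if (mx + mn == 0) return(structure(0, valid = FALSE))
  (mx - mn) / (mx + mn)
}

#' Voxel-wise Michelson anisotropy map
#'
#' Computes the Michelson contrast of the relaxation time over the
#' orientation axis of a co-registered [OrientationStack-class], inside its
#' joint validity mask. Voxels with any invalid orientation are excluded
#' entirely (a min/max over a subset of orientations would bias A downward
#' inconsistently).
#'
#' @param stack an [OrientationStack-class] (>= 2 orientations).
#' @return an [AnisotropyMap-class].
#' @export
anisotropyMap <- function(stack) {
  stopifnot(is(stack, "OrientationStack"))
  tmaps <- lapply(stack@maps, relaxationTime)
  mx <- Reduce(pmax, tmaps)
  mn <- Reduce(pmin, tmaps)
  valid <- stack@jointValidity & is.finite(mx) & is.finite(mn) & (mx + mn) > 0
  a <- matrix(NA_real_, nrow(mx), ncol(mx))
  a[valid] <- (mx[valid] - mn[valid]) / (mx[valid] + mn[valid])
  new("AnisotropyMap", values = a, validityMask = valid,
      quantity = quantityLabel(stack@maps[[1]]@protocol),
      nOrientations = length(stack@maps))
}

#' Per-ROI relaxation and anisotropy statistics
#'
#' For each ROI label: the mean relaxation time at each orientation, the
#' mean and SD of the voxel-wise anisotropy A over the ROI's valid voxels
#' (the primary anisotropy statistic), and additionally the Michelson
#' contrast of the ROI-mean times (`anisotropyOfMeans`) — an ROI-level
#' alternative in which voxel noise averages out before the min/max is
#' taken. A label with no valid voxels is reported with `nVoxels = 0`,
#' missing statistics, and a warning.
#'
#' @param stack an [OrientationStack-class].
#' @param aniso the matching [AnisotropyMap-class].
#' @param roiMask integer label matrix on the reference grid (0 = outside).
#' @param labelNames optional character vector naming the labels, indexed by
#'   label value.
#' @return a `data.frame` with one row per label: `roi`, `label`,
#'   `nVoxels`, `meanAnisotropy`, `sdAnisotropy`, `anisotropyOfMeans` and
#'   one `meanTime_<deg>` column (seconds) per orientation.
#' @export
roiStats <- function(stack, aniso, roiMask, labelNames = NULL) {
  stopifnot(is(stack, "OrientationStack"), is(aniso, "AnisotropyMap"))
  stopifnot(identical(dim(roiMask), dim(stack@jointValidity)))
  labs <- sort(unique(roiMask[roiMask > 0]))
  if (!length(labs)) stop("roiMask contains no positive labels")
  tmaps <- lapply(stack@maps, relaxationTime)
  orients <- stack@orientationsDeg
  rows <- lapply(labs, function(lb) {
    inRoi <- roiMask == lb
    ok <- inRoi & aniso@validityMask
    n <- sum(ok)
    nm <- if (!is.null(labelNames) && lb <= length(labelNames))
      labelNames[lb] else paste0("roi", lb)
    mt <- vapply(tmaps, function(m) mean(m[ok]), 0)
    if (n == 0L) {
      warning("ROI label ", lb, " has no valid voxels")
      mt <- rep(NA_real_, length(tmaps))
    }
    av <- aniso@values[ok]
    out <- data.frame(roi = nm, label = lb, nVoxels = n,
                      meanAnisotropy = if (n) mean(av) else NA_real_,
                      sdAnisotropy = if (n > 1) stats::sd(av) else NA_real_,
                      anisotropyOfMeans = if (n) michelson(mt) else NA_real_)
    for (i in seq_along(orients))
      out[[sprintf("meanTime_%g", orients[i])]] <- mt[i]
    out
  })
  res <- do.call(rbind, rows)
  attr(res, "quantity") <- aniso@quantity
  res
}

#' Cross-sample anisotropy report
#'
#' Aggregates per-sample ROI statistics into the study-style summary table:
#' mean anisotropy (in percent) per quantity and ROI across samples, with
#' the between-sample SD and sample count. Input statistics must carry
#' `quantity`, `roi` and `meanAnisotropy` columns ([roiStats()] output rows
#' gain `quantity` via [stackReport()] or can be annotated by hand).
#'
#' @param samples list (one element per sample) of `data.frame`s with
#'   columns `quantity`, `roi`, `meanAnisotropy` (fractions in \[0, 1\]).
#' @param file optional path; when given the long-format table is written
#'   as CSV with header `quantity,roi,mean_anisotropy_percent,sd,n_samples`.
#' @return a `data.frame` in that long format (invisible when written).
#' @export
anisotropyTable <- function(samples, file = NULL) {
  if (!length(samples)) stop("anisotropyTable: empty input")
  keys <- lapply(samples, function(s) {
    stopifnot(all(c("quantity", "roi", "meanAnisotropy") %in% colnames(s)))
    paste(s$quantity, s$roi, sep = "\r")
  })
  ref <- sort(unique(keys[[1]]))
  for (i in seq_along(keys)) {
    ki <- sort(unique(keys[[i]]))
    if (!identical(ki, ref))
      stop("inconsistent ROI/quantity labels across samples: sample ", i,
           " has {", paste(gsub("\r", ":", ki), collapse = ", "),
           "} vs {", paste(gsub("\r", ":", ref), collapse = ", "), "}")
  }
  all <- do.call(rbind, lapply(samples, function(s)
    s[, c("quantity", "roi", "meanAnisotropy")]))
  agg <- stats::aggregate(meanAnisotropy ~ quantity + roi, data = all,
                          FUN = function(x)
                            c(m = mean(x), s = stats::sd(x), n = length(x)))
  out <- data.frame(quantity = agg$quantity, roi = agg$roi,
                    mean_anisotropy_percent =
                      round(100 * agg$meanAnisotropy[, "m"], 1),
                    sd = round(100 * agg$meanAnisotropy[, "s"], 1),
                    n_samples = as.integer(agg$meanAnisotropy[, "n"]))
  out <- out[order(out$quantity, out$roi), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(file)) {
    utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
    return(invisible(out))
  }
  out
}

#' Annotated ROI statistics for one co-registered stack
#'
#' Convenience composition: computes the anisotropy map of a stack, the ROI
#' statistics, and annotates them with the quantity label so they can feed
#' [anisotropyTable()] directly.
#'
#' @inheritParams roiStats
#' @return the [roiStats()] `data.frame` with a `quantity` column prepended.
#' @export
stackReport <- function(stack, roiMask, labelNames = NULL) {
  aniso <- anisotropyMap(stack)
  st <- roiStats(stack, aniso, roiMask, labelNames)
  cbind(quantity = aniso@quantity, st)
}
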