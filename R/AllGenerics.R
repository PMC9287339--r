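#' @include AllClasses.R
NULL

#' Accessors for RelaxAniso objects
#'
#' Standard accessor generics for the package's S4 containers. Accessors are
#' the supported way to reach object contents; slots are internal.
#'
#' @param object a RelaxAniso S4 object.
#' @return The corresponding component (see each method's class).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("images", function(object) standardGeneric("images"))

#' @rdname accessors
#' @export
setGeneric("protocol", function(object) standardGeneric("protocol"))

#' @rdname accessors
#' @export
setGeneric("timingAxis", function(object) standardGeneric("timingAxis"))

#' @rdname accessors
#' @export
setGeneric("orientationDeg", function(object) standardGeneric("orientationDeg"))

#' @rdname accessors
#' @export
setGeneric("relaxationTime", function(object) standardGeneric("relaxationTime"))

#' @rdname accessors
#' @export
setGeneric("amplitudeMap", function(object) standardGeneric("amplitudeMap"))

#' @rdname accessors
#' @export
setGeneric("steadyStateMap", function(object) standardGeneric("steadyStateMap"))

#' @rdname accessors
#' @export
setGeneric("validityMask", function(object) standardGeneric("validityMask"))

#' @rdname accessors
#' @export
setGeneric("sigmaFloor", function(object) standardGeneric("sigmaFloor"))

#' @rdname accessors
#' @export
setGeneric("fitParams", function(object) standardGeneric("fitParams"))

#' @rdname accessors
#' @export
setGeneric("maps", function(object) standardGeneric("maps"))

#' @rdname accessors
#' @export
setGeneric("transforms", function(object) standardGeneric("transforms"))

#' @rdname accessors
#' @export
setGeneric("orientationsDeg", function(object) standardGeneric("orientationsDeg"))

#' @rdname accessors
#' @export
setGeneric("jointValidity", function(object) standardGeneric("jointValidity"))

#' @rdname accessors
#' @export
setGeneric("anisoValues", function(object) standardGeneric("anisoValues"))

#' @rdname accessors
#' @export
setMethod("images", "RelaxationSeries", function(object) object@images)

#' @rdname accessors
#' @export
setMethod("protocol", "RelaxationSeries", function(object) object@protocol)

#' @rdname accessors
#' @export
setMethod("protocol", "ParameterMap", function(object) object@protocol)

#' @rdname accessors
#' @export
setMethod("timingAxis", "SequenceProtocol", function(object) object@timingAxis)

#' @rdname accessors
#' @export
setMethod("timingAxis", "RelaxationSeries",
          function(object) object@protocol@timingAxis)

#' @rdname accessors
#' @export
setMethod("orientationDeg", "RelaxationSeries",
          function(object) object@orientationDeg)

#' @rdname accessors
#' @export
setMethod("orientationDeg", "ParameterMap",
          function(object) object@orientationDeg)

#' @rdname accessors
#' @export
setMethod("relaxationTime", "ParameterMap",
          function(object) object@relaxationTime)

#' @rdname accessors
#' @export
setMethod("relaxationTime", "FitResult",
          function(object) object@params@relaxationTime)

#' @rdname accessors
#' @export
setMethod("amplitudeMap", "ParameterMap", function(object) object@amplitude)

#' @rdname accessors
#' @export
setMethod("steadyStateMap", "ParameterMap", function(object) object@steadyState)

#' @rdname accessors
#' @export
setMethod("validityMask", "ParameterMap", function(object) object@validityMask)

#' @rdname accessors
#' @export
setMethod("validityMask", "AnisotropyMap", function(object) object@validityMask)

#' @rdname accessors
#' @export
setMethod("sigmaFloor", "NoiseEstimate", function(object) object@sigmaFloor)

#' @rdname accessors
#' @export
setMethod("fitParams", "FitResult", function(object) object@params)

#' @rdname accessors
#' @export
setMethod("maps", "OrientationStack", function(object) object@maps)

#' @rdname accessors
#' @export
setMethod("transforms", "OrientationStack", function(object) object@transforms)

#' @rdname accessors
#' @export
setMethod("orientationsDeg", "OrientationStack",
          function(object) object@orientationsDeg)

#' @rdname accessors
#' @export
setMethod("jointValidity", "OrientationStack",
          function(object) object@jointValidity)

#' @rdname accessors
#' @export
setMethod("anisoValues", "AnisotropyMap", function(object) object@values)
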