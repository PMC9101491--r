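#' Accessor generics
#'
#' Small accessor generics shared by the wheatBRF S4 classes: sample grids
#' and values of irradiance spectra, band metadata, raster payloads and the
#' label raster of a segmentation.
#'
#' @param object An object of one of the wheatBRF S4 classes.
#' @return The slot content; see the class documentation pages.
#' @name wheatBRF-accessors
#' @rdname wheatBRF-accessors
NULL

#' @rdname wheatBRF-accessors
#' @export
setGeneric("wavelengths", function(object) standardGeneric("wavelengths"))

#' @rdname wheatBRF-accessors
#' @export
setGeneric("irradiance", function(object) standardGeneric("irradiance"))

#' @rdname wheatBRF-accessors
#' @export
setGeneric("bandLabel", function(object) standardGeneric("bandLabel"))

#' @rdname wheatBRF-accessors
#' @export
setGeneric("bandCenter", function(object) standardGeneric("bandCenter"))

#' @rdname wheatBRF-accessors
#' @export
setGeneric("bandWidth", function(object) standardGeneric("bandWidth"))

#' @rdname wheatBRF-accessors
#' @export
setGeneric("bandRange", function(object) standardGeneric("bandRange"))

#' @rdname wheatBRF-accessors
#' @export
setGeneric("bands", function(object) standardGeneric("bands"))

#' @rdname wheatBRF-accessors
#' @export
setGeneric("dn", function(object) standardGeneric("dn"))

#' @rdname wheatBRF-accessors
#' @export
setGeneric("brf", function(object) standardGeneric("brf"))

#' @rdname wheatBRF-accessors
#' @export
setGeneric("saturationMask", function(object) standardGeneric("saturationMask"))

#' @rdname wheatBRF-accessors
#' @export
setGeneric("labelRaster", function(object) standardGeneric("labelRaster"))

#' @rdname wheatBRF-accessors
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))

#' @rdname wheatBRF-accessors
#' @export
setGeneric("exposureTime", function(object) standardGeneric("exposureTime"))

#' @rdname wheatBRF-accessors
#' @export
setGeneric("curveCoefficients", function(object) standardGeneric("curveCoefficients"))

#' @rdname wheatBRF-accessors
#' @export
setGeneric("fitDomain", function(object) standardGeneric("fitDomain"))

#' @rdname wheatBRF-accessors
#' @export
setGeneric("rSquared", function(object) standardGeneric("rSquared"))

#' @rdname wheatBRF-accessors
#' @export
setGeneric("panelTargets", function(object) standardGeneric("panelTargets"))

#' @rdname wheatBRF-accessors
#' @export
setGeneric("panelRois", function(object) standardGeneric("panelRois"))
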