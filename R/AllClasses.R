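## Central S4 data objects of the package. All rasters follow the row-major
## convention: origin top-left, indexed (row, col).

setOldClass("POSIXct")

## -- internal condition helpers ---------------------------------------------

wbrfStop <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "wheatBRFError", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

wbrfWarn <- function(msg, class) {
  warning(structure(
    class = c(class, "wheatBRFWarning", "warning", "condition"),
    list(message = msg, call = NULL)
  ))
}

.emptyTime <- function() as.POSIXct(character(0), tz = "UTC")

## -- FilterBand --------------------------------------------------------------

#' Ideal optical filter band
#'
#' A camera filter band described by its center and full width, with unit
#' transmission inside \eqn{[c - w/2, c + w/2]} and zero outside (ideal
#' filter). The stock band set of the six-camera multispectral array is
#' available through [mcaBands()].
#'
#' @slot centerNm Band center in nm.
#' @slot widthNm Full band width in nm (> 0).
#' @slot label Band name; by convention the center wavelength as a string.
#'
#' @param centerNm,widthNm,label See slots.
#' @return A `FilterBand` object.
#' @examples
#' FilterBand(800, 10)
#' @export FilterBand
#' @exportClass FilterBand
FilterBand <- setClass("FilterBand", slots = c(
  centerNm = "numeric", widthNm = "numeric", label = "character"
))

setValidity("FilterBand", function(object) {
  if (length(object@centerNm) != 1L || !is.finite(object@centerNm))
    return("centerNm must be a single finite number")
  if (length(object@widthNm) != 1L || !is.finite(object@widthNm) ||
      object@widthNm <= 0)
    return("widthNm must be a single positive number")
  if (length(object@label) != 1L || !nzchar(object@label))
    return("label must be a non-empty string")
  TRUE
})

setMethod("initialize", "FilterBand", function(.Object, centerNm, widthNm,
                                               label = as.character(centerNm),
                                               ...) {
  .Object <- callNextMethod(.Object, centerNm = centerNm, widthNm = widthNm,
                            label = label, ...)
  validObject(.Object)
  .Object
})

#' @rdname wheatBRF-accessors
setMethod("bandLabel", "FilterBand", function(object) object@label)
#' @rdname wheatBRF-accessors
setMethod("bandCenter", "FilterBand", function(object) object@centerNm)
#' @rdname wheatBRF-accessors
setMethod("bandWidth", "FilterBand", function(object) object@widthNm)
#' @rdname wheatBRF-accessors
setMethod("bandRange", "FilterBand", function(object)
  object@centerNm + c(-0.5, 0.5) * object@widthNm)

setMethod("show", "FilterBand", function(object) {
  r <- bandRange(object)
  cat(sprintf("FilterBand '%s': %g nm +/- %g nm [%g, %g]\n",
              object@label, object@centerNm, object@widthNm / 2, r[1], r[2]))
})

#' Stock band set of the multispectral camera array
#'
#' The six narrow band-pass filters of the camera array: centers 490, 550,
#' 680, 720, 800 and 900 nm, each 10 nm wide except the 900 nm band which is
#' 20 nm wide.
#'
#' @return A named list of [FilterBand] objects, ordered by ascending center.
#' @examples
#' names(mcaBands())
#' @export
mcaBands <- function() {
  centers <- c(490, 550, 680, 720, 800, 900)
  widths <- c(10, 10, 10, 10, 10, 20)
  out <- mapply(function(c, w) FilterBand(c, w), centers, widths)
  names(out) <- as.character(centers)
  out
}

## -- IrradianceSpectrum ------------------------------------------------------

#' Downwelling spectral irradiance
#'
#' A sampled incident-light spectrum from an up-facing spectrometer with
#' cosine corrector: spectral irradiance (W m-2 nm-1) on a strictly
#' ascending wavelength grid (nm), optionally time-stamped. Spectra are
#' assumed already corrected for instrument dark noise and non-linearity.
#'
#' @slot wavelengthNm Strictly increasing wavelength grid in nm.
#' @slot irradiance Non-negative spectral irradiance, one value per sample.
#' @slot timestamp Acquisition instant (`POSIXct`, timezone-aware); may be
#'   empty when unknown.
#'
#' @param wavelengthNm,irradiance,timestamp See slots.
#' @return An `IrradianceSpectrum`.
#' @examples
#' s <- IrradianceSpectrum(400:1000, rep(1, 601))
#' integrateBand(s, FilterBand(490, 10))
#' @export IrradianceSpectrum
#' @exportClass IrradianceSpectrum
IrradianceSpectrum <- setClass("IrradianceSpectrum", slots = c(
  wavelengthNm = "numeric", irradiance = "numeric", timestamp = "POSIXct"
), prototype = prototype(timestamp = .emptyTime()))

setValidity("IrradianceSpectrum", function(object) {
  w <- object@wavelengthNm
  e <- object@irradiance
  if (length(w) < 2L) return("need at least two wavelength samples")
  if (length(w) != length(e))
    return("wavelengthNm and irradiance lengths differ")
  if (anyNA(w) || anyNA(e)) return("NA values in spectrum")
  if (any(diff(w) <= 0)) return("wavelengths must be strictly increasing")
  if (any(e < 0)) return("irradiance values must be >= 0")
  if (length(object@timestamp) > 1L) return("timestamp must be length 0 or 1")
  TRUE
})

setMethod("initialize", "IrradianceSpectrum",
          function(.Object, wavelengthNm, irradiance,
                   timestamp = .emptyTime(), ...) {
  .Object <- callNextMethod(.Object, wavelengthNm = as.numeric(wavelengthNm),
                            irradiance = as.numeric(irradiance),
                            timestamp = timestamp, ...)
  validObject(.Object)
  .Object
})

#' @rdname wheatBRF-accessors
setMethod("wavelengths", "IrradianceSpectrum", function(object)
  object@wavelengthNm)
#' @rdname wheatBRF-accessors
setMethod("irradiance", "IrradianceSpectrum", function(object)
  object@irradiance)

setMethod("show", "IrradianceSpectrum", function(object) {
  w <- object@wavelengthNm
  cat(sprintf(
    "IrradianceSpectrum: %d samples, %g-%g nm, peak %.4g W m-2 nm-1\n",
    length(w), min(w), max(w), max(object@irradiance)))
  if (length(object@timestamp))
    cat("  timestamp:", format(object@timestamp, usetz = TRUE), "\n")
})

## -- SunGeometry -------------------------------------------------------------

#' Sun position for an instant and site
#'
#' Sun zenith (degrees from vertical) and azimuth (degrees clockwise from
#' north), together with the instant and site they refer to. Produced by
#' [sunPosition()].
#'
#' @slot zenithDeg Sun zenith angle in degrees, in \eqn{[0, 180]}; values
#'   above 90 mean the sun is below the horizon.
#' @slot azimuthDeg Azimuth in degrees clockwise from north, in \eqn{[0, 360)}.
#' @slot timestamp The instant (`POSIXct`, timezone-aware).
#' @slot latitudeDeg,longitudeDeg Site coordinates (degrees; east positive).
#'
#' @param zenithDeg,azimuthDeg,timestamp,latitudeDeg,longitudeDeg See slots.
#' @return A `SunGeometry`.
#' @export SunGeometry
#' @exportClass SunGeometry
SunGeometry <- setClass("SunGeometry", slots = c(
  zenithDeg = "numeric", azimuthDeg = "numeric", timestamp = "POSIXct",
  latitudeDeg = "numeric", longitudeDeg = "numeric"
), prototype = prototype(timestamp = .emptyTime(),
                         latitudeDeg = NA_real_, longitudeDeg = NA_real_))

setValidity("SunGeometry", function(object) {
  if (length(object@zenithDeg) != 1L || object@zenithDeg < 0 ||
      object@zenithDeg > 180)
    return("zenithDeg must be a single value in [0, 180]")
  if (length(object@azimuthDeg) != 1L || object@azimuthDeg < 0 ||
      object@azimuthDeg >= 360)
    return("azimuthDeg must be a single value in [0, 360)")
  TRUE
})

setMethod("show", "SunGeometry", function(object) {
  cat(sprintf("SunGeometry: zenith %.3f deg, azimuth %.3f deg\n",
              object@zenithDeg, object@azimuthDeg))
  if (length(object@timestamp))
    cat("  at", format(object@timestamp, usetz = TRUE),
        sprintf("(lat %.4f, lon %.4f)\n",
                object@latitudeDeg, object@longitudeDeg))
})

## -- PanelSpec ---------------------------------------------------------------

#' Reference panel specification
#'
#' The calibration panel: four diffuse targets (black, dark_gray,
#' light_gray, white) of known reflectance spectra, plus the pixel
#' rectangles (regions of interest) where each target appears in panel
#' shots. ROIs are integer vectors `c(rowMin, rowMax, colMin, colMax)`,
#' 1-based and inclusive.
#'
#' @slot targets Named list; each element a `data.frame` with columns
#'   `wavelength_nm` and `reflectance` (dimensionless, in \eqn{[0, 1]}).
#' @slot rois Named list of ROI rectangles, same names as `targets`;
#'   rectangles must not overlap.
#'
#' @param targets,rois See slots.
#' @return A `PanelSpec`.
#' @seealso [defaultPanelSpec()] for the synthetic stock panel.
#' @export PanelSpec
#' @exportClass PanelSpec
PanelSpec <- setClass("PanelSpec", slots = c(targets = "list", rois = "list"))

.panelTargetNames <- c("black", "dark_gray", "light_gray", "white")

.roisOverlap <- function(a, b) {
  a[1] <= b[2] && b[1] <= a[2] && a[3] <= b[4] && b[3] <= a[4]
}

setValidity("PanelSpec", function(object) {
  if (!all(.panelTargetNames %in% names(object@targets)))
    return(paste("targets must include:",
                 paste(.panelTargetNames, collapse = ", ")))
  for (nm in names(object@targets)) {
    tg <- object@targets[[nm]]
    if (!is.data.frame(tg) ||
        !all(c("wavelength_nm", "reflectance") %in% names(tg)))
      return(sprintf(
        "target '%s' must be a data.frame(wavelength_nm, reflectance)", nm))
    if (any(tg$reflectance < 0 | tg$reflectance > 1))
      return(sprintf("target '%s' reflectance outside [0, 1]", nm))
    if (any(diff(tg$wavelength_nm) <= 0))
      return(sprintf("target '%s' wavelengths not strictly increasing", nm))
  }
  if (length(object@rois)) {
    if (!all(names(object@rois) %in% names(object@targets)))
      return("roi names must match target names")
    for (r in object@rois)
      if (length(r) != 4L || r[1] > r[2] || r[3] > r[4] || any(r < 1))
        return("each roi must be c(rowMin, rowMax, colMin, colMax), 1-based")
    nm <- names(object@rois)
    for (i in seq_along(nm)) for (j in seq_len(i - 1L))
      if (.roisOverlap(object@rois[[i]], object@rois[[j]]))
        return(sprintf("rois '%s' and '%s' overlap", nm[i], nm[j]))
  }
  TRUE
})

#' @rdname wheatBRF-accessors
setMethod("panelTargets", "PanelSpec", function(object) object@targets)
#' @rdname wheatBRF-accessors
setMethod("panelRois", "PanelSpec", function(object) object@rois)

setMethod("show", "PanelSpec", function(object) {
  cat("PanelSpec with targets:",
      paste(names(object@targets), collapse = ", "), "\n")
  if (length(object@rois)) cat("  rois for:",
      paste(names(object@rois), collapse = ", "), "\n")
})

## -- CalibrationShot ---------------------------------------------------------

#' One panel calibration exposure
#'
#' A single image of the reference panel for one camera band: the DN raster
#' (or, alternatively, pre-extracted per-target mean DNs), the exposure time
#' and the incident-light spectrum recorded at capture.
#'
#' @slot dn Integer-valued DN raster of the panel shot; may be a 0x0 matrix
#'   when `targetDN` is supplied instead.
#' @slot targetDN Named numeric of per-target mean DN (alternative to `dn`).
#' @slot exposureTimeS Exposure time in seconds (> 0).
#' @slot spectrum The [IrradianceSpectrum] at capture.
#' @slot bitDepth Sensor bit depth (DN saturate at `2^bitDepth - 1`).
#'
#' @param dn,targetDN,exposureTimeS,spectrum,bitDepth See slots.
#' @return A `CalibrationShot`.
#' @export CalibrationShot
#' @exportClass CalibrationShot
CalibrationShot <- setClass("CalibrationShot", slots = c(
  dn = "matrix", targetDN = "numeric", exposureTimeS = "numeric",
  spectrum = "IrradianceSpectrum", bitDepth = "integer"
), prototype = prototype(dn = matrix(numeric(0), 0, 0),
                         targetDN = numeric(0), bitDepth = 10L))

setValidity("CalibrationShot", function(object) {
  if (length(object@exposureTimeS) != 1L || object@exposureTimeS <= 0)
    return("exposureTimeS must be a single positive number")
  if (!length(object@dn) && !length(object@targetDN))
    return("either dn raster or targetDN means must be supplied")
  if (length(object@dn) && any(object@dn < 0, na.rm = TRUE))
    return("dn values must be >= 0")
  if (length(object@dn) &&
      any(object@dn > 2^object@bitDepth - 1, na.rm = TRUE))
    return("dn values exceed bit depth")
  TRUE
})

#' @rdname wheatBRF-accessors
setMethod("exposureTime", "CalibrationShot", function(object)
  object@exposureTimeS)
#' @rdname wheatBRF-accessors
setMethod("dn", "CalibrationShot", function(object) object@dn)

## -- ResponseCurve -----------------------------------------------------------

#' Fitted camera response curve
#'
#' The fitted relation between image digital numbers (DN) and exposure at
#' the lens entrance, Hlens = L t (units (W m-2 sr-1) s; the per-steradian
#' factor is implicit throughout because the pi of the reflectance-factor
#' definition absorbs the geometry). The curve is a polynomial with the
#' DN-intercept forced to 0 and must be strictly increasing over its fit
#' domain; the transmission of the optics is absorbed into the fitted
#' coefficients rather than modelled separately.
#'
#' @slot band The [FilterBand] the curve belongs to.
#' @slot coefficients Polynomial coefficients `c(a1, a2, ...)` for
#'   `Hlens = a1 DN + a2 DN^2 + ...` (no constant term).
#' @slot fitDomain DN range `c(min, max)` covered by the calibration points.
#' @slot r2 Coefficient of determination of the fit.
#' @slot nPoints Number of calibration points used.
#'
#' @param band,coefficients,fitDomain,r2,nPoints See slots.
#' @return A `ResponseCurve`.
#' @seealso [fitResponseCurve()], [invertResponse()]
#' @export ResponseCurve
#' @exportClass ResponseCurve
ResponseCurve <- setClass("ResponseCurve", slots = c(
  band = "FilterBand", coefficients = "numeric", fitDomain = "numeric",
  r2 = "numeric", nPoints = "integer"
), prototype = prototype(r2 = NA_real_, nPoints = NA_integer_))

setValidity("ResponseCurve", function(object) {
  if (!length(object@coefficients)) return("no coefficients")
  if (length(object@fitDomain) != 2L || object@fitDomain[1] > object@fitDomain[2])
    return("fitDomain must be c(min, max)")
  ## strict monotonicity on the fit domain (checked on a fine grid)
  g <- seq(max(0, object@fitDomain[1]), object@fitDomain[2], length.out = 513)
  d <- .polyDeriv(object@coefficients, g)
  if (any(d <= 0)) return("curve is not strictly increasing on fitDomain")
  TRUE
})

.polyEval <- function(coefs, x) {
  ## origin-constrained polynomial: sum_k coefs[k] * x^k
  out <- 0
  for (k in rev(seq_along(coefs))) out <- (out + coefs[k]) * x
  out
}

.polyDeriv <- function(coefs, x) {
  out <- 0
  ks <- seq_along(coefs)
  for (k in rev(ks[-1L])) out <- (out + k * coefs[k]) * x
  out + coefs[1L]
}

#' @rdname wheatBRF-accessors
setMethod("curveCoefficients", "ResponseCurve", function(object)
  object@coefficients)
#' @rdname wheatBRF-accessors
setMethod("fitDomain", "ResponseCurve", function(object) object@fitDomain)
#' @rdname wheatBRF-accessors
setMethod("rSquared", "ResponseCurve", function(object) object@r2)
#' @rdname wheatBRF-accessors
setMethod("bands", "ResponseCurve", function(object) object@band)

setMethod("show", "ResponseCurve", function(object) {
  cat(sprintf(
    "ResponseCurve [%s nm]: degree %d, DN domain [%g, %g], R2 = %s\n",
    bandLabel(object@band), length(object@coefficients),
    object@fitDomain[1], object@fitDomain[2],
    ifelse(is.na(object@r2), "NA", sprintf("%.6f", object@r2))))
  cat("  coefficients:", paste(signif(object@coefficients, 6),
                               collapse = ", "), "\n")
})

## -- ChannelImage ------------------------------------------------------------

#' Single-band DN image
#'
#' A per-band canopy (or panel) image as recorded: an integer DN raster with
#' its filter band, exposure time, bit depth and timestamp.
#'
#' @slot dn Integer-valued DN raster (matrix, row-major, origin top-left).
#' @slot band The [FilterBand].
#' @slot exposureTimeS Exposure time in seconds (> 0).
#' @slot bitDepth Sensor bit depth; DN must lie in `[0, 2^bitDepth - 1]`.
#' @slot timestamp Acquisition instant; may be empty.
#'
#' @param dn,band,exposureTimeS,bitDepth,timestamp See slots.
#' @return A `ChannelImage`.
#' @export ChannelImage
#' @exportClass ChannelImage
ChannelImage <- setClass("ChannelImage", slots = c(
  dn = "matrix", band = "FilterBand", exposureTimeS = "numeric",
  bitDepth = "integer", timestamp = "POSIXct"
), prototype = prototype(bitDepth = 10L, timestamp = .emptyTime()))

setValidity("ChannelImage", function(object) {
  if (length(object@exposureTimeS) != 1L || !is.finite(object@exposureTimeS) ||
      object@exposureTimeS <= 0)
    return("exposureTimeS must be a single positive number")
  if (!length(object@dn)) return("empty DN raster")
  if (any(object@dn < 0) || any(object@dn > 2^object@bitDepth - 1))
    return("DN outside bit-depth range")
  TRUE
})

#' @rdname wheatBRF-accessors
setMethod("dn", "ChannelImage", function(object) object@dn)
#' @rdname wheatBRF-accessors
setMethod("bands", "ChannelImage", function(object) object@band)
#' @rdname wheatBRF-accessors
setMethod("exposureTime", "ChannelImage", function(object)
  object@exposureTimeS)

setMethod("show", "ChannelImage", function(object) {
  cat(sprintf("ChannelImage [%s nm]: %d x %d px, t = %g s, %d-bit\n",
              bandLabel(object@band), nrow(object@dn), ncol(object@dn),
              object@exposureTimeS, object@bitDepth))
})

## -- BRFMap ------------------------------------------------------------------

#' Per-band BRF raster
#'
#' The dimensionless bi-directional reflectance factor counterpart of a
#' [ChannelImage]: per-pixel BRF together with the band, the band-integrated
#' incident irradiance used in the conversion and a saturation mask marking
#' pixels at the sensor maximum (excluded from organ means).
#'
#' @slot brf Non-negative finite BRF raster.
#' @slot band The [FilterBand].
#' @slot eBand Band-integrated incident irradiance (W m-2) used.
#' @slot saturated Logical raster, `TRUE` where the source DN was saturated.
#'
#' @param brf,band,eBand,saturated See slots.
#' @return A `BRFMap`. Construction warns (soft physical-plausibility check)
#'   when any BRF exceeds 1.5.
#' @export BRFMap
#' @exportClass BRFMap
BRFMap <- setClass("BRFMap", slots = c(
  brf = "matrix", band = "FilterBand", eBand = "numeric", saturated = "matrix"
))

setValidity("BRFMap", function(object) {
  if (!length(object@brf)) return("empty BRF raster")
  if (any(!is.finite(object@brf))) return("non-finite BRF values")
  if (any(object@brf < 0)) return("negative BRF values")
  if (!identical(dim(object@brf), dim(object@saturated)))
    return("saturation mask shape differs from BRF raster")
  if (length(object@eBand) != 1L || object@eBand < 0)
    return("eBand must be a single non-negative number")
  TRUE
})

setMethod("initialize", "BRFMap", function(.Object, ..., brf) {
  .Object <- callNextMethod(.Object, ..., brf = brf)
  validObject(.Object)
  if (any(.Object@brf > 1.5))
    wbrfWarn(sprintf(
      "%d BRF pixels exceed 1.5 (physically implausible for vegetation)",
      sum(.Object@brf > 1.5)), "implausibleBRFWarning")
  .Object
})

#' @rdname wheatBRF-accessors
setMethod("brf", "BRFMap", function(object) object@brf)
#' @rdname wheatBRF-accessors
setMethod("bands", "BRFMap", function(object) object@band)
#' @rdname wheatBRF-accessors
setMethod("saturationMask", "BRFMap", function(object) object@saturated)

setMethod("show", "BRFMap", function(object) {
  cat(sprintf(
    "BRFMap [%s nm]: %d x %d px, BRF range [%.4f, %.4f], E_band = %.4g W m-2\n",
    bandLabel(object@band), nrow(object@brf), ncol(object@brf),
    min(object@brf), max(object@brf), object@eBand))
  if (any(object@saturated))
    cat(" ", sum(object@saturated), "saturated pixels masked\n")
})

## -- BRFStack ----------------------------------------------------------------

#' Multi-band BRF stack
#'
#' An ordered collection of co-registered [BRFMap] objects (ascending band
#' center), the unit the segmentation and organ-pooling steps operate on.
#' Build with [stackBands()].
#'
#' @slot maps List of [BRFMap], ordered by ascending band center, named by
#'   band label.
#'
#' @param maps See slot.
#' @return A `BRFStack`.
#' @export BRFStack
#' @exportClass BRFStack
BRFStack <- setClass("BRFStack", slots = c(maps = "list"))

setValidity("BRFStack", function(object) {
  if (!length(object@maps)) return("empty stack")
  if (!all(vapply(object@maps, is, logical(1), "BRFMap")))
    return("all elements must be BRFMap objects")
  dims <- vapply(object@maps, function(m) dim(m@brf), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    return("raster shapes differ across bands")
  centers <- vapply(object@maps, function(m) bandCenter(m@band), numeric(1))
  if (any(diff(centers) <= 0))
    return("bands must be distinct and ordered by ascending center")
  TRUE
})

#' @rdname wheatBRF-accessors
setMethod("bands", "BRFStack", function(object)
  lapply(object@maps, function(m) m@band))

#' Extract one band's BRF map from a stack
#'
#' @param x A [BRFStack].
#' @param i Band label (character) or index.
#' @param ... Unused.
#' @return The [BRFMap] for that band.
#' @export
setMethod("[[", "BRFStack", function(x, i, ...) {
  m <- x@maps[[i]]
  if (is.null(m)) wbrfStop(sprintf("no band '%s' in stack", i),
                           "validationError")
  m
})

setMethod("length", "BRFStack", function(x) length(x@maps))

setMethod("names", "BRFStack", function(x) names(x@maps))

setMethod("show", "BRFStack", function(object) {
  cat(sprintf("BRFStack: %d bands (%s), %d x %d px\n", length(object@maps),
              paste(names(object@maps), collapse = ", "),
              nrow(object@maps[[1]]@brf), ncol(object@maps[[1]]@brf)))
})

## -- LabelMap ----------------------------------------------------------------

#' Three-class organ label map
#'
#' Per-pixel class raster used to pool BRF by organ: 0 = background (soil),
#' 1 = leaf (leaves plus visible stems), 2 = ear. Carries provenance: which
#' thresholds fired, the cloudiness gate state and any fallback taken.
#'
#' @slot labels Integer raster with values in \{0, 1, 2\}.
#' @slot provenance Named list describing how the map was produced.
#'
#' @param labels,provenance See slots.
#' @return A `LabelMap`.
#' @export LabelMap
#' @exportClass LabelMap
LabelMap <- setClass("LabelMap", slots = c(
  labels = "matrix", provenance = "list"
), prototype = prototype(provenance = list()))

#' Organ class codes
#' @format Named integer vector mapping organ names to label codes.
#' @export
ORGAN_CLASSES <- c(background = 0L, leaf = 1L, ear = 2L)

setValidity("LabelMap", function(object) {
  if (!length(object@labels)) return("empty label raster")
  if (!all(object@labels %in% ORGAN_CLASSES))
    return("labels must be 0 (background), 1 (leaf) or 2 (ear)")
  TRUE
})

#' @rdname wheatBRF-accessors
setMethod("labelRaster", "LabelMap", function(object) object@labels)
#' @rdname wheatBRF-accessors
setMethod("provenance", "LabelMap", function(object) object@provenance)

setMethod("show", "LabelMap", function(object) {
  n <- length(object@labels)
  counts <- vapply(ORGAN_CLASSES, function(k) sum(object@labels == k),
                   integer(1))
  cat(sprintf("LabelMap: %d x %d px; background %d, leaf %d, ear %d (%.1f%% vegetation)\n",
              nrow(object@labels), ncol(object@labels),
              counts["background"], counts["leaf"], counts["ear"],
              100 * (counts["leaf"] + counts["ear"]) / n))
})

## -- SegmentationConfig ------------------------------------------------------

#' Segmentation configuration
#'
#' Tunables of the background/leaf/ear segmentation. The near-infrared
#' threshold itself is automatic (first local minimum of the smoothed
#' histogram); this object holds the histogram construction parameters, the
#' auxiliary thresholds used under strong direct sunlight and the
#' cloudiness gate. The blue and Excess-Red thresholds are site-specific:
#' the defaults are calibrated on the package's forward simulator and
#' should be re-tuned for real acquisitions.
#'
#' @slot nirBandLabel Label of the near-infrared channel (default "800").
#' @slot blueBandLabel Label of the blue channel (default "490").
#' @slot blueThreshold Auxiliary blue cutoff: candidate vegetation pixels
#'   with blue value above this are rejected when the gate is active.
#'   Interpreted on whatever scale the rasters passed in use (DN by
#'   default).
#' @slot exrThreshold Auxiliary Excess-Red cutoff (chromatic scale);
#'   candidate pixels with ExR above it are rejected when the gate fires.
#' @slot ctGate Cloudiness-index gate in (0, 1]; auxiliary thresholds
#'   activate when C_T < ctGate (strong direct sunlight). Default 0.90.
#' @slot auxNirMax Upper NIR bound of the "low-value" zone to which the
#'   auxiliary tests are applied; `Inf` applies them to every candidate
#'   vegetation pixel.
#' @slot histogramBins Number of histogram bins for the valley search.
#' @slot histogramSmoothingWindow Moving-average window (bins) applied to
#'   the histogram before the valley search.
#' @slot valleyProminence A local minimum counts as a histogram valley
#'   only if the smoothed counts on both sides reach at least this factor
#'   times the valley count; guards against sampling-noise dips in a
#'   unimodal histogram (default 1.5).
#'
#' @param nirBandLabel,blueBandLabel,blueThreshold,exrThreshold,ctGate See slots.
#' @param auxNirMax,histogramBins,histogramSmoothingWindow,valleyProminence See slots.
#' @return A `SegmentationConfig`.
#' @export SegmentationConfig
#' @exportClass SegmentationConfig
SegmentationConfig <- setClass("SegmentationConfig", slots = c(
  nirBandLabel = "character", blueBandLabel = "character",
  blueThreshold = "numeric", exrThreshold = "numeric", ctGate = "numeric",
  auxNirMax = "numeric", histogramBins = "integer",
  histogramSmoothingWindow = "integer", valleyProminence = "numeric"
), prototype = prototype(
  nirBandLabel = "800", blueBandLabel = "490", blueThreshold = 280,
  exrThreshold = 0.10, ctGate = 0.90, auxNirMax = Inf,
  histogramBins = 256L, histogramSmoothingWindow = 5L,
  valleyProminence = 1.5
))

setValidity("SegmentationConfig", function(object) {
  if (!is.finite(object@blueThreshold) || !is.finite(object@exrThreshold))
    return("thresholds must be finite")
  if (object@ctGate <= 0 || object@ctGate > 1)
    return("ctGate must be in (0, 1]")
  if (object@histogramBins < 8L) return("histogramBins too small")
  if (object@histogramSmoothingWindow < 1L ||
      object@histogramSmoothingWindow %% 2L == 0L)
    return("histogramSmoothingWindow must be a positive odd integer")
  if (object@valleyProminence < 1)
    return("valleyProminence must be >= 1")
  TRUE
})

## -- PanelCheck --------------------------------------------------------------

#' Begin/end panel measurement for one band
#'
#' The dark-gray (by default) reference-target BRF measured at the start
#' and end of a field session, with the theoretical band-integrated
#' reference reflectance, as used by the inter-date correction.
#' Missing begin or end measurements are `NA`.
#'
#' @slot band Band label.
#' @slot brfBegin,brfEnd Measured target BRF at session start / end (`NA`
#'   when absent).
#' @slot brfTheoretical Band-integrated reference reflectance (> 0).
#'
#' @param band,brfBegin,brfEnd,brfTheoretical See slots.
#' @return A `PanelCheck`.
#' @export PanelCheck
#' @exportClass PanelCheck
PanelCheck <- setClass("PanelCheck", slots = c(
  band = "character", brfBegin = "numeric", brfEnd = "numeric",
  brfTheoretical = "numeric"
))

setValidity("PanelCheck", function(object) {
  vals <- c(object@brfBegin, object@brfEnd)
  if (any(vals < 0, na.rm = TRUE)) return("measured BRF must be >= 0")
  if (length(object@brfTheoretical) != 1L || is.na(object@brfTheoretical) ||
      object@brfTheoretical <= 0)
    return("brfTheoretical must be a single positive number")
  TRUE
})

## -- SceneTruth --------------------------------------------------------------

#' Ground truth of a simulated scene
#'
#' The forward simulator's scene description: an organ label raster and a
#' reflectance spectrum per class. The per-band true reflectance map any
#' analysis result is compared against derives from these.
#'
#' @slot labels Integer raster with organ codes (see [ORGAN_CLASSES]; 0 is
#'   soil background).
#' @slot spectra Named list (`soil`, `leaf`, and optionally `ear`) of
#'   `data.frame(wavelength_nm, reflectance)` class spectra.
#'
#' @param labels,spectra See slots.
#' @return A `SceneTruth`.
#' @seealso [makeSceneTruth()]
#' @export SceneTruth
#' @exportClass SceneTruth
SceneTruth <- setClass("SceneTruth", slots = c(
  labels = "matrix", spectra = "list"
))

setValidity("SceneTruth", function(object) {
  if (!all(object@labels %in% ORGAN_CLASSES))
    return("labels must use the organ class codes 0/1/2")
  need <- c("soil", "leaf")
  if (!all(need %in% names(object@spectra)))
    return("spectra must include at least 'soil' and 'leaf'")
  if (any(object@labels == ORGAN_CLASSES[["ear"]]) &&
      !("ear" %in% names(object@spectra)))
    return("scene contains ears but no 'ear' spectrum")
  for (nm in names(object@spectra)) {
    sp <- object@spectra[[nm]]
    if (any(sp$reflectance < 0 | sp$reflectance > 1))
      return(sprintf("class '%s' reflectance outside [0, 1]", nm))
  }
  TRUE
})

#' @rdname wheatBRF-accessors
setMethod("labelRaster", "SceneTruth", function(object) object@labels)

## -- CameraModel -------------------------------------------------------------

#' Forward camera model for the simulator
#'
#' Per-band true response (an origin-constrained polynomial mapping DN to
#' Hlens, the same parameterisation the calibration fits), sensor bit
#' depth, multiplicative noise level and a radiometric gain. When
#' rendering, the simulator solves the true response for DN in closed form
#' (or by bisection), so the forward path shares no code with
#' [invertResponse()].
#'
#' @slot bands Named list of [FilterBand] objects.
#' @slot trueCoefficients Named list (same names) of coefficient vectors
#'   `c(a1, a2, ...)` with `Hlens = a1 DN + a2 DN^2 + ...`; strictly
#'   increasing over the DN range.
#' @slot bitDepth Sensor bit depth; DN saturate (clip) at `2^bitDepth - 1`.
#' @slot noiseSigma Multiplicative Gaussian noise sigma applied to DN
#'   before rounding (0 = noiseless).
#' @slot gain Scalar radiometric sensitivity factor multiplying the
#'   exposure seen by the sensor; used to inject inter-date drift
#'   (default 1).
#'
#' @param bands,trueCoefficients,bitDepth,noiseSigma,gain See slots.
#' @return A `CameraModel`.
#' @seealso [defaultCameraModel()]
#' @export CameraModel
#' @exportClass CameraModel
CameraModel <- setClass("CameraModel", slots = c(
  bands = "list", trueCoefficients = "list", bitDepth = "integer",
  noiseSigma = "numeric", gain = "numeric"
), prototype = prototype(bitDepth = 10L, noiseSigma = 0, gain = 1))

setValidity("CameraModel", function(object) {
  if (!length(object@trueCoefficients)) return("no band coefficients")
  if (is.null(names(object@trueCoefficients)))
    return("trueCoefficients must be named by band label")
  if (!identical(sort(names(object@bands)),
                 sort(names(object@trueCoefficients))))
    return("bands and trueCoefficients names must match")
  if (!all(vapply(object@bands, is, logical(1), "FilterBand")))
    return("bands must be FilterBand objects")
  if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
  if (object@gain <= 0) return("gain must be > 0")
  dnMax <- 2^object@bitDepth - 1
  for (nm in names(object@trueCoefficients)) {
    cf <- object@trueCoefficients[[nm]]
    g <- seq(0, dnMax, length.out = 257)
    if (any(.polyDeriv(cf, g) <= 0))
      return(sprintf("band '%s' true response not strictly increasing", nm))
  }
  TRUE
})
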