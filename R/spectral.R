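## Band integration of incident-light spectra and the cloudiness index.

.checkCoverage <- function(w, band) {
  r <- bandRange(band)
  if (r[1] < min(w) - 1e-9 || r[2] > max(w) + 1e-9)
    wbrfStop(sprintf(
      "band '%s' [%g, %g] nm outside spectrum coverage [%g, %g] nm",
      bandLabel(band), r[1], r[2], min(w), max(w)), "coverageError")
  r
}

## Trapezoid integral of (w, y) over [lo, hi]: native grid clipped to the
## window, with linearly interpolated endpoint samples. No resampling, so the
## spectrometer's own resolution is respected.
.trapzWindow <- function(w, y, lo, hi) {
  inside <- w > lo & w < hi
  wi <- c(lo, w[inside], hi)
  yi <- c(stats::approx(w, y, xout = lo, rule = 1)$y,
          y[inside],
          stats::approx(w, y, xout = hi, rule = 1)$y)
  pracma::trapz(wi, yi)
}

#' Band-integrated incident irradiance
#'
#' Integrates a downwelling irradiance spectrum over one camera filter band,
#' treating the filter as ideal: unit transmission inside
#' \eqn{[c - w/2, c + w/2]}, zero outside. This is the per-band incident
#' irradiance E (W m-2) entering the reflectance-factor computation.
#' Trapezoid rule on the native spectrometer grid, with linear interpolation
#' to the exact band edges.
#'
#' @param spectrum An [IrradianceSpectrum].
#' @param band A [FilterBand]; must lie inside the spectrum's coverage.
#' @return Band irradiance in W m-2 (single non-negative number).
#' @examples
#' s <- IrradianceSpectrum(400:1000, rep(1, 601))
#' integrateBand(s, FilterBand(490, 10))  # 10 W m-2
#' @export
integrateBand <- function(spectrum, band) {
  stopifnot(is(spectrum, "IrradianceSpectrum"), is(band, "FilterBand"))
  r <- .checkCoverage(spectrum@wavelengthNm, band)
  .trapzWindow(spectrum@wavelengthNm, spectrum@irradiance, r[1], r[2])
}

#' Band-averaged reflectance
#'
#' Integrates a dimensionless reflectance spectrum over a filter band and
#' divides by the band width, yielding the band-average reflectance in
#' \eqn{[0, 1]}. Used for the reference-panel targets.
#'
#' @param reflectanceSpectrum A `data.frame` with columns `wavelength_nm`
#'   and `reflectance`, or a two-column numeric matrix in that order.
#' @param band A [FilterBand] inside the spectrum's coverage.
#' @return Band-average reflectance (dimensionless).
#' @examples
#' rho <- data.frame(wavelength_nm = 400:1000, reflectance = 0.19)
#' integrateReflectanceBand(rho, FilterBand(550, 10))  # 0.19
#' @export
integrateReflectanceBand <- function(reflectanceSpectrum, band) {
  stopifnot(is(band, "FilterBand"))
  if (is.matrix(reflectanceSpectrum))
    reflectanceSpectrum <- data.frame(
      wavelength_nm = reflectanceSpectrum[, 1],
      reflectance = reflectanceSpectrum[, 2])
  w <- reflectanceSpectrum$wavelength_nm
  y <- reflectanceSpectrum$reflectance
  if (any(diff(w) <= 0))
    wbrfStop("reflectance wavelengths must be strictly increasing",
             "validationError")
  r <- .checkCoverage(w, band)
  .trapzWindow(w, y, r[1], r[2]) / bandWidth(band)
}

#' Total irradiance over the sensor's spectral range
#'
#' The full-range integral of an incident-light spectrum (trapezoid on the
#' native grid), the E of the cloudiness index. The integration range is
#' attached as attribute `"rangeNm"` for comparability across instruments.
#'
#' @param spectrum An [IrradianceSpectrum].
#' @return Total irradiance in W m-2, with attribute `rangeNm`.
#' @export
totalIrradiance <- function(spectrum) {
  stopifnot(is(spectrum, "IrradianceSpectrum"))
  out <- pracma::trapz(spectrum@wavelengthNm, spectrum@irradiance)
  attr(out, "rangeNm") <- range(spectrum@wavelengthNm)
  out
}

#' Solar constant used by the cloudiness index (W m-2)
#' @export
SOLAR_CONSTANT <- 1360

#' Cloudiness index
#'
#' \eqn{C_T = 1 - E / (E_0 \cos z)} with solar constant
#' \eqn{E_0 = 1360} W m-2: the fraction of the clear-sky-normal irradiance
#' missing at the ground. Small values indicate strong direct sunlight,
#' values near 1 heavy overcast; the segmentation gate activates its
#' auxiliary thresholds when `C_T` falls below 0.90.
#'
#' @param totalIrradiance Measured irradiance E (W m-2) over the
#'   incident-light sensor's spectral range (see [totalIrradiance()]).
#' @param geometry A [SunGeometry], or directly the sun zenith angle in
#'   degrees. The sun must be above the horizon (zenith < 90).
#' @return The dimensionless cloudiness index (at most 1; can be negative
#'   when E exceeds the clear-sky-normal value).
#' @examples
#' cloudinessIndex(500, 30)  # 1 - 500 / (1360 * cos(30 deg))
#' @export
cloudinessIndex <- function(totalIrradiance, geometry) {
  z <- if (is(geometry, "SunGeometry")) geometry@zenithDeg
       else as.numeric(geometry)
  if (length(z) != 1L || is.na(z))
    wbrfStop("geometry must give a single zenith angle", "validationError")
  if (z >= 90)
    wbrfStop(sprintf(
      "sun below horizon (zenith %.2f deg >= 90): cos z <= 0", z),
      "geometryError")
  if (totalIrradiance < 0)
    wbrfStop("totalIrradiance must be >= 0", "validationError")
  1 - as.numeric(totalIrradiance) / (SOLAR_CONSTANT * cos(z * .d2r))
}
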