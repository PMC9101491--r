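## Camera response-curve calibration: panel shots -> (DN, Hlens) points ->
## origin-constrained polynomial fit -> DN to exposure-at-lens conversion.

#' Exposure at the lens from a panel target
#'
#' For a Lambertian reference target of band reflectance rho under band
#' irradiance E, the radiance towards a nadir camera is rho E / pi, so the
#' exposure at the lens entrance over an exposure time t is
#' \deqn{H_{lens} = \rho E t / \pi.}
#' This is the known side of every calibration point.
#'
#' @param rhoBand Band-average target reflectance, in \eqn{[0, 1]}.
#' @param eBand Band-integrated incident irradiance (W m-2), >= 0.
#' @param exposureTimeS Exposure time in seconds, > 0.
#' @return Hlens in (W m-2 sr-1) s (the per-steradian factor implicit).
#' @examples
#' hlensFromPanel(1, pi, 1)  # 1
#' @export
hlensFromPanel <- function(rhoBand, eBand, exposureTimeS) {
  if (any(rhoBand < 0) || any(rhoBand > 1))
    wbrfStop("rhoBand must be in [0, 1]", "validationError")
  if (any(eBand < 0)) wbrfStop("eBand must be >= 0", "validationError")
  if (any(exposureTimeS <= 0))
    wbrfStop("exposureTimeS must be > 0", "validationError")
  rhoBand * eBand * exposureTimeS / pi
}

## A target counts as saturated when more than satFraction of its ROI pixels
## sit at the bit-depth maximum (the white target saturates under long
## exposures and must be excluded from calibration).
.targetSaturated <- function(roiPixels, dnMax, satFraction = 0.01) {
  mean(roiPixels >= dnMax) > satFraction
}

.shotTargetDN <- function(shot, target, panel) {
  if (length(shot@targetDN)) {
    if (!target %in% names(shot@targetDN)) return(NULL)
    val <- shot@targetDN[[target]]
    satur <- isTRUE(attr(shot@targetDN, "saturated")[[target]])
    return(list(dn = val, saturated = satur))
  }
  roi <- panel@rois[[target]]
  if (is.null(roi))
    wbrfStop(sprintf("no ROI configured for target '%s'", target),
             "configurationError")
  px <- shot@dn[roi[1]:roi[2], roi[3]:roi[4]]
  dnMax <- 2^shot@bitDepth - 1
  list(dn = mean(px), saturated = .targetSaturated(px, dnMax))
}

#' Calibration points from panel shots
#'
#' Builds the (DN, Hlens) point cloud a response curve is fitted to: one
#' point per shot and unsaturated target. DN is the mean over the target's
#' region of interest; Hlens comes from [hlensFromPanel()] with the
#' band-integrated target reflectance and the band-integrated incident
#' irradiance of the spectrum recorded at that shot. Points from all
#' targets are pooled, unweighted. Saturated targets (more than 1\% of ROI
#' pixels at the bit-depth maximum) are dropped with a warning; a shot with
#' all targets saturated contributes nothing.
#'
#' @param shots List of [CalibrationShot] (>= 1; a full calibration
#'   campaign uses 50 shots at distinct exposure times).
#' @param panel A [PanelSpec] with ROIs (unless shots carry per-target
#'   means).
#' @param band The [FilterBand] being calibrated.
#' @return A `data.frame(dn, hlens, target, shot)`.
#' @export
buildCalibrationPoints <- function(shots, panel, band) {
  stopifnot(is(panel, "PanelSpec"), is(band, "FilterBand"))
  if (!length(shots)) wbrfStop("no shots supplied", "calibrationError")
  rho <- vapply(panel@targets, integrateReflectanceBand, numeric(1),
                band = band)
  rows <- list()
  for (i in seq_along(shots)) {
    shot <- shots[[i]]
    eBand <- integrateBand(shot@spectrum, band)
    nKept <- 0L
    for (target in names(panel@targets)) {
      ext <- .shotTargetDN(shot, target, panel)
      if (is.null(ext)) next
      if (ext$saturated) {
        wbrfWarn(sprintf("shot %d: target '%s' saturated, excluded",
                         i, target), "saturationWarning")
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        dn = ext$dn,
        hlens = hlensFromPanel(rho[[target]], eBand, shot@exposureTimeS),
        target = target, shot = i)
      nKept <- nKept + 1L
    }
    if (nKept == 0L)
      wbrfWarn(sprintf("shot %d: all targets saturated, shot skipped", i),
               "saturationWarning")
  }
  if (!length(rows))
    wbrfStop("no usable calibration points (all targets saturated?)",
             "calibrationError")
  do.call(rbind, rows)
}

#' Fit a camera response curve
#'
#' Least-squares polynomial through the origin relating DN to Hlens. The
#' DN-intercept is imposed at 0 so that small DN values can never map to a
#' negative exposure. The fitted curve must be strictly increasing over the
#' data range; a non-monotone fit is rejected with advice to lower the
#' degree.
#'
#' @param points A `data.frame` with columns `dn` and `hlens` (from
#'   [buildCalibrationPoints()]), or a two-column matrix in that order.
#' @param band The [FilterBand] the points belong to.
#' @param degree Polynomial degree, one of 1, 2 or 3 (default 2: responses
#'   are near-linear but may curve).
#' @return A [ResponseCurve] with coefficients, fit domain and R-squared.
#' @examples
#' pts <- data.frame(dn = 0:100, hlens = 2e-4 * (0:100))
#' fitResponseCurve(pts, FilterBand(800, 10), degree = 1)
#' @export
fitResponseCurve <- function(points, band, degree = 2L) {
  stopifnot(is(band, "FilterBand"))
  if (is.matrix(points))
    points <- data.frame(dn = points[, 1], hlens = points[, 2])
  if (!all(c("dn", "hlens") %in% names(points)))
    wbrfStop("points must have columns dn and hlens", "validationError")
  degree <- as.integer(degree)
  if (!degree %in% 1:3)
    wbrfStop("degree must be 1, 2 or 3", "validationError")
  if (nrow(points) < degree)
    wbrfStop(sprintf("need at least %d points for degree %d",
                     degree, degree), "calibrationError")
  if (diff(range(points$dn)) <= 0)
    wbrfStop("DN range of points has zero span", "calibrationError")
  X <- outer(points$dn, seq_len(degree), `^`)
  fit <- stats::lm.fit(X, points$hlens)
  coefs <- unname(fit$coefficients)
  coefs[is.na(coefs)] <- 0
  fitted <- .polyEval(coefs, points$dn)
  ssRes <- sum((points$hlens - fitted)^2)
  ssTot <- sum((points$hlens - mean(points$hlens))^2)
  r2 <- if (ssTot > 0) 1 - ssRes / ssTot else NA_real_
  domain <- c(0, max(points$dn))
  grid <- seq(domain[1], domain[2], length.out = 513)
  if (any(.polyDeriv(coefs, grid) <= 0))
    wbrfStop(paste("fitted response curve is not strictly increasing over",
                   "the data range; try a lower degree"),
             "monotonicityError")
  ResponseCurve(band = band, coefficients = coefs, fitDomain = domain,
                r2 = r2, nPoints = nrow(points))
}

#' Convert DN to exposure at the lens
#'
#' Evaluates a fitted [ResponseCurve] at DN values (scalar or raster),
#' returning Hlens. DN 0 maps to exactly 0 (forced intercept). Values
#' outside the fit domain are still evaluated but flagged: the result
#' carries an `"extrapolated"` attribute with the count, and a message is
#' emitted.
#'
#' @param curve A [ResponseCurve].
#' @param dn Numeric scalar, vector or matrix of DN values (>= 0).
#' @return Hlens values with the shape of `dn`.
#' @export
invertResponse <- function(curve, dn) {
  stopifnot(is(curve, "ResponseCurve"))
  if (any(dn < 0)) wbrfStop("DN must be >= 0", "validationError")
  out <- .polyEval(curve@coefficients, dn)
  nOut <- sum(dn > curve@fitDomain[2])
  if (nOut > 0) {
    message(sprintf(
      "invertResponse: %d DN value(s) above fit domain [%g, %g], extrapolating",
      nOut, curve@fitDomain[1], curve@fitDomain[2]))
    attr(out, "extrapolated") <- nOut
  }
  out
}
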