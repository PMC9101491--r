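# Shared fixtures, built in code once per test run. The calibration of all
# six bands from a 50-shot series is the expensive part, so it is cached.

.fx <- new.env(parent = emptyenv())

fxPanel <- function() {
  if (is.null(.fx$panel)) .fx$panel <- defaultPanelSpec()
  .fx$panel
}

fxCamera <- function() {
  if (is.null(.fx$camera)) .fx$camera <- defaultCameraModel()
  .fx$camera
}

fxSpectrum <- function() {
  if (is.null(.fx$spectrum))
    .fx$spectrum <- makeSpectrum("cloudy", 40, seed = 3)
  .fx$spectrum
}

# noiseless curves fitted from a 50-shot synthetic panel series
fxCurves <- function() {
  if (is.null(.fx$curves)) {
    shots <- makeCalibrationSeries(fxPanel(), fxCamera(), fxSpectrum(),
                                   nShots = 50L, seed = 2)
    .fx$curves <- calibrateResponseCurves(shots, fxPanel())
  }
  .fx$curves
}

fxTruth <- function() {
  if (is.null(.fx$truth)) .fx$truth <- makeSceneTruth(seed = 5)
  .fx$truth
}

# a flat unit spectrum covering the band set
flatSpectrum <- function(level = 1, from = 400, to = 1000) {
  IrradianceSpectrum(seq(from, to), rep(level, to - from + 1))
}

# fine-grid trapezoid oracle for band integrals (0.01 nm resolution)
oracleBandIntegral <- function(wl, y, band) {
  r <- bandRange(band)
  g <- seq(r[1], r[2], by = 0.01)
  yy <- stats::approx(wl, y, xout = g)$y
  pracma::trapz(g, yy)
}

gembloux <- list(lat = 50 + 33 / 60 + 50 / 3600, lon = 4.7,
                 tz = "Europe/Brussels")
allDayDates2021 <- c("2021-04-13", "2021-05-28", "2021-06-10",
                     "2021-06-23", "2021-07-01", "2021-07-22")

# hand-built single-band stack from a plain BRF matrix
simpleStack <- function(m, band = mcaBands()[["800"]]) {
  stackBands(list(BRFMap(brf = m, band = band, eBand = 1,
                         saturated = matrix(FALSE, nrow(m), ncol(m)))))
}
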