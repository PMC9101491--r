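## Forward scene simulator: irradiance spectra, panel calibration series,
## organ-structured canopy acquisitions and multi-date campaigns with known
## ground truth, so the whole analysis chain is testable without field data.
##
## The forward radiometric chain is written independently of the analysis:
## DN are obtained by solving the true response polynomial for DN (closed
## form or bisection), never by evaluating a fitted curve, so round-trip
## tests are genuine.

## evaluate expr with a temporary RNG state seeded at `seed`
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## -- class reflectance templates --------------------------------------------

.pwlSpectrum <- function(wl, refl) {
  grid <- seq(min(wl), max(wl), by = 2)
  data.frame(wavelength_nm = grid,
             reflectance = stats::approx(wl, refl, xout = grid)$y)
}

#' Stock class reflectance spectra for the simulator
#'
#' Piecewise-linear reflectance templates on a 2 nm grid over
#' 400-1000 nm: a green-leaf spectrum with a red edge rising to about
#' 0.45 in the near infrared, an ear spectrum of the same shape but with
#' lower NIR plateau (about 0.35), and a nearly flat, slightly rising soil
#' spectrum around 0.15. These are simulator defaults chosen to be
#' field-plausible, not measurements of any particular crop.
#'
#' @return A `data.frame(wavelength_nm, reflectance)`.
#' @name classSpectra
#' @rdname classSpectra
NULL

#' @rdname classSpectra
#' @export
leafSpectrum <- function() .pwlSpectrum(
  c(400, 500, 550, 640, 680, 700, 750, 780, 1000),
  c(0.04, 0.06, 0.12, 0.08, 0.05, 0.12, 0.42, 0.45, 0.45))

#' @rdname classSpectra
#' @export
earSpectrum <- function() .pwlSpectrum(
  c(400, 500, 550, 640, 680, 700, 750, 780, 1000),
  c(0.07, 0.09, 0.15, 0.13, 0.11, 0.17, 0.33, 0.35, 0.35))

#' @rdname classSpectra
#' @export
soilSpectrum <- function() .pwlSpectrum(
  c(400, 700, 1000), c(0.12, 0.15, 0.18))

#' Synthetic stock reference panel
#'
#' A [PanelSpec] with four spectrally flat-ish diffuse targets (black 0.02,
#' dark gray 0.19, light gray 0.38, white 0.87 nominal reflectance, each
#' with a mild wavelength slope) and a default 24 x 24 px panel-shot layout
#' with one 10 x 10 ROI per target. Entirely synthetic: a stand-in for a
#' manufacturer-characterised panel.
#'
#' @return A [PanelSpec].
#' @export
defaultPanelSpec <- function() {
  mk <- function(level, slope) .pwlSpectrum(
    c(400, 1000), pmin(1, pmax(0, c(level - slope, level + slope))))
  PanelSpec(
    targets = list(black = mk(0.02, 0.004), dark_gray = mk(0.19, 0.01),
                   light_gray = mk(0.38, 0.015), white = mk(0.87, 0.01)),
    rois = list(black = c(2L, 11L, 2L, 11L),
                dark_gray = c(2L, 11L, 14L, 23L),
                light_gray = c(14L, 23L, 2L, 11L),
                white = c(14L, 23L, 14L, 23L)))
}

#' Stock forward camera model
#'
#' A six-band camera array model matching [mcaBands()]: each band has a
#' mildly non-linear true response `Hlens = a1 DN + a2 DN^2` through the
#' origin (a2 contributing about 15\% of the response at full scale),
#' band-to-band sensitivity differences, 10-bit depth and configurable
#' multiplicative noise.
#'
#' @param noiseSigma Multiplicative DN noise sigma (default 0, noiseless).
#' @param bitDepth Sensor bit depth (default 10).
#' @param degree 1 for strictly linear true responses, 2 (default) for the
#'   mildly curved ones.
#' @return A [CameraModel].
#' @export
defaultCameraModel <- function(noiseSigma = 0, bitDepth = 10L, degree = 2L) {
  bands <- mcaBands()
  dnMax <- 2^bitDepth - 1
  a1 <- c(`490` = 1.1e-5, `550` = 1.3e-5, `680` = 1.5e-5,
          `720` = 1.6e-5, `800` = 1.8e-5, `900` = 2.1e-5)
  coefs <- lapply(names(bands), function(nm) {
    if (degree == 1L) a1[[nm]]
    else c(a1[[nm]], 0.15 * a1[[nm]] / dnMax)
  })
  names(coefs) <- names(bands)
  CameraModel(bands = bands, trueCoefficients = coefs,
              bitDepth = as.integer(bitDepth), noiseSigma = noiseSigma,
              gain = 1)
}

## -- irradiance spectra ------------------------------------------------------

## smooth daylight-like relative spectral shape on [400, 1000] nm
.daylightShape <- function(grid, jitterAmp = 0) {
  ## broad thermal-like envelope peaking near 520 nm with a gentle NIR decay
  shape <- exp(-((grid - 520) / 350)^2) * (1 + 0.15 * sin(grid / 90))
  if (jitterAmp > 0) {
    ph <- stats::runif(3, 0, 2 * pi)
    shape <- shape * (1 + jitterAmp * (
      sin(grid / 55 + ph[1]) + 0.5 * sin(grid / 23 + ph[2]) +
        0.25 * sin(grid / 11 + ph[3])) / 1.75)
  }
  pmax(shape, 1e-6)
}

#' Simulated incident-light spectrum
#'
#' Generates a smooth, strictly positive downwelling irradiance spectrum
#' over 400-1000 nm (1 nm grid) whose full-range integral realises a sky
#' condition through the cloudiness index: `"sunny"` targets C_T = 0.25,
#' `"mixed"` 0.75 (both below the 0.90 gate, i.e. direct sunlight
#' present) and `"cloudy"` 0.96 (gate inactive). A small seeded spectral
#' jitter keeps repeated spectra distinct yet reproducible.
#'
#' @param kind `"sunny"`, `"cloudy"` or `"mixed"`.
#' @param zenithDeg Sun zenith angle in degrees (< 90).
#' @param seed Integer seed; the same seed gives a bit-identical spectrum.
#' @param timestamp Optional timezone-aware timestamp to attach.
#' @return An [IrradianceSpectrum].
#' @export
makeSpectrum <- function(kind = c("sunny", "cloudy", "mixed"),
                         zenithDeg = 40, seed = 1,
                         timestamp = .emptyTime()) {
  kind <- match.arg(kind)
  if (zenithDeg >= 90)
    wbrfStop("zenithDeg must be < 90 (sun above horizon)", "geometryError")
  ctTarget <- switch(kind, sunny = 0.25, mixed = 0.75, cloudy = 0.96)
  .withSeed(seed, {
    grid <- seq(400, 1000, by = 1)
    shape <- .daylightShape(grid, jitterAmp = 0.03)
    eTotal <- (1 - ctTarget) * SOLAR_CONSTANT * cos(zenithDeg * .d2r)
    scale <- eTotal / pracma::trapz(grid, shape)
    IrradianceSpectrum(wavelengthNm = grid, irradiance = shape * scale,
                       timestamp = timestamp)
  })
}

## -- scene truth -------------------------------------------------------------

## smooth random field in [0, 1] built from seeded low-frequency sinusoids
.smoothField <- function(nr, nc) {
  r <- matrix(seq_len(nr), nr, nc)
  c <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  f <- matrix(0, nr, nc)
  for (k in 1:4) {
    fr <- stats::runif(1, 0.5, 2.5) * 2 * pi / nr
    fc <- stats::runif(1, 0.5, 2.5) * 2 * pi / nc
    ph <- stats::runif(2, 0, 2 * pi)
    f <- f + sin(fr * r + ph[1]) * sin(fc * c + ph[2]) / k
  }
  (f - min(f)) / (max(f) - min(f))
}

#' Generate an organ-structured scene truth
#'
#' Builds a patchy canopy scene: a smooth random field thresholded to the
#' requested soil fraction gives the soil/vegetation partition, and a
#' second field carves ear blobs out of the vegetation. Class reflectance
#' spectra default to the stock templates.
#'
#' @param nrow,ncol Raster size in pixels (default 60 x 80).
#' @param soilFraction Fraction of soil pixels (default 0.35).
#' @param earFraction Fraction of all pixels that are ears (default 0.15;
#'   0 for an ear-free scene).
#' @param seed Integer seed (reproducible).
#' @param spectra Named list of class spectra (`soil`, `leaf`, `ear`).
#' @return A [SceneTruth].
#' @export
makeSceneTruth <- function(nrow = 60L, ncol = 80L, soilFraction = 0.35,
                           earFraction = 0.15, seed = 1,
                           spectra = list(soil = soilSpectrum(),
                                          leaf = leafSpectrum(),
                                          ear = earSpectrum())) {
  .withSeed(seed, {
    f1 <- .smoothField(nrow, ncol)
    labels <- matrix(ORGAN_CLASSES[["leaf"]], nrow, ncol)
    labels[f1 <= stats::quantile(f1, soilFraction)] <-
      ORGAN_CLASSES[["background"]]
    if (earFraction > 0) {
      f2 <- .smoothField(nrow, ncol)
      veg <- labels == ORGAN_CLASSES[["leaf"]]
      cut <- stats::quantile(f2[veg], 1 - earFraction / mean(veg))
      labels[veg & f2 > cut] <- ORGAN_CLASSES[["ear"]]
    }
    SceneTruth(labels = labels, spectra = spectra)
  })
}

#' Band-integrated true reflectance of a scene class
#'
#' @param truth A [SceneTruth].
#' @param class Class name (`"soil"`, `"leaf"`, `"ear"`).
#' @param band A [FilterBand].
#' @return The class's band-average reflectance.
#' @export
trueClassReflectance <- function(truth, class, band) {
  stopifnot(is(truth, "SceneTruth"))
  integrateReflectanceBand(truth@spectra[[class]], band)
}

## -- forward rendering -------------------------------------------------------

## solve a1 x + a2 x^2 (+ a3 x^3) = h for x >= 0; closed form up to degree 2,
## bisection above. Vectorised over h.
.forwardDN <- function(coefs, h) {
  d <- length(coefs)
  if (d == 1L) return(h / coefs[1])
  if (d == 2L) {
    a1 <- coefs[1]; a2 <- coefs[2]
    return((-a1 + sqrt(a1^2 + 4 * a2 * h)) / (2 * a2))
  }
  vapply(h, function(hh) {
    if (hh <= 0) return(0)
    hi <- 1
    while (.polyEval(coefs, hi) < hh) hi <- hi * 2
    stats::uniroot(function(x) .polyEval(coefs, x) - hh, c(0, hi),
                   tol = 1e-12)$root
  }, numeric(1))
}

## per-band true reflectance map of a scene
.sceneRhoMap <- function(truth, band) {
  rho <- c(soil = NA_real_, leaf = NA_real_, ear = NA_real_)
  for (nm in names(truth@spectra))
    rho[nm] <- integrateReflectanceBand(truth@spectra[[nm]], band)
  classOf <- c(`0` = "soil", `1` = "leaf", `2` = "ear")
  matrix(rho[classOf[as.character(truth@labels)]],
         nrow(truth@labels), ncol(truth@labels))
}

#' Render a multi-band acquisition of a scene
#'
#' The forward imaging model: per band, the scene radiance is
#' \eqn{L = \rho E_{band} / \pi} (Lambertian classes, optionally modulated
#' by a per-pixel illumination factor to mimic shading), the exposure at
#' the lens is \eqn{H_{lens} = L t}, and DN are obtained by solving the
#' camera's true response for DN, applying the camera gain, multiplicative
#' noise, rounding and clipping at the saturation DN.
#'
#' @param truth A [SceneTruth].
#' @param camera A [CameraModel].
#' @param spectrum An [IrradianceSpectrum] covering all bands.
#' @param exposureTimeS Exposure time in seconds.
#' @param seed Integer seed for the noise draw (ignored when the camera is
#'   noiseless).
#' @param illumination Optional per-pixel multiplicative irradiance factor
#'   (matrix of the scene shape); 1 everywhere by default. Values below 1
#'   mimic shaded pixels, which scale the radiance but not the chromatic
#'   coordinates.
#' @param timestamp Optional timestamp attached to the images.
#' @param quantize Round DN to integers and clip (default `TRUE`, the
#'   real sensor; `FALSE` models an ideal unquantized sensor for algebraic
#'   invariance checks).
#' @return Named list of [ChannelImage], one per camera band.
#' @export
renderAcquisition <- function(truth, camera, spectrum, exposureTimeS,
                              seed = 1, illumination = NULL,
                              timestamp = .emptyTime(), quantize = TRUE) {
  stopifnot(is(truth, "SceneTruth"), is(camera, "CameraModel"),
            is(spectrum, "IrradianceSpectrum"))
  if (exposureTimeS <= 0)
    wbrfStop("exposureTimeS must be > 0", "validationError")
  dnMax <- 2^camera@bitDepth - 1
  if (is.null(illumination))
    illumination <- matrix(1, nrow(truth@labels), ncol(truth@labels))
  .withSeed(seed, {
    out <- lapply(names(camera@bands), function(nm) {
      band <- camera@bands[[nm]]
      eBand <- integrateBand(spectrum, band)
      rho <- .sceneRhoMap(truth, band)
      hlens <- camera@gain * rho * illumination * eBand *
        exposureTimeS / pi
      dnReal <- .forwardDN(camera@trueCoefficients[[nm]], hlens)
      if (camera@noiseSigma > 0)
        dnReal <- dnReal * (1 + stats::rnorm(length(dnReal), 0,
                                             camera@noiseSigma))
      if (quantize) dnReal <- round(dnReal)
      dnI <- matrix(pmin(dnMax, pmax(0, dnReal)),
                    nrow(rho), ncol(rho))
      ChannelImage(dn = dnI, band = band, exposureTimeS = exposureTimeS,
                   bitDepth = camera@bitDepth, timestamp = timestamp)
    })
    names(out) <- names(camera@bands)
    out
  })
}

#' Chromatic red/green coordinates of a scene
#'
#' Renders broad-band red, green and blue radiances of the scene from the
#' class spectra and the incident spectrum (band windows 600-680, 500-580
#' and 420-500 nm) and returns the chromatic coordinates r = R/(R+G+B) and
#' g = G/(R+G+B), which are illumination-invariant: shading cancels in the
#' ratio. These feed the Excess-Red auxiliary test.
#'
#' @param truth A [SceneTruth].
#' @param spectrum An [IrradianceSpectrum].
#' @return List with matrices `r` and `g`.
#' @export
renderChromatic <- function(truth, spectrum) {
  bb <- list(R = FilterBand(640, 80, "R"), G = FilterBand(540, 80, "G"),
             B = FilterBand(460, 80, "B"))
  rad <- lapply(bb, function(b)
    .sceneRhoMap(truth, b) * integrateBand(spectrum, b))
  tot <- rad$R + rad$G + rad$B
  list(r = rad$R / tot, g = rad$G / tot)
}

## -- calibration series ------------------------------------------------------

#' Simulate a panel calibration series
#'
#' Renders `nShots` panel images per band at distinct, log-spaced exposure
#' times over `exposureRange`, each with the supplied incident spectrum.
#' With `saturateWhite = TRUE` the exposure range is stretched so the white
#' target clips at the sensor maximum in the longest exposures, exercising
#' the saturation-exclusion path of the calibration.
#'
#' @param panel A [PanelSpec] with ROIs.
#' @param camera A [CameraModel].
#' @param spectrum An [IrradianceSpectrum].
#' @param nShots Number of shots (default 50, a full campaign).
#' @param exposureRange `c(min, max)` exposure times in seconds.
#' @param seed Integer seed for the noise draws.
#' @param saturateWhite Force white-target saturation at long exposures.
#' @param quantize Round DN to integers. Default: only when the camera has
#'   noise. The noiseless calibration series models an idealized sensor
#'   without quantization, so that zero-noise parameter recovery is exact;
#'   quantization is part of the noise budget otherwise.
#' @return Named list (by band label) of lists of [CalibrationShot].
#' @export
makeCalibrationSeries <- function(panel, camera, spectrum, nShots = 50L,
                                  exposureRange = c(0.001, 0.02), seed = 1,
                                  saturateWhite = FALSE, quantize = NULL) {
  stopifnot(is(panel, "PanelSpec"), is(camera, "CameraModel"))
  if (any(exposureRange <= 0) || exposureRange[1] >= exposureRange[2])
    wbrfStop("exposureRange must be positive and increasing",
             "validationError")
  if (is.null(quantize)) quantize <- camera@noiseSigma > 0
  dnMax <- 2^camera@bitDepth - 1
  times <- exp(seq(log(exposureRange[1]), log(exposureRange[2]),
                   length.out = nShots))
  rois <- panel@rois
  canvas <- c(max(vapply(rois, `[`, integer(1), 2L)) + 1L,
              max(vapply(rois, `[`, integer(1), 4L)) + 1L)
  if (saturateWhite) {
    ## stretch so the white target's noiseless DN tops out ~40% over range
    b800 <- camera@bands[[1]]
    eB <- integrateBand(spectrum, b800)
    rhoW <- integrateReflectanceBand(panel@targets$white, b800)
    cf <- camera@trueCoefficients[[1]]
    hSat <- .polyEval(cf, dnMax)
    tSat <- hSat * pi / (camera@gain * rhoW * eB)
    times <- exp(seq(log(exposureRange[1]), log(1.4 * tSat),
                     length.out = nShots))
  }
  .withSeed(seed, {
    out <- lapply(names(camera@bands), function(nm) {
      band <- camera@bands[[nm]]
      eBand <- integrateBand(spectrum, band)
      cf <- camera@trueCoefficients[[nm]]
      lapply(seq_len(nShots), function(i) {
        img <- matrix(0, canvas[1], canvas[2])
        for (tg in names(rois)) {
          rho <- integrateReflectanceBand(panel@targets[[tg]], band)
          hl <- camera@gain * rho * eBand * times[i] / pi
          roi <- rois[[tg]]
          npx <- (roi[2] - roi[1] + 1L) * (roi[4] - roi[3] + 1L)
          dnReal <- rep(.forwardDN(cf, hl), npx)
          if (camera@noiseSigma > 0)
            dnReal <- dnReal * (1 + stats::rnorm(npx, 0,
                                                 camera@noiseSigma))
          if (quantize) dnReal <- round(dnReal)
          img[roi[1]:roi[2], roi[3]:roi[4]] <-
            pmin(dnMax, pmax(0, dnReal))
        }
        CalibrationShot(dn = img, exposureTimeS = times[i],
                        spectrum = spectrum,
                        bitDepth = camera@bitDepth)
      })
    })
    names(out) <- names(camera@bands)
    out
  })
}

## -- full campaign -----------------------------------------------------------

#' Simulate a multi-date campaign with inter-date drift
#'
#' For each date: a begin panel shot, `nCanopy` canopy acquisitions of the
#' scene, and an end panel shot, all rendered under that date's radiometric
#' gain drift (a multiplicative factor on the exposure seen by the sensor,
#' mimicking session-to-session changes in the acquisition configuration).
#' The drift-free truth is known, so the inter-date panel correction can be
#' validated against it.
#'
#' @param dates Character or `Date` vector of session dates.
#' @param driftFactors Numeric vector, one gain factor per date.
#' @param truth A [SceneTruth] (same scene every date by default).
#' @param camera Base [CameraModel] (gain 1).
#' @param panel A [PanelSpec] with ROIs.
#' @param spectrumKind Sky condition for all dates (default `"cloudy"`).
#' @param exposureTimeS Canopy exposure time (panel shots use half of it).
#' @param nCanopy Canopy acquisitions per date (default 1).
#' @param seed Integer seed; everything derived from it is reproducible.
#' @return A list with elements `dates`, `driftFactors`, `truth`, `panel`,
#'   and `sessions` — one element per date holding `spectrum`,
#'   `panelBegin`, `panelEnd` (per-band [CalibrationShot]) and `canopy`
#'   (list of per-band [ChannelImage] sets).
#' @export
makeSeason <- function(dates, driftFactors, truth, camera = NULL,
                       panel = defaultPanelSpec(),
                       spectrumKind = "cloudy", exposureTimeS = 0.1,
                       nCanopy = 1L, seed = 1) {
  if (length(driftFactors) != length(dates))
    wbrfStop("need one drift factor per date", "validationError")
  if (is.null(camera)) camera <- defaultCameraModel()
  sessions <- vector("list", length(dates))
  names(sessions) <- as.character(dates)
  for (i in seq_along(dates)) {
    cam <- camera
    cam@gain <- camera@gain * driftFactors[i]
    spec <- makeSpectrum(spectrumKind, zenithDeg = 40,
                         seed = seed * 1000L + i)
    panelShot <- function(off)
      lapply(makeCalibrationSeries(panel, cam, spec, nShots = 1L,
                                   exposureRange = c(exposureTimeS / 2,
                                                     exposureTimeS),
                                   seed = seed * 1000L + i + off,
                                   quantize = TRUE),
             `[[`, 1L)
    canopy <- lapply(seq_len(nCanopy), function(k)
      renderAcquisition(truth, cam, spec, exposureTimeS,
                        seed = seed * 1000L + i + 500L + k))
    sessions[[i]] <- list(spectrum = spec, panelBegin = panelShot(100L),
                          canopy = canopy, panelEnd = panelShot(200L))
  }
  list(dates = as.character(dates), driftFactors = driftFactors,
       truth = truth, panel = panel, sessions = sessions)
}
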