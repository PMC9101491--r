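# Channel blur, DN-to-BRF conversion, band stacking.

test_that("5x5 mean blur matches a direct convolution oracle", {
  # constant raster unchanged
  cst <- matrix(0.7, 8, 9)
  expect_equal(blurChannel(cst), cst)
  # centered impulse of 25 spreads to a 5x5 patch of ones
  imp <- matrix(0, 11, 11); imp[6, 6] <- 25
  out <- blurChannel(imp)
  expected <- matrix(0, 11, 11); expected[4:8, 4:8] <- 1
  expect_equal(out, expected)
  # affine ramp: interior unchanged (symmetric window on an affine field)
  ramp <- outer(1:12, 1:15, function(i, j) 2 * i + 3 * j - 4)
  br <- blurChannel(ramp)
  expect_equal(br[3:10, 3:13], ramp[3:10, 3:13])
  # direct 5x5 convolution oracle on a random interior
  set.seed(9)
  m <- matrix(runif(20 * 16), 20, 16)
  bm <- blurChannel(m)
  for (k in 1:5) {
    i <- sample(3:18, 1); j <- sample(3:14, 1)
    expect_equal(bm[i, j], mean(m[(i - 2):(i + 2), (j - 2):(j + 2)]))
  }
  expect_error(blurChannel(matrix(0, 4, 10)), class = "validationError")
})

test_that("an algebraically exact chain recovers uniform reflectance to 1e-6", {
  band <- mcaBands()[["800"]]
  spec <- flatSpectrum(0.8)
  eBand <- integrateBand(spec, band)
  a <- 1.8e-5
  curve <- ResponseCurve(band = band, coefficients = a,
                         fitDomain = c(0, 1023))
  rho <- 0.45; t <- 0.01
  dnVal <- rho * eBand * t / pi / a       # forward model, unquantized
  img <- ChannelImage(dn = matrix(dnVal, 10, 12), band = band,
                      exposureTimeS = t)
  map <- dnToBrf(img, curve, spec)
  expect_lt(max(abs(brf(map) / rho - 1)), 1e-6)
})

test_that("simulator round trip recovers the scene within 1% noiseless", {
  truth <- fxTruth()
  imgs <- renderAcquisition(truth, fxCamera(), fxSpectrum(), 0.1,
                            seed = 7)
  for (bl in c("490", "800")) {
    map <- dnToBrf(imgs[[bl]], fxCurves()[[bl]], fxSpectrum())
    for (cls in c("soil", "leaf", "ear")) {
      code <- ORGAN_CLASSES[[c(soil = "background", leaf = "leaf",
                               ear = "ear")[[cls]]]]
      sel <- labelRaster(truth) == code
      tr <- trueClassReflectance(truth, cls, mcaBands()[[bl]])
      expect_lt(abs(mean(brf(map)[sel]) / tr - 1), 0.01)
    }
  }
})

test_that("zero DN maps to zero BRF and degenerate inputs error", {
  band <- mcaBands()[["550"]]
  curve <- fxCurves()[["550"]]
  img <- ChannelImage(dn = matrix(0, 6, 6), band = band,
                      exposureTimeS = 0.01)
  expect_true(all(brf(dnToBrf(img, curve, fxSpectrum())) == 0))
  # dark spectrum: zero band irradiance is a division error
  dark <- IrradianceSpectrum(400:1000, rep(0, 601))
  expect_error(dnToBrf(img, curve, dark), class = "divisionError")
  # band mismatch between image and curve
  expect_error(dnToBrf(img, fxCurves()[["800"]], fxSpectrum()),
               class = "validationError")
})

test_that("a rendered dark-gray panel patch reads back its reflectance", {
  truth <- SceneTruth(labels = matrix(ORGAN_CLASSES[["leaf"]], 8, 8),
                      spectra = list(soil = soilSpectrum(),
                                     leaf = fxPanel()@targets$dark_gray))
  imgs <- renderAcquisition(truth, fxCamera(), fxSpectrum(), 0.1,
                            seed = 1, quantize = FALSE)
  for (bl in c("550", "800")) {
    map <- dnToBrf(imgs[[bl]], fxCurves()[[bl]], fxSpectrum())
    rhoTheo <- integrateReflectanceBand(fxPanel()@targets$dark_gray,
                                        mcaBands()[[bl]])
    expect_lt(abs(mean(brf(map)) / rhoTheo - 1), 0.01)
  }
})

test_that("BRF is bit-invariant to exposure doubling and spectrum scaling", {
  cam <- defaultCameraModel(degree = 1L)
  truth <- fxTruth()
  spec <- fxSpectrum()
  spec2 <- IrradianceSpectrum(wavelengths(spec), 2 * irradiance(spec))
  # curve fitted on the same linear camera, so conversion matches render
  shots <- makeCalibrationSeries(fxPanel(), cam, spec, nShots = 20L,
                                 seed = 2)
  curves <- list(`800` = fitResponseCurve(
    buildCalibrationPoints(shots[["800"]], fxPanel(), mcaBands()[["800"]]),
    mcaBands()[["800"]], 1))
  render <- function(s, t) renderAcquisition(truth, cam, s, t, seed = 1,
                                             quantize = FALSE)
  base <- dnToBrf(render(spec, 0.05)[["800"]], curves[["800"]], spec)
  dblT <- dnToBrf(render(spec, 0.10)[["800"]], curves[["800"]], spec)
  dblE <- dnToBrf(render(spec2, 0.05)[["800"]], curves[["800"]], spec2)
  expect_identical(brf(base), brf(dblT))
  expect_identical(brf(base), brf(dblE))
})

test_that("with quantization, exposure invariance holds to rounding error", {
  truth <- fxTruth()
  imgs1 <- renderAcquisition(truth, fxCamera(), fxSpectrum(), 0.05,
                             seed = 1)
  imgs2 <- renderAcquisition(truth, fxCamera(), fxSpectrum(), 0.10,
                             seed = 1)
  b1 <- brf(dnToBrf(imgs1[["800"]], fxCurves()[["800"]], fxSpectrum()))
  b2 <- brf(dnToBrf(imgs2[["800"]], fxCurves()[["800"]], fxSpectrum()))
  expect_lt(max(abs(b1 - b2) / b1), 0.02)
})

test_that("saturated pixels are masked in the BRF map", {
  band <- mcaBands()[["800"]]
  dn <- matrix(500, 6, 6); dn[1, 1] <- 1023
  img <- ChannelImage(dn = dn, band = band, exposureTimeS = 0.01,
                      bitDepth = 10L)
  map <- suppressWarnings(dnToBrf(img, fxCurves()[["800"]], fxSpectrum()))
  expect_true(saturationMask(map)[1, 1])
  expect_equal(sum(saturationMask(map)), 1L)
})

test_that("stacking orders bands and enforces registration", {
  spec <- fxSpectrum()
  truth <- fxTruth()
  imgs <- renderAcquisition(truth, fxCamera(), spec, 0.1, seed = 7)
  maps <- lapply(rev(names(imgs)), function(bl)
    dnToBrf(imgs[[bl]], fxCurves()[[bl]], spec))
  st <- stackBands(maps)    # given in descending order on purpose
  expect_equal(names(st), c("490", "550", "680", "720", "800", "900"))
  expect_equal(length(st), 6L)
  expect_s4_class(st[["800"]], "BRFMap")

  one <- stackBands(maps[1])
  expect_equal(length(one), 1L)
  # duplicate band labels rejected
  expect_error(stackBands(list(maps[[1]], maps[[1]])),
               class = "validationError")
  # shape mismatch is a registration error
  small <- BRFMap(brf = matrix(0.2, 3, 3), band = mcaBands()[["490"]],
                  eBand = 1, saturated = matrix(FALSE, 3, 3))
  expect_error(stackBands(list(small, maps[[1]])),
               class = "registrationError")
})

test_that("implausibly high BRF triggers the soft warning", {
  expect_warning(
    BRFMap(brf = matrix(2, 3, 3), band = mcaBands()[["490"]], eBand = 1,
           saturated = matrix(FALSE, 3, 3)),
    class = "implausibleBRFWarning")
})
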