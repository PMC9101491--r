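# Forward simulator: spectra, scene rendering, calibration series and
# multi-date campaigns.

test_that("simulated spectra realise their sky condition and are seeded", {
  sunny <- makeSpectrum("sunny", 30, seed = 5)
  cloudy <- makeSpectrum("cloudy", 30, seed = 5)
  mixed <- makeSpectrum("mixed", 30, seed = 5)
  ctOf <- function(s) cloudinessIndex(totalIrradiance(s), 30)
  expect_lt(ctOf(sunny), 0.90)
  expect_gte(ctOf(cloudy), 0.90)
  expect_lt(ctOf(mixed), 0.90)
  expect_gt(ctOf(mixed), ctOf(sunny))
  # determinism and coverage
  again <- makeSpectrum("sunny", 30, seed = 5)
  expect_identical(irradiance(sunny), irradiance(again))
  expect_false(identical(irradiance(sunny),
                         irradiance(makeSpectrum("sunny", 30, seed = 6))))
  expect_true(all(irradiance(sunny) > 0))
  expect_lte(min(wavelengths(sunny)), 480)
  expect_gte(max(wavelengths(sunny)), 910)
  expect_error(makeSpectrum("sunny", 95), class = "geometryError")
})

test_that("rendering follows the forward radiometric model", {
  dark <- SceneTruth(labels = matrix(ORGAN_CLASSES[["leaf"]], 5, 5),
                     spectra = list(
                       soil = soilSpectrum(),
                       leaf = data.frame(wavelength_nm = c(400, 1000),
                                         reflectance = c(0, 0))))
  imgs <- renderAcquisition(dark, fxCamera(), fxSpectrum(), 0.01)
  expect_true(all(dn(imgs[["800"]]) == 0))

  # doubling exposure doubles DN for a linear response (unquantized)
  cam1 <- defaultCameraModel(degree = 1L)
  truth <- fxTruth()
  i1 <- renderAcquisition(truth, cam1, fxSpectrum(), 0.02,
                          quantize = FALSE)
  i2 <- renderAcquisition(truth, cam1, fxSpectrum(), 0.04,
                          quantize = FALSE)
  expect_equal(dn(i2[["800"]]), 2 * dn(i1[["800"]]), tolerance = 1e-12)

  # saturation clips at the bit-depth maximum
  iSat <- renderAcquisition(truth, cam1, fxSpectrum(), 10, seed = 1)
  expect_equal(max(dn(iSat[["800"]])), 2^cam1@bitDepth - 1)
})

test_that("seeded rendering is bit-identical and noise respects the seed", {
  cam <- defaultCameraModel(noiseSigma = 0.01)
  truth <- fxTruth()
  a <- renderAcquisition(truth, cam, fxSpectrum(), 0.1, seed = 17)
  b <- renderAcquisition(truth, cam, fxSpectrum(), 0.1, seed = 17)
  expect_identical(lapply(a, dn), lapply(b, dn))
  c2 <- renderAcquisition(truth, cam, fxSpectrum(), 0.1, seed = 18)
  expect_false(identical(dn(a[["800"]]), dn(c2[["800"]])))
})

test_that("calibration series have distinct exposures and recover the
           camera", {
  shots <- makeCalibrationSeries(fxPanel(), fxCamera(), fxSpectrum(),
                                 nShots = 50L, seed = 2)
  expect_equal(length(shots[["800"]]), 50L)
  times <- vapply(shots[["800"]], exposureTime, numeric(1))
  expect_equal(length(unique(times)), 50L)
  one <- makeCalibrationSeries(fxPanel(), fxCamera(), fxSpectrum(),
                               nShots = 1L, seed = 2)
  expect_equal(length(one[["550"]]), 1L)
  # fitted curve reproduces the true one
  for (bl in c("490", "900")) {
    fit <- fitResponseCurve(
      buildCalibrationPoints(shots[[bl]], fxPanel(), mcaBands()[[bl]]),
      mcaBands()[[bl]], 2)
    expect_gte(rSquared(fit), 0.999)
    expect_equal(curveCoefficients(fit),
                 fxCamera()@trueCoefficients[[bl]], tolerance = 1e-6)
  }
})

test_that("scene truths partition the raster and respect fractions", {
  for (seed in 1:3) {
    truth <- makeSceneTruth(nrow = 40, ncol = 50, soilFraction = 0.3,
                            earFraction = 0.1, seed = seed)
    lab <- labelRaster(truth)
    expect_equal(dim(lab), c(40L, 50L))
    expect_true(all(lab %in% 0:2))
    expect_equal(mean(lab == 0), 0.3, tolerance = 0.05)
    expect_equal(mean(lab == 2), 0.1, tolerance = 0.05)
  }
  expect_identical(labelRaster(makeSceneTruth(seed = 4)),
                   labelRaster(makeSceneTruth(seed = 4)))
})

test_that("a unit-drift season leaves correction a no-op", {
  truth <- fxTruth()
  season <- makeSeason(c("2021-05-01", "2021-06-01"), c(1, 1), truth,
                       fxCamera(), fxPanel(), seed = 3)
  un <- processSeason(season, fxCurves(), correct = FALSE)
  co <- processSeason(season, fxCurves(), correct = TRUE)
  expect_equal(co$mean_brf, co$mean_brf_raw * co$correction_factor)
  expect_equal(co$mean_brf_raw, un$mean_brf)
  # factors are ~1: no drift to remove (within panel measurement error)
  expect_lt(max(abs(co$correction_factor - 1)), 0.01)
  # a 10% drift on one date shows as a spike, removed by correction
  season2 <- makeSeason(c("2021-05-01", "2021-06-01"), c(1, 1.1), truth,
                        fxCamera(), fxPanel(), seed = 3)
  un2 <- processSeason(season2, fxCurves(), correct = FALSE)
  co2 <- processSeason(season2, fxCurves(), correct = TRUE)
  leafU <- un2$mean_brf[un2$organ == "leaf" & un2$band == "800"]
  leafC <- co2$mean_brf[co2$organ == "leaf" & co2$band == "800"]
  expect_gt(leafU[2] / leafU[1], 1.08)
  # residual is panel-shot DN quantization, well under the 1% drift bound
  expect_lt(abs(leafC[2] / leafC[1] - 1), 0.01)
})

test_that("season regeneration under the same seed is bit-identical", {
  truth <- fxTruth()
  s1 <- makeSeason("2021-06-01", 1.05, truth, fxCamera(), fxPanel(),
                   seed = 8)
  s2 <- makeSeason("2021-06-01", 1.05, truth, fxCamera(), fxPanel(),
                   seed = 8)
  expect_identical(dn(s1$sessions[[1]]$canopy[[1]][["800"]]),
                   dn(s2$sessions[[1]]$canopy[[1]][["800"]]))
  expect_identical(s1$sessions[[1]]$panelBegin[["490"]]@dn,
                   s2$sessions[[1]]$panelBegin[["490"]]@dn)
})
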