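# Valley thresholding, Excess Red, the cloudiness-gated background
# segmentation, ear-mask application and organ pooling.

test_that("valley threshold separates two well-separated Gaussian modes", {
  set.seed(21)
  soil <- rnorm(4000, 30, 5)
  canopy <- rnorm(6000, 180, 5)
  thr <- firstLocalMinimumThreshold(c(soil, canopy))
  expect_gt(thr, 45); expect_lt(thr, 165)
  acc <- (sum(soil < thr) + sum(canopy > thr)) / 10000
  expect_gte(acc, 0.999)
})

test_that("unimodal histograms yield a no-valley signal", {
  set.seed(22)
  expect_error(firstLocalMinimumThreshold(rnorm(5000, 100, 10)),
               class = "noValleyError")
  expect_error(firstLocalMinimumThreshold(rep(7, 100)),
               class = "noValleyError")
})

test_that("two spikes with an empty valley give a threshold between them", {
  vals <- c(rep(10, 500), rep(200, 700))
  thr <- firstLocalMinimumThreshold(vals)
  expect_gt(thr, 10); expect_lt(thr, 200)
})

test_that("Excess Red follows 1.4 r - g", {
  expect_equal(excessRed(0, 0), 0)
  expect_equal(excessRed(0.5, 0.3), 0.4)
  expect_equal(excessRed(0, 1), -1)
  r <- matrix(runif(12), 3, 4)
  g <- matrix(runif(12), 3, 4)
  expect_equal(excessRed(r, g), 1.4 * r - g)
  expect_error(excessRed(matrix(0, 2, 2), matrix(0, 3, 3)),
               class = "validationError")
})

test_that("under diffuse sky the mask equals pure NIR thresholding", {
  truth <- fxTruth()
  imgs <- renderAcquisition(truth, defaultCameraModel(noiseSigma = 0.01),
                            fxSpectrum(), 0.1, seed = 13)
  nir <- dn(imgs[["800"]])
  mask <- segmentBackground(nir, cloudiness = 0.96)   # gate inactive
  thr <- firstLocalMinimumThreshold(as.vector(nir))
  expect_equal(mask, nir > as.numeric(thr), ignore_attr = TRUE)
  expect_false(attr(mask, "provenance")$gateActive)
  acc <- mean(mask == (labelRaster(truth) > 0))
  expect_gte(acc, 0.99)
})

test_that("the sunlit-soil scene needs and gets the auxiliary thresholds", {
  # Sunlit soil matches shaded leaves in NIR radiance; blue and ExR
  # disambiguate. Illumination: sun patches at 1, shade at 0.33.
  truth <- makeSceneTruth(seed = 31, earFraction = 0)
  sunny <- makeSpectrum("sunny", 35, seed = 31)
  shade <- matrix(1, 60, 80)
  shade[, 1:40] <- 0.33          # left half shaded (soil and leaves alike)
  cam <- defaultCameraModel(noiseSigma = 0.005)
  imgs <- renderAcquisition(truth, cam, sunny, 0.006, seed = 32,
                            illumination = shade)
  chrom <- renderChromatic(truth, sunny)
  ct <- cloudinessIndex(totalIrradiance(sunny), 35)
  expect_lt(ct, 0.90)
  cfg <- SegmentationConfig(blueThreshold = 280, exrThreshold = 0.10)
  maskAux <- segmentBackground(dn(imgs[["800"]]), blue = dn(imgs[["490"]]),
                               red = chrom$r, green = chrom$g,
                               cloudiness = ct, config = cfg)
  accAux <- mean(maskAux == (labelRaster(truth) > 0))
  expect_gte(accAux, 0.99)
  expect_true(attr(maskAux, "provenance")$gateActive)
  expect_gt(attr(maskAux, "provenance")$auxRejected, 0)
  # without the gate, sunlit soil pollutes the vegetation mask
  maskNir <- segmentBackground(dn(imgs[["800"]]), cloudiness = 0.96,
                               config = cfg)
  expect_lt(mean(maskNir == (labelRaster(truth) > 0)), accAux)
})

test_that("the gate can only remove soil-like pixels, never add any", {
  truth <- makeSceneTruth(seed = 31, earFraction = 0)
  sunny <- makeSpectrum("sunny", 35, seed = 31)
  shade <- matrix(1, 60, 80); shade[, 1:40] <- 0.33
  imgs <- renderAcquisition(truth, defaultCameraModel(), sunny, 0.006,
                            seed = 33, illumination = shade)
  chrom <- renderChromatic(truth, sunny)
  ct <- cloudinessIndex(totalIrradiance(sunny), 35)
  cfg <- SegmentationConfig(blueThreshold = 280, exrThreshold = 0.10)
  args <- list(dn(imgs[["800"]]), blue = dn(imgs[["490"]]),
               red = chrom$r, green = chrom$g, config = cfg)
  gated <- do.call(segmentBackground, c(args, cloudiness = ct))
  ungated <- do.call(segmentBackground, c(args, cloudiness = 0.99))
  expect_true(all(ungated[gated]))     # gated mask is a subset
  # true vegetation survives the auxiliary tests
  veg <- labelRaster(truth) > 0
  expect_equal(sum(gated & veg), sum(ungated & veg))
})

test_that("gate firing requires the auxiliary channels", {
  truth <- fxTruth()
  imgs <- renderAcquisition(truth, fxCamera(), fxSpectrum(), 0.1,
                            seed = 7)
  expect_error(segmentBackground(dn(imgs[["800"]]), cloudiness = 0.2),
               class = "configurationError")
})

test_that("an all-vegetation scene falls back to Otsu with a warning", {
  allVeg <- SceneTruth(labels = matrix(ORGAN_CLASSES[["leaf"]], 30, 30),
                       spectra = list(soil = soilSpectrum(),
                                      leaf = leafSpectrum()))
  imgs <- renderAcquisition(allVeg, defaultCameraModel(noiseSigma = 0.01),
                            fxSpectrum(), 0.1, seed = 41)
  expect_warning(mask <- segmentBackground(dn(imgs[["800"]]),
                                           cloudiness = 0.96),
                 class = "fallbackWarning")
  expect_equal(attr(mask, "provenance")$fallback, "otsu")
  expect_gt(mean(mask), 0.4)   # no crash, a usable mask
})

test_that("ear-mask combination follows the set algebra", {
  veg <- matrix(c(TRUE, TRUE, FALSE, FALSE,
                  TRUE, TRUE, FALSE, FALSE), 2, 4, byrow = TRUE)
  # empty ear mask: two-class map
  lm0 <- applyEarMask(veg, NULL)
  expect_setequal(unique(as.vector(labelRaster(lm0))), c(0L, 1L))
  # ear strictly inside vegetation: count preserved
  ear <- matrix(FALSE, 2, 4); ear[1, 1] <- TRUE
  lm1 <- applyEarMask(veg, ear)
  expect_equal(sum(labelRaster(lm1) == ORGAN_CLASSES[["ear"]]), 1L)
  # ear overlapping background stays background
  ear2 <- matrix(FALSE, 2, 4); ear2[1, 3] <- TRUE; ear2[1, 1] <- TRUE
  lm2 <- applyEarMask(veg, ear2)
  expect_equal(labelRaster(lm2)[1, 3], ORGAN_CLASSES[["background"]])
  expect_equal(sum(labelRaster(lm2) == ORGAN_CLASSES[["ear"]]), 1L)
  # ear mask with zero vegetation overlap is suspicious
  earBad <- matrix(FALSE, 2, 4); earBad[1, 3] <- TRUE
  expect_warning(applyEarMask(veg, earBad), class = "registrationWarning")
  expect_error(applyEarMask(veg, matrix(FALSE, 3, 3)),
               class = "validationError")
})

test_that("class counts always partition the image", {
  for (seed in 1:3) {
    truth <- makeSceneTruth(seed = seed)
    imgs <- renderAcquisition(truth, defaultCameraModel(noiseSigma = 0.01),
                              fxSpectrum(), 0.1, seed = seed)
    mask <- segmentBackground(dn(imgs[["800"]]), cloudiness = 0.96)
    lm <- applyEarMask(mask, labelRaster(truth) == ORGAN_CLASSES[["ear"]])
    counts <- table(factor(labelRaster(lm), levels = 0:2))
    expect_equal(sum(counts), length(labelRaster(lm)))
    # and the segmentation is accurate under 6-sigma class separation
    expect_gte(mean(labelRaster(lm) == labelRaster(truth)), 0.99)
  }
})

test_that("organ means pool unsaturated pixels and report counts", {
  m <- matrix(0.2, 4, 4)
  m[1, 1] <- 0.4; m[1, 2] <- 0.6
  labels <- matrix(ORGAN_CLASSES[["background"]], 4, 4)
  labels[1, 1:2] <- ORGAN_CLASSES[["leaf"]]
  lm <- LabelMap(labels = labels)
  rec <- organMeanBrf(simpleStack(m), lm, "leaf")
  expect_equal(rec$mean_brf, 0.5)
  expect_equal(rec$n_pixels, 2L)
  # uniform leaf value comes back exactly
  lmAll <- LabelMap(labels = matrix(ORGAN_CLASSES[["leaf"]], 4, 4))
  expect_equal(organMeanBrf(simpleStack(matrix(0.45, 4, 4)),
                            lmAll, "leaf")$mean_brf, 0.45)
  # empty class is an explicit signal, not NaN
  expect_error(organMeanBrf(simpleStack(m), lm, "ear"),
               class = "emptyClassError")
  # saturated pixels are excluded from the mean
  sat <- matrix(FALSE, 4, 4); sat[1, 2] <- TRUE
  st <- stackBands(list(BRFMap(brf = m, band = mcaBands()[["800"]],
                               eBand = 1, saturated = sat)))
  expect_equal(organMeanBrf(st, lm, "leaf")$mean_brf, 0.4)
})

test_that("leaf and ear means conserve the vegetation mean", {
  truth <- fxTruth()
  imgs <- renderAcquisition(truth, fxCamera(), fxSpectrum(), 0.1, seed = 7)
  maps <- lapply(names(imgs), function(bl)
    dnToBrf(imgs[[bl]], fxCurves()[[bl]], fxSpectrum()))
  st <- stackBands(maps)
  mask <- segmentBackground(dn(imgs[["800"]]), cloudiness = 0.96)
  lm <- applyEarMask(mask, labelRaster(truth) == ORGAN_CLASSES[["ear"]])
  leaf <- organMeanBrf(st, lm, "leaf")
  ear <- organMeanBrf(st, lm, "ear")
  for (k in seq_len(nrow(leaf))) {
    vegMean <- (leaf$mean_brf[k] * leaf$n_pixels[k] +
                  ear$mean_brf[k] * ear$n_pixels[k]) /
      (leaf$n_pixels[k] + ear$n_pixels[k])
    sel <- labelRaster(lm) > 0
    expect_equal(vegMean, mean(brf(st[[leaf$band[k]]])[sel]),
                 tolerance = 1e-12)
  }
})

test_that("segmentation accuracy holds at 6-sigma NIR separation across seeds", {
  for (seed in 4:6) {
    truth <- makeSceneTruth(seed = seed, earFraction = 0)
    # 1% multiplicative noise: class DN separation is far above 6 sigma
    imgs <- renderAcquisition(truth, defaultCameraModel(noiseSigma = 0.01),
                              fxSpectrum(), 0.1, seed = seed + 100)
    mask <- segmentBackground(dn(imgs[["800"]]), cloudiness = 0.96)
    expect_gte(mean(mask == (labelRaster(truth) > 0)), 0.99)
  }
})
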