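# Response-curve calibration: Hlens arithmetic, point building, fitting,
# and DN-to-exposure conversion.

test_that("panel Hlens follows rho E t / pi", {
  expect_equal(hlensFromPanel(1, pi, 1), 1)
  expect_equal(hlensFromPanel(0, 123, 0.5), 0)
  expect_equal(hlensFromPanel(0.19, 300, 0.01), 0.19 * 300 * 0.01 / pi)
  expect_error(hlensFromPanel(-0.1, 1, 1), class = "validationError")
  expect_error(hlensFromPanel(0.2, -1, 1), class = "validationError")
  expect_error(hlensFromPanel(0.2, 1, 0), class = "validationError")
})

test_that("a 50-shot, 4-target series yields 200 calibration points", {
  shots <- makeCalibrationSeries(fxPanel(), fxCamera(), fxSpectrum(),
                                 nShots = 50L, seed = 2)
  pts <- buildCalibrationPoints(shots[["800"]], fxPanel(),
                                mcaBands()[["800"]])
  expect_equal(nrow(pts), 200L)
  expect_setequal(unique(pts$target),
                  c("black", "dark_gray", "light_gray", "white"))
})

test_that("saturated white targets are excluded from the point cloud", {
  shots <- makeCalibrationSeries(fxPanel(), fxCamera(), fxSpectrum(),
                                 nShots = 12L, seed = 2,
                                 saturateWhite = TRUE)
  pts <- suppressWarnings(buildCalibrationPoints(shots[["490"]], fxPanel(),
                                                 mcaBands()[["490"]]))
  expect_warning(buildCalibrationPoints(shots[["490"]], fxPanel(),
                                        mcaBands()[["490"]]),
                 class = "saturationWarning")
  nWhite <- sum(pts$target == "white")
  expect_lt(nWhite, 12L)                 # some shots lost the white target
  expect_equal(sum(pts$target == "black"), 12L)
  dnMax <- 2^fxCamera()@bitDepth - 1
  expect_true(all(pts$dn < dnMax))
})

test_that("a single shot with per-target means yields a single point", {
  shot <- CalibrationShot(targetDN = c(dark_gray = 310),
                          exposureTimeS = 0.01, spectrum = fxSpectrum())
  pts <- buildCalibrationPoints(list(shot), fxPanel(), mcaBands()[["550"]])
  expect_equal(nrow(pts), 1L)
  expect_equal(pts$dn, 310)
})

test_that("fitting recovers exact linear and quadratic generators", {
  band <- mcaBands()[["800"]]
  dn <- seq(10, 900, length.out = 60)
  a <- 2.3e-5
  fitL <- fitResponseCurve(data.frame(dn = dn, hlens = a * dn), band, 1)
  expect_equal(curveCoefficients(fitL), a, tolerance = 1e-12)
  expect_equal(rSquared(fitL), 1, tolerance = 1e-12)

  b <- 4e-9
  fitQ <- fitResponseCurve(data.frame(dn = dn, hlens = a * dn + b * dn^2),
                           band, 2)
  expect_equal(curveCoefficients(fitQ), c(a, b), tolerance = 1e-6)

  # forced zero intercept: DN 0 maps to exactly 0
  expect_identical(invertResponse(fitQ, 0), 0)
})

test_that("parameter recovery holds across seeds and noise levels", {
  cam0 <- fxCamera()
  true800 <- cam0@trueCoefficients[["800"]]
  for (seed in 1:3) {
    for (sigma in c(0, 0.005, 0.01)) {
      cam <- defaultCameraModel(noiseSigma = sigma)
      shots <- makeCalibrationSeries(fxPanel(), cam, fxSpectrum(),
                                     nShots = 50L, seed = seed)
      pts <- buildCalibrationPoints(shots[["800"]], fxPanel(),
                                    mcaBands()[["800"]])
      fit <- fitResponseCurve(pts, mcaBands()[["800"]], 2)
      relErr <- max(abs(curveCoefficients(fit) / true800 - 1))
      if (sigma == 0) {
        expect_lt(relErr, 1e-6)
        expect_equal(rSquared(fit), 1, tolerance = 1e-9)
      } else {
        expect_lt(relErr, 0.05)
        expect_gt(rSquared(fit), 0.99)
      }
    }
  }
})

test_that("calibration is invariant to a global exposure-time scaling", {
  fitAt <- function(range) {
    shots <- makeCalibrationSeries(fxPanel(), fxCamera(), fxSpectrum(),
                                   nShots = 20L, exposureRange = range,
                                   seed = 4)
    pts <- buildCalibrationPoints(shots[["550"]], fxPanel(),
                                  mcaBands()[["550"]])
    curveCoefficients(fitResponseCurve(pts, mcaBands()[["550"]], 2))
  }
  base <- fitAt(c(0.001, 0.01))
  scaled <- fitAt(3 * c(0.001, 0.01))
  expect_equal(scaled, base, tolerance = 1e-6)
})

test_that("non-monotone fits are rejected with a monotonicity error", {
  dn <- seq(0, 400, by = 10)
  h <- 1e-5 * (dn - 0.0017 * dn^2)   # peaks near DN 294, then decreases
  expect_error(fitResponseCurve(data.frame(dn = dn, hlens = h),
                                mcaBands()[["680"]], 2),
               class = "monotonicityError")
})

test_that("degenerate point sets are calibration errors", {
  band <- mcaBands()[["490"]]
  expect_error(fitResponseCurve(data.frame(dn = numeric(0),
                                           hlens = numeric(0)), band, 1),
               class = "calibrationError")
  expect_error(fitResponseCurve(data.frame(dn = c(5, 5), hlens = c(1, 2)),
                                band, 1), class = "calibrationError")
  expect_error(fitResponseCurve(data.frame(dn = 1:10, hlens = 1:10),
                                band, 5), class = "validationError")
})

test_that("DN conversion is element-wise and flags extrapolation", {
  band <- mcaBands()[["720"]]
  curve <- ResponseCurve(band = band, coefficients = c(2e-5, 3e-9),
                         fitDomain = c(0, 800))
  dnRaster <- matrix(c(100, 500, 100, 500), 2, 2)
  out <- invertResponse(curve, dnRaster)
  scalar <- function(x) 2e-5 * x + 3e-9 * x^2
  expect_equal(as.numeric(out), scalar(as.numeric(dnRaster)))
  expect_equal(dim(out), dim(dnRaster))
  # round trip of noiseless linear calibration points
  pts <- data.frame(dn = seq(5, 700, by = 5), hlens = 1.7e-5 *
                      seq(5, 700, by = 5))
  fit <- fitResponseCurve(pts, band, 1)
  expect_equal(invertResponse(fit, pts$dn), pts$hlens, tolerance = 1e-12)
  # above-domain DN evaluated but flagged
  expect_message(v <- invertResponse(curve, 900), "extrapolat")
  expect_equal(attr(v, "extrapolated"), 1)
  expect_error(invertResponse(curve, -1), class = "validationError")
})

test_that("response curves are strictly increasing and zero at DN 0", {
  for (bl in names(fxCurves())) {
    cv <- fxCurves()[[bl]]
    expect_identical(as.numeric(invertResponse(cv, 0)), 0)
    g <- seq(0, fitDomain(cv)[2], length.out = 200)
    expect_true(all(diff(invertResponse(cv, g)) > 0))
  }
})
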