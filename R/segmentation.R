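## Background / leaf / ear segmentation and per-organ BRF pooling.
##
## Step 1 separates soil from vegetation with an automatic threshold in the
## 800 nm channel (first local minimum of the smoothed histogram; soil is
## dark and vegetation bright in the near infrared). Under strong direct
## sunlight — cloudiness index below the gate — sunlit soil can reach DN
## levels comparable to shaded leaves, so auxiliary blue and Excess-Red
## tests reject soil-like pixels among the low-NIR candidates. Step 2
## splits vegetation into leaves and ears using an externally supplied ear
## mask (ear detection is an input contract, not re-implemented here).

#' Automatic valley threshold of a NIR sample
#'
#' Builds a histogram of the pixel values (256 bins over the observed range
#' by default), smooths it with a centred moving average (5 bins), and
#' returns the center of the first interior local-minimum bin, scanning
#' upward from the first non-empty bin; ties break toward the lower bin. A
#' candidate minimum counts as a valley only if (i) the smoothed histogram
#' on both sides reaches at least `valleyProminence` times the valley
#' count, and (ii) each side holds at least 2\% of the samples — sampling
#' noise dents a unimodal histogram with shallow shoulder dips and
#' spurious tail minima, and neither must become a threshold. A unimodal
#' or monotone histogram therefore yields a `noValleyError` instead of a
#' spurious threshold; the caller is expected to fall back to
#' [otsuThreshold()] in that case.
#'
#' @param values Numeric vector of pixel values (e.g. the 800 nm channel).
#' @param config A [SegmentationConfig] (histogram parameters).
#' @return The threshold value, with attribute `"binWidth"`.
#' @export
firstLocalMinimumThreshold <- function(values,
                                       config = SegmentationConfig()) {
  values <- values[is.finite(values)]
  if (length(values) < 2L || diff(range(values)) == 0)
    wbrfStop("degenerate sample: no spread in values", "noValleyError")
  ## never bin finer than the data's discrete resolution (integer DN over
  ## a narrow range would otherwise give a comb of spurious empty valleys)
  nb <- max(8L, min(config@histogramBins, length(unique(values))))
  breaks <- seq(min(values), max(values), length.out = nb + 1L)
  binWidth <- breaks[2] - breaks[1]
  idx <- pmin(nb, pmax(1L, findInterval(values, breaks,
                                        rightmost.closed = TRUE)))
  counts <- tabulate(idx, nbins = nb)
  s <- .movingAverage(counts, config@histogramSmoothingWindow)
  first <- which(s > 0)[1]
  if (is.na(first) || first >= nb - 1L)
    wbrfStop("histogram has no interior structure", "noValleyError")
  prom <- config@valleyProminence
  eps <- 0.5 / config@histogramSmoothingWindow  # a lone count, smoothed
  cumMass <- cumsum(counts) / sum(counts)
  for (i in (first + 1L):(nb - 1L)) {
    if (s[i] <= s[i - 1L] && s[i] <= s[i + 1L]) {
      floorCount <- max(s[i], eps)
      if (cumMass[i] >= 0.02 && cumMass[i] <= 0.98 &&
          max(s[first:(i - 1L)]) >= prom * floorCount &&
          max(s[(i + 1L):nb]) >= prom * floorCount) {
        thr <- (breaks[i] + breaks[i + 1L]) / 2
        attr(thr, "binWidth") <- binWidth
        return(thr)
      }
    }
  }
  wbrfStop("no interior local minimum: histogram is unimodal", "noValleyError")
}

## centred moving average with shrinking windows at the edges
.movingAverage <- function(x, window) {
  h <- window %/% 2L
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    out[i] <- mean(x[lo:hi])
  }
  out
}

#' Otsu threshold
#'
#' Classic between-class-variance-maximising threshold, used as the
#' fallback when the histogram valley search finds no interior minimum
#' (e.g. an all-vegetation scene).
#'
#' @param values Numeric vector of pixel values.
#' @param nBins Histogram bins (default 256).
#' @return Threshold value.
#' @export
otsuThreshold <- function(values, nBins = 256L) {
  values <- values[is.finite(values)]
  if (diff(range(values)) == 0) return(values[1])
  breaks <- seq(min(values), max(values), length.out = nBins + 1L)
  idx <- pmin(nBins, pmax(1L, findInterval(values, breaks,
                                           rightmost.closed = TRUE)))
  p <- tabulate(idx, nbins = nBins) / length(values)
  centers <- (breaks[-1] + breaks[-(nBins + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * centers)
  muT <- mu[nBins]
  sigmaB <- (muT * w0 - mu)^2 / (w0 * (1 - w0))
  sigmaB[!is.finite(sigmaB)] <- 0
  centers[which.max(sigmaB)]
}

#' Excess Red index
#'
#' \eqn{ExR = 1.4 r - g} on chromatic (normalized, \eqn{[0, 1]}) red and
#' green coordinates. Soil scores high (reddish), vegetation low; used as
#' an auxiliary rejection test for sunlit soil.
#'
#' @param red,green Numeric rasters of identical shape, normalized to
#'   \eqn{[0, 1]}.
#' @return The ExR raster.
#' @examples
#' excessRed(0.5, 0.3)  # 0.4
#' @export
excessRed <- function(red, green) {
  if (!identical(dim(red), dim(green)) || length(red) != length(green))
    wbrfStop("red and green rasters have different shapes",
             "validationError")
  1.4 * red - green
}

#' Background/vegetation segmentation
#'
#' First segmentation step: vegetation = pixels above the automatic valley
#' threshold in the 800 nm channel (fallback to Otsu with a warning when no
#' valley exists). When the cloudiness index is below `config@ctGate`
#' (strong direct sunlight), candidate vegetation pixels in the low-NIR
#' zone (NIR value at most `config@auxNirMax`) are kept only if they pass
#' both auxiliary tests — blue value below `config@blueThreshold` and
#' Excess Red below `config@exrThreshold` — which removes sunlit soil that
#' the NIR threshold alone confuses with shaded leaves. The thresholds
#' operate on whatever scale the supplied rasters use; DN rasters (before
#' BRF conversion) are the default convention.
#'
#' @param nir Near-infrared (800 nm) raster.
#' @param blue Blue-channel raster (required only when the gate fires).
#' @param red,green Chromatic red/green rasters for Excess Red (required
#'   only when the gate fires).
#' @param cloudiness The cloudiness index C_T at acquisition (see
#'   [cloudinessIndex()]); `NA` disables the gate.
#' @param config A [SegmentationConfig].
#' @return Logical vegetation mask with attribute `"provenance"` (a list:
#'   threshold used, fallback flag, C_T, gate state, auxiliary rejections).
#' @export
segmentBackground <- function(nir, blue = NULL, red = NULL, green = NULL,
                              cloudiness = NA_real_,
                              config = SegmentationConfig()) {
  if (!is.matrix(nir)) wbrfStop("nir must be a matrix", "validationError")
  prov <- list(ctGate = config@ctGate, cloudiness = cloudiness)
  thr <- tryCatch(firstLocalMinimumThreshold(as.vector(nir), config),
                  noValleyError = function(e) e)
  if (inherits(thr, "noValleyError")) {
    wbrfWarn(paste("no histogram valley in the NIR channel;",
                   "falling back to Otsu threshold"), "fallbackWarning")
    thr <- otsuThreshold(as.vector(nir), config@histogramBins)
    prov$fallback <- "otsu"
  } else {
    prov$fallback <- "none"
  }
  prov$nirThreshold <- as.numeric(thr)
  mask <- nir > as.numeric(thr)
  gateActive <- is.finite(cloudiness) && cloudiness < config@ctGate
  prov$gateActive <- gateActive
  prov$auxRejected <- 0L
  if (gateActive) {
    if (is.null(blue) || is.null(red) || is.null(green))
      wbrfStop(paste("cloudiness gate fired (strong direct sunlight) but",
                     "blue/red/green channels are missing"),
               "configurationError")
    exr <- excessRed(red, green)
    lowZone <- mask & (nir <= config@auxNirMax)
    soilLike <- lowZone & (blue > config@blueThreshold |
                             exr > config@exrThreshold)
    prov$auxRejected <- sum(soilLike)
    mask[soilLike] <- FALSE
  }
  attr(mask, "provenance") <- prov
  mask
}

#' Combine a vegetation mask with an ear mask
#'
#' Second segmentation step: ears are the intersection of the external ear
#' mask with vegetation, leaves are the remaining vegetation, background is
#' everything else. Ear pixels falling on background stay background; an
#' ear mask with no vegetation overlap at all triggers a warning
#' (suspicious registration).
#'
#' @param vegetationMask Logical raster from [segmentBackground()].
#' @param earMask Logical (or 0/1) raster of detected ears, same shape; may
#'   be `NULL` for an ear-free scene.
#' @return A [LabelMap].
#' @export
applyEarMask <- function(vegetationMask, earMask = NULL) {
  veg <- vegetationMask
  prov <- attr(vegetationMask, "provenance")
  if (is.null(prov)) prov <- list()
  labels <- matrix(ORGAN_CLASSES[["background"]], nrow(veg), ncol(veg))
  labels[veg] <- ORGAN_CLASSES[["leaf"]]
  if (!is.null(earMask)) {
    if (!identical(dim(earMask), dim(veg)))
      wbrfStop("ear mask shape differs from vegetation mask",
               "validationError")
    ear <- earMask > 0
    if (any(ear) && !any(ear & veg))
      wbrfWarn("ear mask has no overlap with vegetation: check registration",
               "registrationWarning")
    labels[ear & veg] <- ORGAN_CLASSES[["ear"]]
    prov$earPixels <- sum(ear & veg)
  }
  LabelMap(labels = labels, provenance = prov)
}

#' Per-organ mean BRF
#'
#' Arithmetic mean BRF of one organ class, per band, over unsaturated
#' pixels, with the pixel count. An absent class is an explicit
#' `emptyClassError`, never silent `NaN`.
#'
#' @param stack A [BRFStack].
#' @param labelMap A [LabelMap] of the same shape.
#' @param organ One of `"background"`, `"leaf"`, `"ear"`.
#' @return A `data.frame(organ, band, mean_brf, n_pixels)`, one row per
#'   band.
#' @export
organMeanBrf <- function(stack, labelMap, organ = c("leaf", "ear",
                                                    "background")) {
  organ <- match.arg(organ)
  stopifnot(is(stack, "BRFStack"), is(labelMap, "LabelMap"))
  lab <- labelMap@labels
  if (!identical(dim(lab), dim(stack@maps[[1]]@brf)))
    wbrfStop("label map shape differs from stack", "validationError")
  sel <- lab == ORGAN_CLASSES[[organ]]
  if (!any(sel))
    wbrfStop(sprintf("no '%s' pixels in the label map", organ),
             "emptyClassError")
  rows <- lapply(stack@maps, function(m) {
    use <- sel & !m@saturated
    if (!any(use))
      wbrfStop(sprintf(
        "all '%s' pixels saturated in band '%s'", organ,
        bandLabel(m@band)), "emptyClassError")
    data.frame(organ = organ, band = bandLabel(m@band),
               mean_brf = mean(m@brf[use]), n_pixels = sum(use))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
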