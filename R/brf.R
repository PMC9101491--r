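## DN raster -> BRF map conversion and band stacking.

#' Mean blur of a channel raster
#'
#' Applies a k x k arithmetic-mean filter (default 5 x 5) to a raster, with
#' symmetric-reflection edge handling, to dampen residual band-to-band
#' registration errors before BRF conversion. Implemented with a summed-area
#' table, so it is exact and fast.
#'
#' @param raster Numeric matrix at least `kernelSize` x `kernelSize`.
#' @param kernelSize Odd window size (default 5).
#' @return Blurred matrix of the same shape.
#' @examples
#' m <- matrix(0, 9, 9); m[5, 5] <- 25
#' blurChannel(m)[5, 5]  # 1
#' @export
blurChannel <- function(raster, kernelSize = 5L) {
  kernelSize <- as.integer(kernelSize)
  if (kernelSize < 1L || kernelSize %% 2L == 0L)
    wbrfStop("kernelSize must be a positive odd integer", "validationError")
  if (!is.matrix(raster) || nrow(raster) < kernelSize ||
      ncol(raster) < kernelSize)
    wbrfStop(sprintf("raster must be at least %d x %d",
                     kernelSize, kernelSize), "validationError")
  h <- kernelSize %/% 2L
  nr <- nrow(raster); nc <- ncol(raster)
  ri <- c(h:1, 1:nr, nr:(nr - h + 1L))        # symmetric reflection pad
  ci <- c(h:1, 1:nc, nc:(nc - h + 1L))
  p <- raster[ri, ci, drop = FALSE]
  ## summed-area table with a zero first row/col
  s <- matrix(0, nrow(p) + 1L, ncol(p) + 1L)
  s[-1, -1] <- apply(apply(p, 2, cumsum), 1, cumsum) |> t()
  i0 <- 1:nr; j0 <- 1:nc
  (s[i0 + kernelSize, j0 + kernelSize, drop = FALSE] -
     s[i0, j0 + kernelSize, drop = FALSE] -
     s[i0 + kernelSize, j0, drop = FALSE] +
     s[i0, j0, drop = FALSE]) / kernelSize^2
}

#' Convert a DN image to a BRF map
#'
#' Inverts the radiometric chain for one band: per pixel,
#' \deqn{BRF = \pi \, H_{lens}(DN) / (E_{band} \, t)}
#' where Hlens comes from the fitted camera response curve, E_band is the
#' incident-light spectrum integrated over the filter band and t the
#' exposure time. Because Hlens is proportional to t for a given scene, the
#' result is independent of the auto-exposure setting; because it is
#' proportional to E, it is independent of the illumination level — the two
#' invariances that make BRF comparable across the day.
#'
#' Pixels at the sensor maximum are marked in the saturation mask carried by
#' the result (their BRF value is still computed but downstream organ means
#' exclude them).
#'
#' @param image A [ChannelImage].
#' @param curve The [ResponseCurve] for the same band.
#' @param spectrum The [IrradianceSpectrum] recorded at acquisition.
#' @param blur Apply the 5 x 5 mean blur ([blurChannel()]) to the DN raster
#'   before conversion (default `FALSE`; the full processing chain enables
#'   it to dampen registration errors, see [processAcquisition()]).
#' @return A [BRFMap].
#' @export
dnToBrf <- function(image, curve, spectrum, blur = FALSE) {
  stopifnot(is(image, "ChannelImage"), is(curve, "ResponseCurve"),
            is(spectrum, "IrradianceSpectrum"))
  if (bandLabel(image@band) != bandLabel(curve@band))
    wbrfStop(sprintf("band mismatch: image '%s' vs curve '%s'",
                     bandLabel(image@band), bandLabel(curve@band)),
             "validationError")
  eBand <- integrateBand(spectrum, image@band)
  if (eBand <= 0)
    wbrfStop(sprintf(
      "band irradiance is zero for band '%s': dark spectrum, cannot divide",
      bandLabel(image@band)), "divisionError")
  dnMax <- 2^image@bitDepth - 1
  saturated <- image@dn >= dnMax
  dnIn <- if (blur) blurChannel(image@dn) else image@dn
  hlens <- suppressMessages(invertResponse(curve, dnIn))
  brfRaster <- pi * as.matrix(hlens) / (eBand * image@exposureTimeS)
  brfRaster[brfRaster < 0] <- 0  # guard: monotone curve keeps this empty
  attr(brfRaster, "extrapolated") <- NULL
  BRFMap(brf = brfRaster, band = image@band, eBand = eBand,
         saturated = saturated)
}

#' Stack per-band BRF maps
#'
#' Assembles co-registered per-band [BRFMap] objects into a [BRFStack],
#' ordered by ascending band center with metadata preserved. Inputs must be
#' pre-registered: a shape mismatch is a registration error, and duplicate
#' bands are rejected.
#'
#' @param maps List of [BRFMap] objects with identical raster shapes and
#'   distinct bands.
#' @return A [BRFStack] named by band label.
#' @export
stackBands <- function(maps) {
  if (!length(maps)) wbrfStop("no maps to stack", "validationError")
  if (!all(vapply(maps, is, logical(1), "BRFMap")))
    wbrfStop("all elements must be BRFMap objects", "validationError")
  dims <- vapply(maps, function(m) dim(m@brf), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    wbrfStop("raster shapes differ: inputs must be pre-registered",
             "registrationError")
  labels <- vapply(maps, function(m) bandLabel(m@band), character(1))
  if (anyDuplicated(labels))
    wbrfStop(sprintf("duplicate band labels: %s",
                     paste(labels[duplicated(labels)], collapse = ", ")),
             "validationError")
  ord <- order(vapply(maps, function(m) bandCenter(m@band), numeric(1)))
  maps <- maps[ord]
  names(maps) <- labels[ord]
  BRFStack(maps = maps)
}
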