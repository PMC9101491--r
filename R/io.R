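## Readers and writers: spectra and panel CSVs, DN / BRF / label rasters as
## TIFF, acquisition manifests and pipeline configuration.
##
## Conventions: rasters are row-major matrices, origin top-left. DN images
## are stored as 16-bit grayscale TIFF (exact for any bit depth up to 16);
## BRF stacks as multi-page 32-bit float TIFF scaled into [0, 1] by a
## factor recorded in the JSON sidecar; label maps as 8-bit TIFF with the
## 3-value palette 0 = background, 1 = leaf, 2 = ear.

#' Read an incident-light spectrum CSV
#'
#' Two-column CSV with header `wavelength_nm, irradiance_W_m2_nm` (the
#' irradiance column may also be named `irradiance`). Wavelengths must be
#' strictly increasing and irradiance non-negative; violations report the
#' offending line.
#'
#' @param path CSV file path.
#' @param timestamp Optional timezone-aware `POSIXct` to attach (sidecar
#'   metadata convention: the acquisition manifest carries it).
#' @return An [IrradianceSpectrum].
#' @export
readSpectrum <- function(path, timestamp = .emptyTime()) {
  if (!file.exists(path))
    wbrfStop(sprintf("spectrum file not found: %s", path), "ioError")
  df <- utils::read.csv(path, check.names = FALSE)
  wCol <- "wavelength_nm"
  eCol <- intersect(c("irradiance_W_m2_nm", "irradiance"), names(df))[1]
  if (!wCol %in% names(df) || is.na(eCol))
    wbrfStop(sprintf(
      "%s: header must name wavelength_nm and irradiance_W_m2_nm", path),
      "parseError")
  w <- df[[wCol]]; e <- df[[eCol]]
  bad <- which(diff(w) <= 0)
  if (length(bad))
    wbrfStop(sprintf("%s: wavelengths not strictly increasing at line %d",
                     path, bad[1] + 2L), "parseError")
  bad <- which(e < 0)
  if (length(bad))
    wbrfStop(sprintf("%s: negative irradiance at line %d", path,
                     bad[1] + 1L), "parseError")
  IrradianceSpectrum(wavelengthNm = w, irradiance = e,
                     timestamp = timestamp)
}

#' Write an incident-light spectrum CSV
#'
#' @param spectrum An [IrradianceSpectrum].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeSpectrum <- function(spectrum, path) {
  stopifnot(is(spectrum, "IrradianceSpectrum"))
  df <- data.frame(wavelength_nm = spectrum@wavelengthNm,
                   irradiance_W_m2_nm = spectrum@irradiance)
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a reference-panel specification
#'
#' The panel manifest is a YAML file naming, for each target, its
#' reflectance CSV (columns `wavelength_nm, reflectance`) and optionally
#' its ROI rectangle `[rowMin, rowMax, colMin, colMax]` in panel shots:
#'
#' ```
#' targets:
#'   dark_gray: {spectrum: dark_gray.csv, roi: [2, 11, 14, 23]}
#'   ...
#' ```
#'
#' Relative spectrum paths resolve against the manifest's directory.
#'
#' @param path Manifest YAML path.
#' @return A [PanelSpec].
#' @export
readPanelSpec <- function(path) {
  if (!file.exists(path))
    wbrfStop(sprintf("panel manifest not found: %s", path), "ioError")
  man <- yaml::read_yaml(path)
  base <- dirname(path)
  targets <- list(); rois <- list()
  for (nm in names(man$targets)) {
    entry <- man$targets[[nm]]
    sp <- entry$spectrum
    if (!file.exists(sp)) sp <- file.path(base, entry$spectrum)
    targets[[nm]] <- utils::read.csv(sp)
    if (!is.null(entry$roi)) rois[[nm]] <- as.integer(entry$roi)
  }
  PanelSpec(targets = targets, rois = rois)
}

#' Write a panel specification (manifest + per-target CSVs)
#'
#' @param panel A [PanelSpec].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
writePanelSpec <- function(panel, dir) {
  stopifnot(is(panel, "PanelSpec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- list(targets = list())
  for (nm in names(panel@targets)) {
    f <- paste0(nm, ".csv")
    utils::write.csv(panel@targets[[nm]], file.path(dir, f),
                     row.names = FALSE, quote = FALSE)
    man$targets[[nm]] <- list(spectrum = f)
    if (!is.null(panel@rois[[nm]]))
      man$targets[[nm]]$roi <- as.integer(panel@rois[[nm]])
  }
  out <- file.path(dir, "panel.yaml")
  yaml::write_yaml(man, out)
  invisible(out)
}

#' Write / read a single-band DN image as 16-bit TIFF
#'
#' DN values are stored exactly (scaled into the 16-bit range), so the
#' round trip is lossless for any sensor depth up to 16 bits.
#'
#' @param image A [ChannelImage].
#' @param path Output `.tif` path.
#' @return `path` (writer, invisibly) / a [ChannelImage] (reader).
#' @rdname channelImageIO
#' @export
writeChannelImage <- function(image, path) {
  stopifnot(is(image, "ChannelImage"))
  tiff::writeTIFF(image@dn / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @param band,exposureTimeS,bitDepth,timestamp Metadata for the reader
#'   (the manifest carries them; TIFF stores only pixels).
#' @rdname channelImageIO
#' @export
readChannelImage <- function(path, band, exposureTimeS, bitDepth = 10L,
                             timestamp = .emptyTime()) {
  if (!file.exists(path))
    wbrfStop(sprintf("image not found: %s", path), "ioError")
  px <- round(tiff::readTIFF(path) * 65535)
  ChannelImage(dn = px, band = band, exposureTimeS = exposureTimeS,
               bitDepth = as.integer(bitDepth), timestamp = timestamp)
}

#' Write / read a BRF stack as multi-page float TIFF with JSON sidecar
#'
#' One 32-bit float page per band, values divided by a scale factor so
#' they fit the [0, 1] storage range; the sidecar
#' (`<path>.json`) records band centers/widths/labels, the scale, the
#' per-band integrated irradiance, saturated-pixel counts and,
#' when supplied, the cloudiness index and acquisition timestamp.
#'
#' @param stack A [BRFStack].
#' @param path Output `.tif` path (sidecar written next to it).
#' @param cloudiness Optional cloudiness index C_T at acquisition.
#' @param timestamp Optional acquisition timestamp (ISO-8601 string or
#'   `POSIXct`).
#' @return `path` (writer, invisibly) / a [BRFStack] (reader).
#' @rdname brfStackIO
#' @export
writeBRFStack <- function(stack, path, cloudiness = NA_real_,
                          timestamp = NULL) {
  stopifnot(is(stack, "BRFStack"))
  scale <- max(1, ceiling(max(vapply(stack@maps, function(m) max(m@brf),
                                     numeric(1)))))
  pages <- lapply(stack@maps, function(m) m@brf / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  side <- list(
    scale = scale,
    cloudiness_index = cloudiness,
    timestamp = if (is.null(timestamp)) NA_character_
                else format(timestamp, "%Y-%m-%dT%H:%M:%S%z"),
    bands = lapply(stack@maps, function(m) list(
      label = bandLabel(m@band), center_nm = bandCenter(m@band),
      width_nm = bandWidth(m@band), e_band_W_m2 = m@eBand,
      n_saturated = sum(m@saturated))))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname brfStackIO
#' @export
readBRFStack <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  maps <- mapply(function(pg, meta) {
    BRFMap(brf = pg * side$scale,
           band = FilterBand(meta$center_nm, meta$width_nm, meta$label),
           eBand = meta$e_band_W_m2,
           saturated = matrix(FALSE, nrow(pg), ncol(pg)))
  }, pages, side$bands, SIMPLIFY = FALSE)
  suppressWarnings(stackBands(maps))
}

#' Write / read a label map as 8-bit TIFF
#'
#' Palette: 0 = background, 1 = leaf, 2 = ear (stored exactly).
#'
#' @param labelMap A [LabelMap].
#' @param path Output `.tif` path.
#' @return `path` (writer, invisibly) / a [LabelMap] (reader; provenance
#'   is not round-tripped).
#' @rdname labelMapIO
#' @export
writeLabelMap <- function(labelMap, path) {
  stopifnot(is(labelMap, "LabelMap"))
  tiff::writeTIFF(labelMap@labels / 255, path, bits.per.sample = 8L,
                  compression = "none")
  invisible(path)
}

#' @rdname labelMapIO
#' @export
readLabelMap <- function(path) {
  px <- round(tiff::readTIFF(path) * 255)
  LabelMap(labels = matrix(as.integer(px), nrow(px), ncol(px)))
}

#' Read / write a binary mask image (TIFF or PNG)
#'
#' Masks are single-band 0/1 images, e.g. externally produced ear masks.
#'
#' @param path File path (`.tif`/`.tiff` or `.png`).
#' @return Logical matrix (reader) / `path` invisibly (writer).
#' @rdname maskIO
#' @export
readMask <- function(path) {
  if (!file.exists(path))
    wbrfStop(sprintf("mask not found: %s", path), "ioError")
  px <- if (grepl("\\.png$", path, ignore.case = TRUE))
    png::readPNG(path) else tiff::readTIFF(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  px > 0.5
}

#' @param mask Logical (or 0/1) matrix.
#' @rdname maskIO
#' @export
writeMask <- function(mask, path) {
  tiff::writeTIFF((mask > 0) * 1, path, bits.per.sample = 8L,
                  compression = "none")
  invisible(path)
}

#' Response-curve JSON persistence
#'
#' Documented stable schema: `band` (label, center_nm, width_nm),
#' `degree`, `coefficients` (ascending powers, no constant term),
#' `fit_domain`, `r_squared`, `n_points`, `schema_version`.
#'
#' @param curve A [ResponseCurve].
#' @param path Output `.json` path.
#' @return `path` (writer, invisibly) / a [ResponseCurve] (reader).
#' @rdname responseCurveIO
#' @export
writeResponseCurve <- function(curve, path) {
  stopifnot(is(curve, "ResponseCurve"))
  jsonlite::write_json(list(
    schema_version = 1L,
    band = list(label = bandLabel(curve@band),
                center_nm = bandCenter(curve@band),
                width_nm = bandWidth(curve@band)),
    degree = length(curve@coefficients),
    coefficients = curve@coefficients,
    fit_domain = curve@fitDomain,
    r_squared = curve@r2,
    n_points = curve@nPoints), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname responseCurveIO
#' @export
readResponseCurve <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  ResponseCurve(
    band = FilterBand(j$band$center_nm, j$band$width_nm, j$band$label),
    coefficients = as.numeric(j$coefficients),
    fitDomain = as.numeric(j$fit_domain),
    r2 = as.numeric(j$r_squared),
    nPoints = as.integer(j$n_points))
}

#' Read an acquisition manifest
#'
#' CSV with one row per (acquisition, band):
#' `acquisition, plot, band, image, exposure_time_s, spectrum, timestamp`
#' and optional `ear_mask`. Paths resolve against the manifest directory;
#' timestamps are ISO-8601 with explicit offsets. Each band may appear
#' only once per acquisition and referenced files must exist.
#'
#' @param path Manifest CSV path.
#' @return A `data.frame` with resolved paths.
#' @export
readManifest <- function(path) {
  if (!file.exists(path))
    wbrfStop(sprintf("manifest not found: %s", path), "ioError")
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("acquisition", "plot", "band", "image", "exposure_time_s",
            "spectrum", "timestamp")
  missing <- setdiff(need, names(man))
  if (length(missing))
    wbrfStop(sprintf("manifest lacks column(s): %s",
                     paste(missing, collapse = ", ")), "parseError")
  base <- dirname(path)
  resolve <- function(p) ifelse(nzchar(p) & !file.exists(p),
                                file.path(base, p), p)
  man$image <- resolve(man$image)
  man$spectrum <- resolve(man$spectrum)
  if ("ear_mask" %in% names(man)) man$ear_mask <- resolve(man$ear_mask)
  dup <- duplicated(man[, c("acquisition", "band")])
  if (any(dup))
    wbrfStop("manifest repeats a band within an acquisition", "parseError")
  for (f in c(man$image, man$spectrum))
    if (nzchar(f) && !file.exists(f))
      wbrfStop(sprintf("manifest references missing file: %s", f),
               "ioError")
  man
}

#' Read a pipeline configuration YAML
#'
#' Fields: `site` (`latitude_deg`, `longitude_deg`, `timezone`), `bands`
#' (list of center/width/label), `curve_degree`, `segmentation`
#' (thresholds and gate), `correction_direction`, `bit_depth`. Missing
#' fields fall back to package defaults; malformed values fail with an
#' actionable message.
#'
#' @param path YAML path.
#' @return A named list: `site`, `bands` (list of [FilterBand]),
#'   `curveDegree`, `segmentation` ([SegmentationConfig]),
#'   `correctionDirection`, `bitDepth`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  site <- y$site
  if (is.null(site$latitude_deg) || is.null(site$longitude_deg) ||
      is.null(site$timezone))
    wbrfStop("config site: needs latitude_deg, longitude_deg, timezone",
             "configurationError")
  bands <- if (is.null(y$bands)) mcaBands() else {
    bl <- lapply(y$bands, function(b)
      FilterBand(b$center_nm, b$width_nm,
                 if (is.null(b$label)) as.character(b$center_nm) else b$label))
    names(bl) <- vapply(bl, bandLabel, character(1))
    bl
  }
  segArgs <- y$segmentation
  seg <- SegmentationConfig()
  if (!is.null(segArgs)) {
    if (!is.null(segArgs$blue_threshold)) seg@blueThreshold <- segArgs$blue_threshold
    if (!is.null(segArgs$exr_threshold)) seg@exrThreshold <- segArgs$exr_threshold
    if (!is.null(segArgs$ct_gate)) seg@ctGate <- segArgs$ct_gate
    if (!is.null(segArgs$aux_nir_max)) seg@auxNirMax <- segArgs$aux_nir_max
    if (!is.null(segArgs$nir_band)) seg@nirBandLabel <- as.character(segArgs$nir_band)
    if (!is.null(segArgs$blue_band)) seg@blueBandLabel <- as.character(segArgs$blue_band)
    validObject(seg)
  }
  direction <- if (is.null(y$correction_direction)) "corrective"
               else y$correction_direction
  if (!direction %in% c("corrective", "literal"))
    wbrfStop("config correction_direction must be 'corrective' or 'literal'",
             "configurationError")
  list(site = list(latitudeDeg = site$latitude_deg,
                   longitudeDeg = site$longitude_deg,
                   timezone = site$timezone),
       bands = bands,
       curveDegree = if (is.null(y$curve_degree)) 2L
                     else as.integer(y$curve_degree),
       segmentation = seg,
       correctionDirection = direction,
       bitDepth = if (is.null(y$bit_depth)) 10L else as.integer(y$bit_depth))
}

#' Write organ-BRF records to the tidy output CSV
#'
#' Schema (version 1): `date, plot, organ, band, mean_brf, n_pixels`, plus
#' correction columns when present. Numeric formatting is fixed so reruns
#' are byte-identical.
#'
#' @param records `data.frame` of organ records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeOrganBrfCsv <- function(records, path) {
  num <- vapply(records, is.numeric, logical(1))
  records[num] <- lapply(records[num], function(x)
    formatC(x, digits = 10, format = "g"))
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
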