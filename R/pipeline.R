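## Workflow plumbing: calibration over all bands, panel BRF measurement,
## per-acquisition processing (DN -> BRF -> segmentation -> organ means),
## inter-date correction, and campaign serialization for the CLI.

#' Fit response curves for every band of a calibration series
#'
#' @param shotsByBand Named list (band label) of [CalibrationShot] lists,
#'   e.g. from [makeCalibrationSeries()].
#' @param panel The [PanelSpec].
#' @param bands Named list of [FilterBand] matching the shot list.
#' @param degree Polynomial degree (1-3, default 2).
#' @return Named list of [ResponseCurve].
#' @export
calibrateResponseCurves <- function(shotsByBand, panel,
                                    bands = mcaBands(), degree = 2L) {
  out <- lapply(names(shotsByBand), function(nm) {
    pts <- buildCalibrationPoints(shotsByBand[[nm]], panel, bands[[nm]])
    fitResponseCurve(pts, bands[[nm]], degree)
  })
  names(out) <- names(shotsByBand)
  out
}

#' Measured BRF of a panel target in one shot
#'
#' Mean DN over the target's ROI (no blur), through the fitted response
#' curve and the band-integrated irradiance of the shot's spectrum:
#' \eqn{BRF = \pi H_{lens}(\bar{DN}) / (E_{band} t)}.
#'
#' @param shot A [CalibrationShot].
#' @param panel The [PanelSpec] (for the ROI).
#' @param target Target name (default `"dark_gray"`, the correction
#'   target).
#' @param curve The band's [ResponseCurve].
#' @return The measured target BRF (single number).
#' @export
measurePanelBrf <- function(shot, panel, curve, target = "dark_gray") {
  stopifnot(is(shot, "CalibrationShot"), is(curve, "ResponseCurve"))
  ext <- .shotTargetDN(shot, target, panel)
  if (ext$saturated)
    wbrfWarn(sprintf("target '%s' saturated in panel shot", target),
             "saturationWarning")
  eBand <- integrateBand(shot@spectrum, curve@band)
  hl <- suppressMessages(invertResponse(curve, ext$dn))
  pi * as.numeric(hl) / (eBand * shot@exposureTimeS)
}

## chromatic coordinates from three DN rasters (fallback when no RGB camera
## data accompany the multispectral stack; band sensitivities are absorbed
## by the site-specific ExR threshold)
.chromaticFromDN <- function(red, green, blue) {
  tot <- red + green + blue
  tot[tot == 0] <- 1
  list(r = red / tot, g = green / tot)
}

#' Process one acquisition to organ BRF records
#'
#' The per-acquisition chain: 5 x 5 blur of the DN channels, DN to BRF per
#' band, stack, cloudiness-gated background segmentation on the unblurred
#' DN channels (blurring would smear class boundaries into the
#' thresholds), ear-mask application, organ pooling.
#'
#' @param images Named list of [ChannelImage] (band label -> image).
#' @param spectrum The acquisition's [IrradianceSpectrum].
#' @param curves Named list of [ResponseCurve].
#' @param geometry A [SunGeometry] (or `NULL` to skip the cloudiness
#'   gate).
#' @param earMask Optional logical ear mask.
#' @param segConfig A [SegmentationConfig].
#' @param blur Apply the 5 x 5 registration-error blur before BRF
#'   conversion (default `TRUE`).
#' @return List: `stack` ([BRFStack]), `labelMap` ([LabelMap]),
#'   `records` (organ-mean `data.frame`), `cloudiness`.
#' @export
processAcquisition <- function(images, spectrum, curves, geometry = NULL,
                               earMask = NULL,
                               segConfig = SegmentationConfig(),
                               blur = TRUE) {
  maps <- lapply(names(images), function(nm)
    dnToBrf(images[[nm]], curves[[nm]], spectrum, blur = blur))
  stack <- stackBands(maps)
  ct <- NA_real_
  if (!is.null(geometry))
    ct <- tryCatch(cloudinessIndex(totalIrradiance(spectrum), geometry),
                   geometryError = function(e) NA_real_)
  rawDN <- function(lbl) images[[lbl]]@dn
  nir <- rawDN(segConfig@nirBandLabel)
  gateMayFire <- is.finite(ct) && ct < segConfig@ctGate
  if (gateMayFire) {
    chrom <- .chromaticFromDN(rawDN("680"), rawDN("550"),
                              rawDN(segConfig@blueBandLabel))
    veg <- segmentBackground(nir, blue = rawDN(segConfig@blueBandLabel),
                             red = chrom$r, green = chrom$g,
                             cloudiness = ct, config = segConfig)
  } else {
    veg <- segmentBackground(nir, cloudiness = ct, config = segConfig)
  }
  labelMap <- applyEarMask(veg, earMask)
  organs <- c("leaf", if (any(labelMap@labels == ORGAN_CLASSES[["ear"]]))
    "ear")
  records <- do.call(rbind, lapply(organs, function(o)
    organMeanBrf(stack, labelMap, o)))
  list(stack = stack, labelMap = labelMap, records = records,
       cloudiness = ct)
}

#' Inter-date panel correction of pipeline records
#'
#' Groups records by date, extracts the begin/end panel rows
#' (`organ == "panel:<target>"`, `plot` `"panel_begin"` / `"panel_end"`),
#' applies the begin/end consistency rule ([sessionPanelBrf()]) and
#' multiplies every record of that date by the per-band factor
#' ([correctionFactor()]).
#'
#' @param records Tidy record `data.frame` with columns `date, plot,
#'   organ, band, mean_brf, ...`.
#' @param panel The [PanelSpec] (theoretical reflectances).
#' @param bands Named list of [FilterBand].
#' @param target Correction target (default `"dark_gray"`).
#' @param direction Correction direction (see [correctionFactor()]).
#' @param relTol Begin/end consistency tolerance (default 0.03).
#' @return Corrected records (non-destructive: raw values and factors kept
#'   as extra columns).
#' @export
correctRecords <- function(records, panel, bands = mcaBands(),
                           target = "dark_gray",
                           direction = c("corrective", "literal"),
                           relTol = 0.03) {
  direction <- match.arg(direction)
  panelOrgan <- paste0("panel:", target)
  out <- list()
  for (d in unique(records$date)) {
    sub <- records[records$date == d, , drop = FALSE]
    factors <- numeric(0)
    for (bl in unique(as.character(sub$band))) {
      theo <- integrateReflectanceBand(panel@targets[[target]],
                                       bands[[bl]])
      pick <- function(which) {
        v <- sub$mean_brf[sub$organ == panelOrgan & sub$band == bl &
                            sub$plot == which]
        if (length(v)) v[1] else NA_real_
      }
      check <- PanelCheck(band = bl, brfBegin = pick("panel_begin"),
                          brfEnd = pick("panel_end"),
                          brfTheoretical = theo)
      measured <- sessionPanelBrf(check, relTol)
      factors[bl] <- correctionFactor(as.numeric(measured), theo,
                                      direction)
    }
    out[[d]] <- applyCorrection(sub, factors)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the full pipeline on an acquisition manifest
#'
#' For every acquisition in the manifest: read the per-band DN images and
#' the incident-light spectrum, compute the sun geometry and cloudiness
#' index from the timestamp and the configured site, convert to BRF
#' (5 x 5 blur first), segment, pool organ means, and write the BRF stack
#' (+ JSON sidecar with bands, E_band, C_T, timestamp), the label map and
#' one tidy CSV of records. Rows whose manifest `plot` is `"panel_begin"`
#' or `"panel_end"` are treated as reference-panel shots and measured into
#' `organ = "panel:dark_gray"` rows instead of being segmented. A failure
#' in one acquisition is recorded and isolated; the others still run.
#' Reruns on identical inputs are byte-identical.
#'
#' @param manifest Path to a manifest CSV (see [readManifest()]) or an
#'   equivalent `data.frame`.
#' @param config Path to a configuration YAML (see [readPipelineConfig()])
#'   or an equivalent list.
#' @param curves Named list of [ResponseCurve], or a directory containing
#'   `curve_<band>.json` files.
#' @param outDir Output directory.
#' @param panel Optional [PanelSpec]; required when the manifest contains
#'   panel shots or correction is requested.
#' @param correct Apply the inter-date panel correction to the record CSV
#'   (default `TRUE` when panel shots are present).
#' @return Invisibly, a list: `records` (the corrected data frame),
#'   `errors` (per-acquisition error records, zero rows when clean),
#'   `outputs` (paths written).
#' @export
runPipeline <- function(manifest, config, curves, outDir, panel = NULL,
                        correct = NA) {
  if (is.character(manifest)) manifest <- readManifest(manifest)
  if (is.character(config)) config <- readPipelineConfig(config)
  if (is.character(curves)) {
    files <- list.files(curves, pattern = "^curve_.*\\.json$",
                        full.names = TRUE)
    curves <- lapply(files, readResponseCurve)
    names(curves) <- vapply(curves, function(cv) bandLabel(cv@band),
                            character(1))
  }
  needBands <- setdiff(unique(as.character(manifest$band)), names(curves))
  if (length(needBands))
    wbrfStop(sprintf("no response curve for band(s): %s",
                     paste(needBands, collapse = ", ")),
             "configurationError")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outDir, "brf"), showWarnings = FALSE)
  dir.create(file.path(outDir, "labels"), showWarnings = FALSE)

  recordsAll <- list(); errors <- list(); outputs <- character(0)
  logLines <- list()
  for (acq in unique(manifest$acquisition)) {
    rows <- manifest[manifest$acquisition == acq, , drop = FALSE]
    res <- tryCatch({
      ts <- .parseIso8601(rows$timestamp[1])
      spectrum <- readSpectrum(rows$spectrum[1], timestamp = ts)
      date <- format(ts, "%Y-%m-%d",
                     tz = config$site$timezone)
      isPanel <- rows$plot[1] %in% c("panel_begin", "panel_end")
      images <- list()
      for (k in seq_len(nrow(rows))) {
        bl <- as.character(rows$band[k])
        images[[bl]] <- readChannelImage(
          rows$image[k], config$bands[[bl]], rows$exposure_time_s[k],
          config$bitDepth, ts)
      }
      geometry <- sunPosition(config$site$latitudeDeg,
                              config$site$longitudeDeg, ts)
      if (isPanel) {
        if (is.null(panel))
          wbrfStop("manifest has panel shots but no panel spec given",
                   "configurationError")
        recs <- do.call(rbind, lapply(names(images), function(bl) {
          shot <- CalibrationShot(dn = images[[bl]]@dn,
                                  exposureTimeS = images[[bl]]@exposureTimeS,
                                  spectrum = spectrum,
                                  bitDepth = config$bitDepth)
          data.frame(date = date, plot = rows$plot[1],
                     organ = "panel:dark_gray", band = bl,
                     mean_brf = measurePanelBrf(shot, panel, curves[[bl]]),
                     n_pixels = NA_integer_)
        }))
        list(records = recs, stack = NULL, labelMap = NULL)
      } else {
        earMask <- NULL
        if ("ear_mask" %in% names(rows) && nzchar(rows$ear_mask[1]) &&
            !is.na(rows$ear_mask[1]))
          earMask <- readMask(rows$ear_mask[1])
        pr <- processAcquisition(images, spectrum, curves, geometry,
                                 earMask, config$segmentation)
        pr$records <- cbind(data.frame(date = date, plot = rows$plot[1]),
                            pr$records)
        pr
      }
    }, wheatBRFError = function(e) e, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[acq]] <- data.frame(acquisition = acq,
                                  error = conditionMessage(res))
      next
    }
    recordsAll[[acq]] <- res$records
    if (!is.null(res$stack)) {
      p <- file.path(outDir, "brf", paste0(acq, ".tif"))
      writeBRFStack(res$stack, p, cloudiness = res$cloudiness,
                    timestamp = .parseIso8601(rows$timestamp[1]))
      writeLabelMap(res$labelMap,
                    file.path(outDir, "labels", paste0(acq, ".tif")))
      outputs <- c(outputs, p)
    }
    logLines[[acq]] <- data.frame(
      acquisition = acq,
      inputs = paste(basename(c(rows$image, rows$spectrum[1])),
                     collapse = ";"),
      md5 = paste(tools::md5sum(c(rows$image, rows$spectrum[1])),
                  collapse = ";"))
  }
  records <- do.call(rbind, recordsAll)
  rownames(records) <- NULL
  hasPanel <- !is.null(records) &&
    any(records$plot %in% c("panel_begin", "panel_end"))
  if (is.na(correct)) correct <- hasPanel
  if (isTRUE(correct)) {
    if (!hasPanel)
      wbrfStop("correction requested but manifest has no panel shots",
               "correctionError")
    records <- correctRecords(records, panel, config$bands,
                              direction = config$correctionDirection)
  }
  csvPath <- file.path(outDir, "organ_brf.csv")
  writeOrganBrfCsv(records, csvPath)
  errDf <- if (length(errors)) do.call(rbind, errors)
           else data.frame(acquisition = character(0),
                           error = character(0))
  if (length(logLines))
    utils::write.csv(do.call(rbind, logLines),
                     file.path(outDir, "pipeline_log.csv"),
                     row.names = FALSE)
  if (nrow(errDf))
    utils::write.csv(errDf, file.path(outDir, "errors.csv"),
                     row.names = FALSE)
  invisible(list(records = records, errors = errDf,
                 outputs = c(outputs, csvPath)))
}

.parseIso8601 <- function(s) {
  t <- as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%S%z", tz = "UTC")
  if (is.na(t)) t <- as.POSIXct(s, format = "%Y-%m-%d %H:%M:%S%z",
                                tz = "UTC")
  if (is.na(t))
    wbrfStop(sprintf(
      "timestamp '%s' is not ISO-8601 with an explicit offset", s),
      "parseError")
  t
}

#' Analyse a simulated season in memory
#'
#' Runs the analysis chain over a [makeSeason()] campaign: calibrates
#' nothing (curves are supplied), measures the begin/end dark-gray panel
#' BRF, converts and segments every canopy acquisition (the scene's true
#' ear pixels serve as the external ear-mask input), pools organ means and
#' optionally applies the inter-date correction.
#'
#' @param season Output of [makeSeason()].
#' @param curves Named list of [ResponseCurve] fitted on an undrifted
#'   calibration series.
#' @param segConfig A [SegmentationConfig].
#' @param correct Apply the panel correction (default `TRUE`).
#' @param direction Correction direction.
#' @return Tidy `data.frame` of per-date records (panel and organ rows;
#'   corrected columns when `correct`).
#' @export
processSeason <- function(season, curves,
                          segConfig = SegmentationConfig(),
                          correct = TRUE,
                          direction = c("corrective", "literal")) {
  direction <- match.arg(direction)
  earMask <- season$truth@labels == ORGAN_CLASSES[["ear"]]
  if (!any(earMask)) earMask <- NULL
  bandObjs <- lapply(curves, function(cv) cv@band)
  recs <- list()
  for (d in season$dates) {
    ses <- season$sessions[[d]]
    for (side in c("panelBegin", "panelEnd")) {
      plot <- if (side == "panelBegin") "panel_begin" else "panel_end"
      recs[[paste(d, side)]] <- do.call(rbind, lapply(names(curves),
        function(bl) data.frame(
          date = d, plot = plot, organ = "panel:dark_gray", band = bl,
          mean_brf = measurePanelBrf(ses[[side]][[bl]], season$panel,
                                     curves[[bl]]),
          n_pixels = NA_integer_)))
    }
    for (k in seq_along(ses$canopy)) {
      pr <- processAcquisition(ses$canopy[[k]], ses$spectrum, curves,
                               geometry = NULL, earMask = earMask,
                               segConfig = segConfig)
      recs[[paste(d, "canopy", k)]] <-
        cbind(data.frame(date = d, plot = sprintf("plot%02d", k)),
              pr$records)
    }
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  if (correct)
    records <- correctRecords(records, season$panel, bandObjs,
                              direction = direction)
  records
}

#' Serialize a simulated campaign to disk
#'
#' Writes the directory tree the pipeline CLI consumes: `images/` (16-bit
#' DN TIFFs), `spectra/` (CSV), `panel/` (panel manifest + target CSVs),
#' `truth/` (label map and true ear mask), `manifest.csv` and
#' `config.yaml`. Timestamps are synthesized near local solar noon of each
#' date so the solar geometry is sane.
#'
#' @param season Output of [makeSeason()].
#' @param dir Output directory.
#' @param site List with `latitudeDeg`, `longitudeDeg`, `timezone`.
#' @return The manifest path, invisibly.
#' @export
writeCampaign <- function(season, dir,
                          site = list(latitudeDeg = 50.5639,
                                      longitudeDeg = 4.70,
                                      timezone = "Europe/Brussels")) {
  for (d in c("", "images", "spectra", "panel", "truth"))
    dir.create(file.path(dir, d), recursive = TRUE, showWarnings = FALSE)
  writePanelSpec(season$panel, file.path(dir, "panel"))
  writeLabelMap(LabelMap(labels = season$truth@labels),
                file.path(dir, "truth", "labels.tif"))
  earMaskPath <- ""
  if (any(season$truth@labels == ORGAN_CLASSES[["ear"]])) {
    earMaskPath <- file.path("truth", "ear_mask.tif")
    writeMask(season$truth@labels == ORGAN_CLASSES[["ear"]],
              file.path(dir, earMaskPath))
  }
  rows <- list()
  for (d in season$dates) {
    ses <- season$sessions[[d]]
    specRel <- file.path("spectra", paste0(d, ".csv"))
    writeSpectrum(ses$spectrum, file.path(dir, specRel))
    noon <- solarNoon(site$latitudeDeg, site$longitudeDeg, d,
                      site$timezone)
    stamp <- function(offMin) format(noon + offMin * 60,
                                     "%Y-%m-%dT%H:%M:%S%z")
    emit <- function(images, acq, plot, offMin, withEars) {
      for (bl in names(images)) {
        img <- images[[bl]]
        rel <- file.path("images", sprintf("%s_%s.tif", acq, bl))
        writeChannelImage(img, file.path(dir, rel))
        rows[[length(rows) + 1L]] <<- data.frame(
          acquisition = acq, plot = plot, band = bl, image = rel,
          exposure_time_s = img@exposureTimeS, spectrum = specRel,
          timestamp = stamp(offMin),
          ear_mask = if (withEars) earMaskPath else "")
      }
    }
    toImages <- function(shots) lapply(shots, function(s)
      ChannelImage(dn = s@dn, band = mcaBands()[[1]],  # band set per label below
                   exposureTimeS = s@exposureTimeS,
                   bitDepth = s@bitDepth))
    pb <- toImages(ses$panelBegin)
    for (bl in names(pb)) pb[[bl]]@band <- mcaBands()[[bl]]
    pe <- toImages(ses$panelEnd)
    for (bl in names(pe)) pe[[bl]]@band <- mcaBands()[[bl]]
    emit(pb, paste0(d, "_panelB"), "panel_begin", -120, FALSE)
    for (k in seq_along(ses$canopy))
      emit(ses$canopy[[k]], sprintf("%s_canopy%02d", d, k),
           sprintf("plot%02d", k), -60 + 10 * k, TRUE)
    emit(pe, paste0(d, "_panelE"), "panel_end", 120, FALSE)
  }
  man <- do.call(rbind, rows)
  manPath <- file.path(dir, "manifest.csv")
  utils::write.csv(man, manPath, row.names = FALSE)
  yaml::write_yaml(list(
    site = list(latitude_deg = site$latitudeDeg,
                longitude_deg = site$longitudeDeg,
                timezone = site$timezone),
    curve_degree = 2L, bit_depth = 10L),
    file.path(dir, "config.yaml"))
  invisible(manPath)
}
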