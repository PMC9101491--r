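## Solar ephemeris after the NOAA solar calculator (Meeus-based low-precision
## theory). Position is good to well under 0.1 deg and transit time to well
## under a minute for the 1900-2100 window, ample for acquisition planning
## and the cloudiness index.

.d2r <- pi / 180

.requireAwareTimestamp <- function(timestamp) {
  if (!inherits(timestamp, "POSIXct"))
    wbrfStop("timestamp must be POSIXct", "validationError")
  tz <- attr(timestamp, "tzone")
  if (is.null(tz) || !nzchar(tz[1]))
    wbrfStop(paste("timestamp must be timezone-aware: build it with an",
                   "explicit tz= (e.g. as.POSIXct(..., tz = 'UTC'))"),
             "validationError")
  invisible(timestamp)
}

## Equation of time (minutes) and solar declination (degrees) at a UTC instant.
.solarEphemeris <- function(tUtc) {
  jd <- as.numeric(tUtc) / 86400 + 2440587.5
  jc <- (jd - 2451545) / 36525
  L0 <- (280.46646 + jc * (36000.76983 + 0.0003032 * jc)) %% 360
  M  <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  ecc <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  C <- sin(M * .d2r) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(2 * M * .d2r) * (0.019993 - 0.000101 * jc) +
    sin(3 * M * .d2r) * 0.000289
  trueLong <- L0 + C
  omega <- (125.04 - 1934.136 * jc) * .d2r
  appLong <- trueLong - 0.00569 - 0.00478 * sin(omega)
  meanObliq <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 -
    jc * 0.001813))) / 60) / 60
  obliq <- meanObliq + 0.00256 * cos(omega)
  decl <- asin(sin(obliq * .d2r) * sin(appLong * .d2r)) / .d2r
  y <- tan(obliq / 2 * .d2r)^2
  eqTime <- 4 / .d2r * (y * sin(2 * L0 * .d2r) - 2 * ecc * sin(M * .d2r) +
    4 * ecc * y * sin(M * .d2r) * cos(2 * L0 * .d2r) -
    0.5 * y^2 * sin(4 * L0 * .d2r) - 1.25 * ecc^2 * sin(2 * M * .d2r))
  list(eqTimeMin = eqTime, declinationDeg = decl)
}

#' Sun position at an instant and site
#'
#' Computes the sun's zenith and azimuth angle with the NOAA solar
#' calculator algorithm. The returned zenith is the geometric
#' (unrefracted) angle; atmospheric refraction only matters within a
#' fraction of a degree of the horizon.
#'
#' @param latitudeDeg Site latitude in degrees (north positive).
#' @param longitudeDeg Site longitude in degrees (east positive).
#' @param timestamp A timezone-aware `POSIXct` instant. Naive timestamps
#'   (no `tzone` attribute) are rejected, because an ambiguous clock time
#'   silently shifts the geometry by hours.
#' @return A [SunGeometry] with zenith and azimuth in degrees, accurate to
#'   well within 0.5 degrees.
#' @examples
#' t <- as.POSIXct("2021-06-23 13:43", tz = "Europe/Brussels")
#' sunPosition(50.5639, 4.70, t)
#' @seealso [solarNoon()], [cloudinessIndex()]
#' @export
sunPosition <- function(latitudeDeg, longitudeDeg, timestamp) {
  .requireAwareTimestamp(timestamp)
  if (abs(latitudeDeg) > 90 || abs(longitudeDeg) > 360)
    wbrfStop("invalid coordinates", "validationError")
  eph <- .solarEphemeris(timestamp)
  minsUtc <- (as.numeric(timestamp) %% 86400) / 60
  trueSolarMin <- (minsUtc + eph$eqTimeMin + 4 * longitudeDeg) %% 1440
  hourAngle <- trueSolarMin / 4 - 180
  if (hourAngle < -180) hourAngle <- hourAngle + 360
  latR <- latitudeDeg * .d2r
  declR <- eph$declinationDeg * .d2r
  cosZen <- sin(latR) * sin(declR) +
    cos(latR) * cos(declR) * cos(hourAngle * .d2r)
  cosZen <- min(1, max(-1, cosZen))
  zen <- acos(cosZen) / .d2r
  ## azimuth, degrees clockwise from north
  denom <- cos(latR) * sin(zen * .d2r)
  if (abs(denom) < 1e-12) {
    az <- 180  # sun at zenith/nadir: azimuth undefined, report due south
  } else {
    cosAz <- (sin(latR) * cosZen - sin(declR)) / denom
    cosAz <- min(1, max(-1, cosAz))
    az <- if (hourAngle > 0) (acos(cosAz) / .d2r + 180) %% 360
          else (540 - acos(cosAz) / .d2r) %% 360
  }
  SunGeometry(zenithDeg = zen, azimuthDeg = az, timestamp = timestamp,
              latitudeDeg = latitudeDeg, longitudeDeg = longitudeDeg)
}

#' Local clock time of solar transit
#'
#' Computes the instant of solar noon (the daily minimum of the sun zenith
#' angle) for a site and date, in the requested timezone, by iterating the
#' NOAA equation of time at the transit estimate.
#'
#' @param latitudeDeg,longitudeDeg Site coordinates (degrees, east
#'   positive).
#' @param date A `Date` or `"YYYY-MM-DD"` string (civil date at the site).
#' @param tz Olson timezone name for the returned clock time, e.g.
#'   `"Europe/Brussels"`.
#' @return A timezone-aware `POSIXct` of the transit, accurate to well
#'   within 2 minutes. In polar night (sun below the horizon even at
#'   transit) a `polarWarning` is signalled; the transit instant itself is
#'   still returned.
#' @examples
#' solarNoon(50.5639, 4.70, "2021-06-23", "Europe/Brussels")
#' @export
solarNoon <- function(latitudeDeg, longitudeDeg, date, tz = "UTC") {
  if (!tz %in% OlsonNames() && tz != "UTC")
    wbrfStop(sprintf("unknown timezone '%s'", tz), "validationError")
  date <- as.Date(date)
  midnightUtc <- as.POSIXct(paste(format(date), "00:00:00"), tz = "UTC")
  noonUtcMin <- 720 - 4 * longitudeDeg
  for (i in 1:3) {
    eph <- .solarEphemeris(midnightUtc + noonUtcMin * 60)
    noonUtcMin <- 720 - 4 * longitudeDeg - eph$eqTimeMin
  }
  transit <- midnightUtc + noonUtcMin * 60
  attr(transit, "tzone") <- tz
  geo <- sunPosition(latitudeDeg, longitudeDeg, transit)
  if (geo@zenithDeg >= 90)
    wbrfWarn(sprintf(
      "polar night: sun below horizon even at transit (zenith %.1f deg)",
      geo@zenithDeg), "polarWarning")
  transit
}
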