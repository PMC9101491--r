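---
title: "Organ-scale wheat reflectance: models, conventions and design choices"
author: "wheatBRF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Organ-scale wheat reflectance: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wheatBRF)
```

## The measurement problem

Canopy reflectance measured in the field mixes the signal of wheat leaves,
ears and the soil background, while the incident sunlight changes from
minute to minute. wheatBRF implements a measurement chain that turns raw
digital numbers (DN) from a nadir-pointing multispectral camera array into
bi-directional reflectance factors (BRF) per canopy organ, using an
up-facing incident-light spectrometer instead of a reference panel in
every image.

The BRF is the ratio of the radiance a surface reflects to what an ideal
Lambertian reflector would reflect under the same illumination and
viewing geometry:

$$\rho(\omega_i, \omega_r, \lambda) \;=\; \frac{L(\omega_r, \lambda)\,\pi}{E(\omega_i, \lambda)}$$

with $L$ the reflected radiance (W m$^{-2}$ sr$^{-1}$), $E$ the incident
irradiance (W m$^{-2}$), and $\omega_i$, $\omega_r$ the illumination and
viewing directions. Under natural light the incident field always mixes a
direct and a diffuse component, so the measured quantity is an
approximated BRF; we keep the conventional name.

## The radiometric chain

**Camera response curves.** A camera's DN respond to the exposure at the
sensor, $H = E_{img}\,t$, which is proportional to scene radiance for a
fixed optical configuration. We therefore fit a *modified response curve*
against the exposure referenced at the lens entrance,

$$H_{lens} = L\,t,$$

which absorbs the (wavelength-dependent) transmission of the filter and
objective into the fitted coefficients instead of modelling it
separately. Calibration uses a four-target diffuse reference panel
(black, dark gray, light gray, white) of known reflectance spectra: for a
panel shot at exposure time $t$ under band irradiance $E$,

$$H_{lens} = \frac{\rho\,E\,t}{\pi},$$

so each (shot, target) pair contributes one $(\overline{DN}, H_{lens})$
point, with $\overline{DN}$ the mean over the target's region of
interest. A calibration campaign takes 50 shots at distinct exposure
times, giving up to 200 points per band, pooled across targets and fitted
by unweighted least squares (the pooling is a deliberate choice; nothing
in the data suggested weighting by target).

Three conventions matter here:

* **The DN-intercept is forced to zero.** A free intercept can put small
  DN below the intercept and produce negative exposures downstream; the
  origin constraint removes that failure mode by construction.
* **The polynomial degree defaults to 2** (configurable in 1-3). Sensor
  responses are near-linear but can curve; degree 2 captures that without
  inviting oscillation. A fitted curve must be strictly increasing over
  the data range - a non-monotone fit is rejected with advice to lower
  the degree, because a non-invertible response has no physical reading.
* **A target is "saturated" when more than 1% of its ROI pixels sit at
  the bit-depth maximum**, and is then excluded from the point cloud.
  In practice the white target saturates first under long exposures (the
  auto-exposure of a real array is tuned to the crop, not to a bright
  panel), and the calibration must survive losing it.

**DN to BRF.** With a fitted curve $H_{lens}(DN)$, a canopy image taken
at exposure time $t$ under a measured incident spectrum converts per
pixel as

$$BRF = \frac{\pi\,H_{lens}(DN)}{E_{band}\,t},$$

where $E_{band}$ integrates the spectrum over the ideal filter window
$[c - w/2,\, c + w/2]$ (unit transmission inside, zero outside). The
stock band set is 490, 550, 680, 720, 800 and 900 nm, 10 nm wide except
20 nm at 900 nm. Because $H_{lens} \propto t$ and $\propto E$, the BRF is
invariant to the auto-exposure setting and to uniform changes of
illumination - the two properties that make values comparable across a
day.

Band integrals use the trapezoid rule on the spectrometer's native grid,
with linear interpolation only at the two band edges: resampling a
measured spectrum to a finer grid would invent resolution the instrument
does not have.

A 5x5 arithmetic-mean blur (`blurChannel()`) is available to dampen
band-to-band registration residuals and is applied by the full pipeline
(`processAcquisition()`, `runPipeline()`) to the DN channels feeding BRF
conversion. The mean (rather than a Gaussian) was chosen so the filter
has an exact, testable algebra. Two placement decisions were open and are
now fixed: the blur runs *before* DN-to-BRF conversion (configurable),
and the segmentation thresholds below operate on the *unblurred* DN
channels - blurring first would smear class boundaries across the
threshold and cost several percent of pixel accuracy regardless of how
separable the classes are.

## Cloudiness and solar geometry

The sky state is summarised by the cloudiness index

$$C_T = 1 - \frac{E}{E_0 \cos z}, \qquad E_0 = 1360\ \mathrm{W\,m^{-2}},$$

with $E$ the measured irradiance over the spectrometer's full spectral
range (recorded in the output metadata for comparability) and $z$ the sun
zenith angle. Clear skies give small $C_T$; heavy overcast approaches 1.
The segmentation gate (below) uses the empirical threshold 0.90: direct
sunlight is declared when $C_T < 0.90$. The inequality direction is a
package decision (the threshold itself is standard but its sense is easy
to state ambiguously): $E$ close to $E_0 \cos z$ *is* strong direct sun.

Sun position and solar transit come from the NOAA solar calculator
algorithm (a Meeus-based low-precision theory), implemented in
`sunPosition()` and `solarNoon()`: position is good to well under 0.1
degrees and transit to well under a minute in the 1900-2100 window, which
comfortably supports the minute-level checks the method needs.
Timestamps must be timezone-aware everywhere; a naive clock time can
shift the geometry by hours, so it is rejected rather than guessed. The
reported zenith is the geometric (unrefracted) angle; refraction only
matters within a fraction of a degree of the horizon, far from any
usable acquisition geometry. One practical note: acquisition guidance in
terms of "zenith above/below" thresholds is easy to invert accidentally,
so the utilities report the raw zenith angle and leave interpretation to
the user.

## Segmentation at the organ scale

Three classes: background (soil), leaf (leaves plus visible stems), ear.

**Step 1 - background vs vegetation.** Wheat is much brighter than soil
in the near infrared, so a threshold in the 800 nm channel separates
them. The threshold is automatic per image: the first local minimum of
the smoothed DN histogram, scanning from low values. Histogram
construction is a package decision: 256 bins over the observed range
(capped at the number of distinct values, so integer DN over a narrow
range cannot produce a comb of empty bins), smoothed by a 5-bin moving
average. A candidate minimum only counts as a valley if the histogram
rises to at least 1.5x the valley count on both sides *and* each side
holds at least 2% of the pixels; both guards exist because sampling noise
dents unimodal histograms with shallow dips that must not become
thresholds. When no valley exists (an all-vegetation plot, say), the
function signals `noValleyError` and the caller falls back to Otsu's
threshold with a logged warning.

**The cloudiness gate.** Under strong direct sunlight ($C_T < 0.90$),
sunlit soil patches can reach the same NIR digital numbers as shaded
leaves, and the NIR threshold alone confuses them. Two auxiliary tests
then discriminate among the low-NIR candidate vegetation pixels: soil is
bright in the blue channel where leaves are dark, and soil is red-ish
where leaves are green, measured by the Excess Red index

$$ExR = 1.4\,r - g$$

on chromatic (normalized) red/green coordinates. A candidate pixel is
kept as vegetation only if it passes both tests (blue below, ExR below
their thresholds); this removes sunlit soil and can never add pixels the
NIR threshold rejected, so tightening the gate is monotone. The blue and
ExR thresholds have no universal values - they depend on the site, the
sensor and the scale the channels are expressed in - so they are
required configuration; the package defaults are calibrated on its own
simulator and must be re-tuned for real acquisitions. Whether the tests
apply to all candidate pixels or only below a NIR ceiling is
configurable (`auxNirMax`; default all - true vegetation passes them
anyway). The auxiliary tests run on DN by convention (thresholding
precedes BRF pooling in the processing order), also configurable by
simply passing BRF rasters instead.

**Step 2 - ears.** Ear detection is deliberately an *input contract*:
modern detectors are deep-learning models far outside this package's
scope, and any of them can supply a binary ear mask aligned to the
stack. `applyEarMask()` then applies pure set algebra: ear = mask AND
vegetation, leaf = vegetation AND NOT ear, background = NOT vegetation.
Ear pixels claimed on background stay background, and a mask with zero
vegetation overlap raises a registration warning. Class counts always
partition the image.

**Organ pooling.** `organMeanBrf()` averages unsaturated pixels of one
class per band and reports the pixel count; an empty class is an explicit
error rather than a propagating `NaN`. The area-weighted leaf and ear
means recompose the vegetation mean exactly.

## Inter-date panel correction

BRF of a stable reference target is flat within a day but shifts between
dates - plausibly from small changes in the acquisition configuration
(cosine-corrector orientation, camera mounting, panel placement), not
sensor drift. The remedy is empirical: photograph the panel at the start
and end of each session, and scale that date's organ BRF by a per-band
factor derived from the dark-gray target (the dark-gray choice avoids
both white-target saturation and black-target noise; it is configurable).

The begin/end pair is combined by a consistency rule: if the two values
differ by no more than 3% (relative to their mean - a relative reading,
since BRF scales differ across bands), use their mean; if they diverge
more, one of them is presumed corrupted (panel mis-placement, a leaf over
the target) and only the value closest to the theoretical reference is
used.

The factor's direction deserves a note. Multiplying by
*measured/theoretical* would amplify a session's radiometric bias;
multiplying by *theoretical/measured* cancels it, and makes the corrected
panel measurement land exactly on the reference (idempotence). The
package default is the corrective direction; the other is available as
`direction = "literal"` for comparison with descriptions that phrase the
ratio the other way, and is not silently reinterpreted anywhere.
Correction is non-destructive (raw value and factor are kept as columns)
and commutes with organ averaging.

## The forward simulator

Every stage above is testable without field data because the package
ships a forward simulator that shares no inversion code with the
analysis: scene DN are produced by *solving* the camera's true response
polynomial (closed form up to degree 2, bisection above), never by
evaluating a fitted curve, so round trips are genuine.

What it emulates:

* **Spectra** (`makeSpectrum()`): smooth positive daylight-like curves
  over 400-1000 nm at 1 nm, scaled so the full-range integral realises a
  target cloudiness index - 0.25 for "sunny", 0.75 for "mixed" (both
  below the 0.90 gate), 0.96 for "cloudy" - with small seeded spectral
  jitter.
* **Scenes** (`makeSceneTruth()`): patchy organ structure from smooth
  random fields, defaults 60x80 px, 35% soil, 15% ears. Class spectra
  are piecewise-linear templates: a leaf with a red edge rising to a
  0.45 NIR plateau, an ear of the same shape plateauing near 0.35, a
  nearly flat soil around 0.15. These are field-plausible simulator
  defaults, not measurements of any particular crop.
* **The camera** (`defaultCameraModel()`): six bands with band-to-band
  sensitivity differences, a mildly curved true response (the quadratic
  term contributes ~15% at full scale), 10-bit depth, multiplicative
  Gaussian DN noise (the dominant photon/gain noise at these exposure
  levels), saturation clipping.
* **Calibration campaigns** (`makeCalibrationSeries()`): 50 log-spaced
  exposure times, optional forced white-target saturation to exercise
  the exclusion path.
* **Seasons** (`makeSeason()`): per date a begin panel shot, canopy
  acquisitions and an end panel shot, all under a per-date radiometric
  gain drift applied to the exposure reaching the sensor - the
  mechanism that makes dates disagree and the panel correction
  worthwhile.
* **Shading** (the `illumination` argument of `renderAcquisition()` and
  `renderChromatic()`): a per-pixel irradiance factor that scales
  radiance but cancels in chromatic coordinates, reproducing the
  sunlit-soil / shaded-leaf ambiguity the auxiliary thresholds exist
  for.

What it does **not** emulate: BRDF anisotropy, shadows cast between
organs, multiple scattering, registration error between bands, or any
radiative-transfer realism. Passing tests therefore demonstrate that the
*measurement chain* is self-consistent and that its inversions are
exact, not that the segmentation thresholds or organ spectra transfer to
a real field unchanged.

### Quantization and the zero-noise contracts

Real DN are integers. Rounding alone injects up to half a DN of error
per pixel, which is invisible in organ means over thousands of pixels
but dominates two strict guarantees the package makes in the noiseless
regime: exact recovery of the camera coefficients from a calibration
series, and bit-for-bit equality of BRF maps under exposure doubling or
uniform irradiance scaling. "Noiseless" is therefore read as *including
no quantization* for those checks: the calibration generator quantizes
only when sensor noise is on, and `renderAcquisition(quantize = FALSE)`
models the ideal sensor. The bit-equality checks additionally use
power-of-two scalings (which commute exactly with floating-point
arithmetic) and a linear true response - a curved response inverts
through a square root whose rounding breaks bitwise equality at the
10^-16 level while leaving the physics untouched. With quantization on,
the same invariances hold to DN rounding error (below 2% per pixel at
realistic levels, and far below that in organ means).

## Numerical choices and degenerate inputs

* Band integration: trapezoid on the native grid; a band extending
  beyond the spectrum's coverage is a `coverageError` naming the band.
* Valley search ties break toward the lower bin (the scan order makes
  the first qualifying bin the lowest).
* `cloudinessIndex()` refuses a sun at or below the horizon
  (cos z <= 0 has no reading as a sky state).
* All-zero or constant rasters: thresholding signals no-valley; organ
  means on an absent class are explicit errors.
* Saturated pixels keep their (extrapolated) BRF value but are masked
  and excluded from every organ mean.
* DN above a curve's fit domain are evaluated but flagged as
  extrapolation.
* Reruns are deterministic: every stochastic step takes a seed, and the
  pipeline writes its CSVs with fixed formatting so reruns are
  byte-identical.

## Problem sizes

The shipped tests and the acceptance script run the full chain on 60x80
px scenes, 50-shot calibration series and six-date seasons. These sizes
were chosen because every quantity the chain certifies - coefficient
recovery, organ-mean accuracy, segmentation accuracy, drift-corrected
CV - is already stable at them; the implementation is vectorised and the
same code runs unchanged on megapixel rasters.

## Known limitations

* The package assumes co-registered band images; registration itself
  (and stereovision) is upstream.
* Ear masks come from an external detector; their quality bounds the
  leaf/ear split.
* The auxiliary segmentation thresholds are site-specific configuration,
  not universal constants.
* The panel correction removes a per-date multiplicative bias; it cannot
  fix within-session illumination-geometry effects (low-sun mornings
  under clear sky), for which the operational advice stands: acquire
  close to solar noon or under overcast skies.
* Absolute BRF accuracy is bounded by the reference panel
  characterisation; the method is at its best for relative dynamics
  across a season.
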