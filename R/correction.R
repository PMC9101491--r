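## Inter-date correction of organ BRF against the dark-gray reference
## target measured at the start and end of each field session.

#' Representative panel BRF of a session
#'
#' Combines the begin and end measurements of the reference target for one
#' band. When the two agree (relative difference with respect to their mean
#' at most `relTol`, default 3\%) the arithmetic mean is used; when they
#' diverge more than that, one of them is considered unreliable (panel
#' mis-placement, a leaf over the target...) and only the value closest to
#' the theoretical reference BRF is kept. With a single measurement
#' available, that value is returned as is.
#'
#' @param check A [PanelCheck].
#' @param relTol Relative begin/end tolerance (default 0.03).
#' @return The representative measured BRF, with attribute `"rule"`
#'   recording which branch was taken (`"mean"`, `"closest"`, `"single"`).
#' @examples
#' sessionPanelBrf(PanelCheck(band = "800", brfBegin = 0.20, brfEnd = 0.22,
#'                            brfTheoretical = 0.19))  # 0.20, rule "closest"
#' @export
sessionPanelBrf <- function(check, relTol = 0.03) {
  stopifnot(is(check, "PanelCheck"))
  b <- check@brfBegin; e <- check@brfEnd
  hasB <- length(b) == 1L && !is.na(b)
  hasE <- length(e) == 1L && !is.na(e)
  if (!hasB && !hasE)
    wbrfStop(sprintf(
      "band '%s': neither begin nor end panel measurement available,
correction impossible", check@band), "correctionError")
  if (hasB && hasE) {
    m <- mean(c(b, e))
    if (m > 0 && abs(b - e) / m <= relTol) {
      out <- m
      attr(out, "rule") <- "mean"
    } else {
      out <- if (abs(b - check@brfTheoretical) <=
                   abs(e - check@brfTheoretical)) b else e
      attr(out, "rule") <- "closest"
    }
  } else {
    out <- if (hasB) b else e
    attr(out, "rule") <- "single"
  }
  out
}

#' Inter-date correction factor
#'
#' The multiplicative factor applied to organ BRF of a date, from the
#' session's representative panel measurement and the theoretical
#' band-integrated reference reflectance. The default direction,
#' `theoretical / measured`, cancels the session's radiometric bias: the
#' corrected panel measurement lands exactly on the reference. The
#' `"literal"` direction (`measured / theoretical`) is also available for
#' comparison with descriptions that phrase the ratio the other way
#' around; note it amplifies rather than removes the bias.
#'
#' @param measured Representative measured panel BRF (> 0), e.g. from
#'   [sessionPanelBrf()].
#' @param theoretical Band-integrated reference reflectance (> 0).
#' @param direction `"corrective"` (default) or `"literal"`.
#' @return The correction factor (1 when measured equals theoretical).
#' @export
correctionFactor <- function(measured, theoretical,
                             direction = c("corrective", "literal")) {
  direction <- match.arg(direction)
  if (any(measured <= 0) || any(theoretical <= 0))
    wbrfStop("measured and theoretical BRF must be > 0", "validationError")
  if (direction == "corrective") theoretical / measured
  else measured / theoretical
}

#' Apply per-band correction factors to organ records
#'
#' Multiplies each record's mean BRF by its band's factor,
#' non-destructively: the original value is kept in `mean_brf_raw`, the
#' factor in `correction_factor`, and `corrected` is set to `TRUE`.
#'
#' @param records A `data.frame` with at least columns `band` and
#'   `mean_brf` (as produced by [organMeanBrf()] or the pipeline CSV).
#' @param factors Named numeric vector of per-band factors; every band
#'   present in `records` must have one.
#' @return The corrected `data.frame`.
#' @export
applyCorrection <- function(records, factors) {
  if (!all(c("band", "mean_brf") %in% names(records)))
    wbrfStop("records must have columns band and mean_brf",
             "validationError")
  bandsPresent <- unique(as.character(records$band))
  missing <- setdiff(bandsPresent, names(factors))
  if (length(missing))
    wbrfStop(sprintf("no correction factor for band(s): %s",
                     paste(missing, collapse = ", ")), "correctionError")
  f <- as.numeric(factors[as.character(records$band)])
  records$mean_brf_raw <- records$mean_brf
  records$correction_factor <- f
  records$mean_brf <- records$mean_brf * f
  records$corrected <- TRUE
  records
}
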