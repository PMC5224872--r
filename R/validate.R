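## Full rhythm-validation chain: quality gate -> spectral detection ->
## Cosinor validation -> residual reinjection for secondary periodicities.

#' Classify a period as ultradian, circadian or infradian
#'
#' Circadian covers 20-28 h inclusive on both sides, ultradian is below 20 h
#' and infradian above 28 h.
#'
#' @param tau period(s) in hours, > 0.
#' @return character vector of classifications.
#' @export
classifyPeriod <- function(tau) {
  if (any(tau <= 0)) stop("period must be positive")
  ifelse(tau < 20, "ultradian", ifelse(tau <= 28, "circadian", "infradian"))
}

arrhythmicReport <- function(id, reason) {
  new("RhythmReport", individualId = id, validated = list(), rhythmic = FALSE,
      classification = "arrhythmic", reason = reason)
}

#' Validate the rhythm(s) of one series
#'
#' Runs the whole chain: the autocorrelation quality gate; Lomb-Scargle
#' spectral analysis; a Cosinor fit at the strongest significant period,
#' accepted when the elliptic test excludes the origin AND the zero-amplitude
#' p-value is below `alpha`; then residual reinjection — the accepted
#' component is removed and the residual series re-enters the spectral step —
#' until no significant period remains, a fit is rejected, or
#' `maxComponents` components have been validated. Any stage failure (e.g.
#' too few samples, zero variance) yields an arrhythmic report carrying the
#' reason rather than an error.
#'
#' @param series a [ValveSeries-class] or numeric vector.
#' @param alpha significance level of the amplitude test (default 0.05).
#' @param maxComponents cap on validated components (default 3).
#' @param periods trial-period grid passed to [lombScargle()].
#' @return a [RhythmReport-class].
#' @export
validateRhythm <- function(series, alpha = 0.05, maxComponents = 3,
                           periods = seq(2, 36, by = 0.1)) {
  id <- if (is(series, "ValveSeries")) series@individualId else "series"
  ty <- asTY(series)
  t <- ty$t; y <- ty$y

  q <- tryCatch(qualityCheck(y), error = function(e) e)
  if (inherits(q, "error")) return(arrhythmicReport(id, conditionMessage(q)))
  if (!q@passes)
    return(arrhythmicReport(id, "failed autocorrelation quality check"))

  cur <- list(times = t, values = y)
  fits <- list()
  while (length(fits) < maxComponents) {
    ls <- tryCatch(lombScargle(cur, periods = periods, alpha = alpha),
                   error = function(e) e)
    if (inherits(ls, "error")) break
    if (!length(ls@significantPeriods)) break
    tau <- ls@significantPeriods[1]
    fit <- tryCatch(
      withCallingHandlers(
        fitCosinor(cur, tau = tau),
        warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) e)
    if (inherits(fit, "error")) break
    if (!(fit@ellipseExcludesOrigin && fit@pAmplitude < alpha)) break
    fits[[length(fits) + 1L]] <- fit
    # reinject residuals (mesor retained so the series keeps its level)
    cur <- list(times = t, values = fit@residuals + fit@mesor)
  }
  if (!length(fits))
    return(arrhythmicReport(id, "no statistically validated periodicity"))
  new("RhythmReport", individualId = id, validated = fits, rhythmic = TRUE,
      classification = classifyPeriod(fits[[1]]@tau), reason = "")
}

#' Population-level rhythm summary of a panel
#'
#' Validates the per-timestamp population mean series and every individual
#' series, and reports the percentage of rhythmic individuals and, among
#' those, the percentage whose primary period is circadian.
#'
#' @param panel a [ValveActivityPanel-class].
#' @param alpha significance level (default 0.05).
#' @param ... passed to [validateRhythm()].
#' @return a [PopulationRhythmReport-class].
#' @export
populationSummary <- function(panel, alpha = 0.05, ...) {
  stopifnot(is(panel, "ValveActivityPanel"))
  n <- ncol(panel@activity)
  if (n < 1) stop("empty panel")
  groupReport <- validateRhythm(meanSeries(panel), alpha = alpha, ...)
  per <- lapply(seq_len(n), function(i)
    validateRhythm(valveSeries(panel, i), alpha = alpha, ...))
  rhythmic <- vapply(per, function(r) r@rhythmic, logical(1))
  pct <- 100 * sum(rhythmic) / n
  circ <- if (any(rhythmic))
    100 * mean(vapply(per[rhythmic], function(r)
      r@classification == "circadian", logical(1)))
  else NA_real_
  new("PopulationRhythmReport", groupReport = groupReport,
      pctRhythmic = pct, pctCircadianAmongRhythmic = circ,
      perIndividual = per)
}
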