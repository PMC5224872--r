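#' @describeIn ValveActivityPanel-class compact display
#' @param object the object to display.
#' @export
setMethod("show", "ValveActivityPanel", function(object) {
  cat(sprintf("ValveActivityPanel: %d individuals x %d time points (%s), %.1f-%.1f h\n",
              ncol(object@activity), length(object@times),
              paste(unique(object@regime), collapse = "/"),
              min(object@times), max(object@times)))
})

#' @describeIn ValveSeries-class compact display
#' @param object the object to display.
#' @export
setMethod("show", "ValveSeries", function(object) {
  cat(sprintf("ValveSeries '%s': %d samples (%s), mean opening %.1f%%\n",
              object@individualId, length(object@values),
              paste(unique(object@regime), collapse = "/"),
              mean(object@values, na.rm = TRUE)))
})

#' @describeIn CosinorFit-class compact display
#' @param object the object to display.
#' @export
setMethod("show", "CosinorFit", function(object) {
  cat(sprintf("CosinorFit: tau = %.2f h [%.2f, %.2f], A = %.2f, phi = %.2f rad, M = %.2f\n",
              object@tau, object@tauCI[1], object@tauCI[2], object@amplitude,
              object@acrophase, object@mesor))
  cat(sprintf("  PR = %.1f%%, p(amplitude) = %.3g, ellipse excludes origin: %s\n",
              object@pr, object@pAmplitude, object@ellipseExcludesOrigin))
})

#' @describeIn RhythmReport-class compact display
#' @param object the object to display.
#' @export
setMethod("show", "RhythmReport", function(object) {
  if (object@rhythmic) {
    taus <- vapply(object@validated, function(f) f@tau, numeric(1))
    cat(sprintf("RhythmReport '%s': rhythmic (%s), periods %s h\n",
                object@individualId, object@classification,
                paste(sprintf("%.1f", taus), collapse = ", ")))
  } else {
    cat(sprintf("RhythmReport '%s': arrhythmic (%s)\n",
                object@individualId, object@reason))
  }
})

#' @describeIn PopulationRhythmReport-class compact display
#' @param object the object to display.
#' @export
setMethod("show", "PopulationRhythmReport", function(object) {
  cat(sprintf("PopulationRhythmReport: %d individuals, %.1f%% rhythmic",
              length(object@perIndividual), object@pctRhythmic))
  if (!is.na(object@pctCircadianAmongRhythmic))
    cat(sprintf(" (%.1f%% circadian among rhythmic)",
                object@pctCircadianAmongRhythmic))
  cat("\n  population mean series: ")
  show(object@groupReport)
})

#' @describeIn PeriodogramResult-class compact display
#' @param object the object to display.
#' @export
setMethod("show", "PeriodogramResult", function(object) {
  cat(sprintf("PeriodogramResult: %d periods (%.1f-%.1f h), threshold %.2f\n",
              length(object@periods), min(object@periods), max(object@periods),
              object@threshold))
  if (length(object@significantPeriods))
    cat("  significant periods (h):",
        paste(sprintf("%.1f", object@significantPeriods), collapse = ", "), "\n")
  else cat("  no significant periods\n")
})

#' @describeIn QualityReport-class compact display
#' @param object the object to display.
#' @export
setMethod("show", "QualityReport", function(object) {
  cat(sprintf("QualityReport: band +/-%.3f, nonrandom: %s, passes: %s\n",
              object@band, object@nonrandom, object@passes))
})

#' @describeIn ActogramGrid-class compact display
#' @param object the object to display.
#' @export
setMethod("show", "ActogramGrid", function(object) {
  cat(sprintf("ActogramGrid: %d rows x %d bins (%.1f h/bin), %s\n",
              nrow(object@grid), ncol(object@grid), object@binHours,
              if (object@doublePlot) "double-plotted" else "single-plotted"))
})

#' @describeIn CorrelationMatrix-class compact display
#' @param object the object to display.
#' @export
setMethod("show", "CorrelationMatrix", function(object) {
  cat(sprintf("CorrelationMatrix: %d genes, n = %d samples (Spearman)\n",
              nrow(object@rho), object@n))
})

#' @describeIn GeneGroups-class compact display
#' @param object the object to display.
#' @export
setMethod("show", "GeneGroups", function(object) {
  tab <- table(object@assignment)
  cat(sprintf("GeneGroups: %d genes in %d group(s) [%s]\n",
              length(object@assignment), length(tab),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
})

#' @describeIn OpenReadingFrame-class compact display
#' @param object the object to display.
#' @export
setMethod("show", "OpenReadingFrame", function(object) {
  if (object@lengthBp > 0)
    cat(sprintf("OpenReadingFrame: %d-%d (+), %d bp, %d codons\n",
                object@start, object@end, object@lengthBp,
                object@lengthBp %/% 3L))
  else cat("OpenReadingFrame: none found\n")
})
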