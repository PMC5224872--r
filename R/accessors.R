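## Accessor generics: users read results through these rather than slots.

#' @name accessors
#' @title Accessors for oysterClock result objects
#' @description Small accessor generics for the package's S4 result classes.
#' @param x an oysterClock object.
#' @return the requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("activityTimes", function(x) standardGeneric("activityTimes"))
#' @rdname accessors
#' @export
setMethod("activityTimes", "ValveActivityPanel", function(x) x@times)
#' @rdname accessors
#' @export
setMethod("activityTimes", "ValveSeries", function(x) x@times)

#' @rdname accessors
#' @export
setGeneric("activityValues", function(x) standardGeneric("activityValues"))
#' @rdname accessors
#' @export
setMethod("activityValues", "ValveActivityPanel", function(x) x@activity)
#' @rdname accessors
#' @export
setMethod("activityValues", "ValveSeries", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("regimeLabels", function(x) standardGeneric("regimeLabels"))
#' @rdname accessors
#' @export
setMethod("regimeLabels", "ValveActivityPanel", function(x) x@regime)
#' @rdname accessors
#' @export
setMethod("regimeLabels", "ValveSeries", function(x) x@regime)

#' @rdname accessors
#' @export
setGeneric("periodHours", function(x) standardGeneric("periodHours"))
#' @rdname accessors
#' @export
setMethod("periodHours", "CosinorFit", function(x) x@tau)
#' @rdname accessors
#' @export
setMethod("periodHours", "RhythmReport", function(x)
  vapply(x@validated, function(f) f@tau, numeric(1)))

#' @rdname accessors
#' @export
setGeneric("amplitude", function(x) standardGeneric("amplitude"))
#' @rdname accessors
#' @export
setMethod("amplitude", "CosinorFit", function(x) x@amplitude)

#' @rdname accessors
#' @export
setGeneric("acrophase", function(x) standardGeneric("acrophase"))
#' @rdname accessors
#' @export
setMethod("acrophase", "CosinorFit", function(x) x@acrophase)

#' @rdname accessors
#' @export
setGeneric("mesor", function(x) standardGeneric("mesor"))
#' @rdname accessors
#' @export
setMethod("mesor", "CosinorFit", function(x) x@mesor)

#' @rdname accessors
#' @export
setGeneric("percentRhythm", function(x) standardGeneric("percentRhythm"))
#' @rdname accessors
#' @export
setMethod("percentRhythm", "CosinorFit", function(x) x@pr)

#' @rdname accessors
#' @export
setGeneric("periodCI", function(x) standardGeneric("periodCI"))
#' @rdname accessors
#' @export
setMethod("periodCI", "CosinorFit", function(x) x@tauCI)

#' @rdname accessors
#' @export
setGeneric("isRhythmic", function(x) standardGeneric("isRhythmic"))
#' @rdname accessors
#' @export
setMethod("isRhythmic", "RhythmReport", function(x) x@rhythmic)

#' @rdname accessors
#' @export
setGeneric("validatedFits", function(x) standardGeneric("validatedFits"))
#' @rdname accessors
#' @export
setMethod("validatedFits", "RhythmReport", function(x) x@validated)

#' @rdname accessors
#' @export
setGeneric("rhythmClass", function(x) standardGeneric("rhythmClass"))
#' @rdname accessors
#' @export
setMethod("rhythmClass", "RhythmReport", function(x) x@classification)

#' @rdname accessors
#' @export
setGeneric("pctRhythmic", function(x) standardGeneric("pctRhythmic"))
#' @rdname accessors
#' @export
setMethod("pctRhythmic", "PopulationRhythmReport", function(x) x@pctRhythmic)

#' @rdname accessors
#' @export
setGeneric("pctCircadian", function(x) standardGeneric("pctCircadian"))
#' @rdname accessors
#' @export
setMethod("pctCircadian", "PopulationRhythmReport",
          function(x) x@pctCircadianAmongRhythmic)

#' @rdname accessors
#' @export
setGeneric("individualReports", function(x) standardGeneric("individualReports"))
#' @rdname accessors
#' @export
setMethod("individualReports", "PopulationRhythmReport",
          function(x) x@perIndividual)

#' @rdname accessors
#' @export
setGeneric("groupReport", function(x) standardGeneric("groupReport"))
#' @rdname accessors
#' @export
setMethod("groupReport", "PopulationRhythmReport", function(x) x@groupReport)

#' @rdname accessors
#' @export
setGeneric("significantPeriods", function(x) standardGeneric("significantPeriods"))
#' @rdname accessors
#' @export
setMethod("significantPeriods", "PeriodogramResult",
          function(x) x@significantPeriods)

#' @rdname accessors
#' @export
setGeneric("powerSpectrum", function(x) standardGeneric("powerSpectrum"))
#' @rdname accessors
#' @export
setMethod("powerSpectrum", "PeriodogramResult", function(x)
  data.frame(period_h = x@periods, power = x@power, threshold = x@threshold))

#' @rdname accessors
#' @export
setGeneric("spearmanRho", function(x) standardGeneric("spearmanRho"))
#' @rdname accessors
#' @export
setMethod("spearmanRho", "CorrelationMatrix", function(x) x@rho)

#' @rdname accessors
#' @export
setGeneric("spearmanP", function(x) standardGeneric("spearmanP"))
#' @rdname accessors
#' @export
setMethod("spearmanP", "CorrelationMatrix", function(x) x@p)

#' @rdname accessors
#' @export
setGeneric("groupAssignment", function(x) standardGeneric("groupAssignment"))
#' @rdname accessors
#' @export
setMethod("groupAssignment", "GeneGroups", function(x) x@assignment)

#' @rdname accessors
#' @export
setGeneric("orfLength", function(x) standardGeneric("orfLength"))
#' @rdname accessors
#' @export
setMethod("orfLength", "OpenReadingFrame", function(x) x@lengthBp)

#' @rdname accessors
#' @export
setGeneric("orfRange", function(x) standardGeneric("orfRange"))
#' @rdname accessors
#' @export
setMethod("orfRange", "OpenReadingFrame", function(x) c(x@start, x@end))

#' @rdname accessors
#' @export
setGeneric("actogramMatrix", function(x) standardGeneric("actogramMatrix"))
#' @rdname accessors
#' @export
setMethod("actogramMatrix", "ActogramGrid", function(x) x@grid)

#' @rdname accessors
#' @export
setGeneric("referenceGenes", function(x) standardGeneric("referenceGenes"))
#' @rdname accessors
#' @export
setMethod("referenceGenes", "CtMatrix", function(x) x@referenceGenes)
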