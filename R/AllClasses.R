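#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames colData rowData
#' @importFrom S4Vectors DataFrame mcols mcols<-
#' @importFrom stats acf pacf lm coef vcov pf qf sd var cor cor.test aov
#'   kruskal.test shapiro.test anova residuals fitted rnorm runif setNames
#'   pchisq p.adjust complete.cases quantile median optim
#' @importFrom utils head write.csv read.csv write.table read.table
NULL

## ---------------------------------------------------------------------------
## Valve-activity containers
## ---------------------------------------------------------------------------

#' ValveActivityPanel: a panel of valve-opening time series
#'
#' Holds hourly (or finer) valve-opening duration series, expressed as a
#' percentage of each hour spent open, for a group of individuals recorded on
#' a common time grid, together with the light-regime annotation of each
#' sample.
#'
#' @slot times numeric, hours from experiment start; strictly increasing.
#' @slot activity numeric matrix, time points x individuals, values in
#'   `[0, 100]` (percent opening); `NA` allowed for missing samples.
#' @slot regime character vector, one of `"LD"` or `"DD"` per time point.
#' @export
setClass("ValveActivityPanel",
  representation(times = "numeric", activity = "matrix", regime = "character"))

setValidity("ValveActivityPanel", function(object) {
  msg <- character()
  if (nrow(object@activity) != length(object@times))
    msg <- c(msg, "nrow(activity) must equal length(times)")
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (length(object@regime) != length(object@times))
    msg <- c(msg, "regime must have one label per time point")
  if (!all(object@regime %in% c("LD", "DD")))
    msg <- c(msg, "regime labels must be 'LD' or 'DD'")
  vals <- object@activity[!is.na(object@activity)]
  if (length(vals) && (min(vals) < 0 || max(vals) > 100))
    msg <- c(msg, "activity values must lie in [0, 100]")
  if (is.null(colnames(object@activity)))
    msg <- c(msg, "activity must have individual ids as colnames")
  if (length(msg)) msg else TRUE
})

#' ValveSeries: one individual's valve-opening series
#'
#' @slot individualId character label.
#' @slot times numeric, hours from experiment start; strictly increasing.
#' @slot values numeric, percent opening in `[0, 100]`.
#' @slot regime character, per-sample regime label (`"LD"`/`"DD"`).
#' @export
setClass("ValveSeries",
  representation(individualId = "character", times = "numeric",
                 values = "numeric", regime = "character"))

setValidity("ValveSeries", function(object) {
  msg <- character()
  if (length(object@times) != length(object@values))
    msg <- c(msg, "times and values must have equal length")
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  vals <- object@values[!is.na(object@values)]
  if (length(vals) && (min(vals) < 0 || max(vals) > 100))
    msg <- c(msg, "values must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Rhythm-analysis results
## ---------------------------------------------------------------------------

#' QualityReport: autocorrelation-based data-quality diagnostics
#'
#' @slot acf numeric, autocorrelation coefficients at lags `1..maxLag`.
#' @slot pacf numeric, partial autocorrelation coefficients (diagnostic only).
#' @slot band numeric(1), the symmetric 95% white-noise band `1.96/sqrt(n)`.
#' @slot nonrandom logical(1), TRUE when the series shows serial structure.
#' @slot passes logical(1), whether the series passes the quality gate.
#' @export
setClass("QualityReport",
  representation(acf = "numeric", pacf = "numeric", band = "numeric",
                 nonrandom = "logical", passes = "logical"))

#' PeriodogramResult: Lomb-Scargle spectrum over a period grid
#'
#' @slot periods numeric, trial periods in hours.
#' @slot power numeric, variance-normalized Lomb-Scargle power per period.
#' @slot threshold numeric(1), significance level on the power scale derived
#'   from the false-alarm relation.
#' @slot significantPeriods numeric, grid local maxima with power above the
#'   threshold, ordered by decreasing power.
#' @export
setClass("PeriodogramResult",
  representation(periods = "numeric", power = "numeric",
                 threshold = "numeric", significantPeriods = "numeric"))

setValidity("PeriodogramResult", function(object) {
  msg <- character()
  if (length(object@power) != length(object@periods))
    msg <- c(msg, "power and periods must have equal length")
  if (any(object@power < 0)) msg <- c(msg, "power must be non-negative")
  if (length(msg)) msg else TRUE
})

#' CosinorFit: a fitted single-component Cosinor model
#'
#' Parameters of `Y(t) = A cos(2 pi t / tau + phi) + M + e(t)` estimated by
#' linearized least squares at a fixed trial period `tau`.
#'
#' @slot tau numeric(1), period (h).
#' @slot amplitude numeric(1), `A >= 0` in signal units.
#' @slot acrophase numeric(1), `phi` in radians in `[-pi, pi)`.
#' @slot mesor numeric(1), `M`, the rhythm-adjusted mean.
#' @slot pr numeric(1), percent rhythm: share of variance explained, in
#'   `[0, 100]`.
#' @slot pAmplitude numeric(1), p-value of the zero-amplitude F-test.
#' @slot ellipseExcludesOrigin logical(1), TRUE when the joint 95% confidence
#'   ellipse of the cosine/sine coefficients excludes the origin.
#' @slot residuals numeric, per-sample residuals.
#' @slot tauCI numeric(2), Halberg-style 95% confidence interval for `tau`.
#' @slot n integer(1), number of samples fitted.
#' @export
setClass("CosinorFit",
  representation(tau = "numeric", amplitude = "numeric", acrophase = "numeric",
                 mesor = "numeric", pr = "numeric", pAmplitude = "numeric",
                 ellipseExcludesOrigin = "logical", residuals = "numeric",
                 tauCI = "numeric", n = "integer"))

setValidity("CosinorFit", function(object) {
  msg <- character()
  if (object@amplitude < 0) msg <- c(msg, "amplitude must be >= 0")
  if (object@pr < -1e-8 || object@pr > 100 + 1e-8)
    msg <- c(msg, "percent rhythm must lie in [0, 100]")
  if (length(object@tauCI) == 2 && !any(is.na(object@tauCI)) &&
      (object@tauCI[1] > object@tau || object@tauCI[2] < object@tau))
    msg <- c(msg, "tauCI must contain tau")
  if (length(msg)) msg else TRUE
})

#' RhythmReport: the outcome of the full validation procedure for one series
#'
#' @slot individualId character label.
#' @slot validated list of [CosinorFit-class], primary component first, then
#'   secondary components found by residual reinjection.
#' @slot rhythmic logical(1); TRUE iff at least one component was validated.
#' @slot classification character(1): `"circadian"`, `"ultradian"`,
#'   `"infradian"` (of the primary period) or `"arrhythmic"`.
#' @slot reason character(1), why the series was declared arrhythmic (empty
#'   when rhythmic).
#' @export
setClass("RhythmReport",
  representation(individualId = "character", validated = "list",
                 rhythmic = "logical", classification = "character",
                 reason = "character"))

setValidity("RhythmReport", function(object) {
  msg <- character()
  if (object@rhythmic != (length(object@validated) > 0))
    msg <- c(msg, "rhythmic must be TRUE iff validated components exist")
  if (length(msg)) msg else TRUE
})

#' PopulationRhythmReport: group-level rhythm summary
#'
#' @slot groupReport [RhythmReport-class] of the population mean series.
#' @slot pctRhythmic numeric(1), percentage of rhythmic individuals.
#' @slot pctCircadianAmongRhythmic numeric(1), percentage of rhythmic
#'   individuals whose primary period is circadian (20-28 h).
#' @slot perIndividual list of per-individual [RhythmReport-class].
#' @export
setClass("PopulationRhythmReport",
  representation(groupReport = "RhythmReport", pctRhythmic = "numeric",
                 pctCircadianAmongRhythmic = "numeric",
                 perIndividual = "list"))

#' ActogramGrid: a (double-plotted) binary actogram
#'
#' @slot grid logical matrix, rows are (pairs of) days, columns time-of-day
#'   bins; TRUE = activity above the day's 24-h mean (drawn black).
#' @slot binHours numeric(1), width of one column in hours.
#' @slot doublePlot logical(1).
#' @slot partialDayPadded logical(1), TRUE when a trailing partial day was
#'   padded with missing bins.
#' @export
setClass("ActogramGrid",
  representation(grid = "matrix", binHours = "numeric",
                 doublePlot = "logical", partialDayPadded = "logical"))

## ---------------------------------------------------------------------------
## Expression containers (SummarizedExperiment-backed)
## ---------------------------------------------------------------------------

#' CtMatrix: raw qPCR quantification-cycle values over a sampling design
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one assay `"ct"`
#' (genes x samples, cycles), colData columns `timepoint_label`, `time_h`,
#' `regime`, and a set of designated reference genes.
#'
#' @slot referenceGenes character, names of reference (housekeeping) genes.
#' @export
setClass("CtMatrix", contains = "SummarizedExperiment",
  representation(referenceGenes = "character"))

setValidity("CtMatrix", function(object) {
  msg <- character()
  if (!"ct" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'ct' is required")
  need <- c("timepoint_label", "time_h", "regime")
  miss <- setdiff(need, colnames(SummarizedExperiment::colData(object)))
  if (length(miss))
    msg <- c(msg, paste("missing colData columns:", paste(miss, collapse = ", ")))
  ct <- SummarizedExperiment::assay(object, "ct")
  if (any(!is.na(ct) & ct <= 0)) msg <- c(msg, "Ct values must be > 0")
  if (length(object@referenceGenes) &&
      !all(object@referenceGenes %in% rownames(object)))
    msg <- c(msg, "referenceGenes must be row names of the matrix")
  if (length(msg)) msg else TRUE
})

#' RQMatrix: relative quantities from comparative-Ct quantification
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one assay `"rq"`
#' holding 2^-ddCt relative quantities (dimensionless, > 0).
#'
#' @slot calibrator character(1), description of the dCt baseline used.
#' @export
setClass("RQMatrix", contains = "SummarizedExperiment",
  representation(calibrator = "character"))

setValidity("RQMatrix", function(object) {
  msg <- character()
  if (!"rq" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'rq' is required")
  rq <- SummarizedExperiment::assay(object, "rq")
  if (any(!is.na(rq) & rq <= 0)) msg <- c(msg, "relative quantities must be > 0")
  if (length(msg)) msg else TRUE
})

#' CorrelationMatrix: pairwise Spearman co-expression estimates
#'
#' @slot rho numeric matrix, gene x gene Spearman coefficients.
#' @slot p numeric matrix, matching p-values.
#' @slot n integer(1), number of samples used.
#' @export
setClass("CorrelationMatrix",
  representation(rho = "matrix", p = "matrix", n = "integer"))

setValidity("CorrelationMatrix", function(object) {
  msg <- character()
  if (!isTRUE(all.equal(object@rho, t(object@rho), tolerance = 1e-12,
                        check.attributes = FALSE)))
    msg <- c(msg, "rho must be symmetric")
  d <- diag(object@rho)
  if (any(!is.na(d) & abs(d - 1) > 1e-12))
    msg <- c(msg, "diagonal rho must equal 1")
  off <- object@rho[!is.na(object@rho)]
  if (length(off) && (min(off) < -1 - 1e-12 || max(off) > 1 + 1e-12))
    msg <- c(msg, "rho must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' GeneGroups: a partition of genes into co-expression groups
#'
#' @slot assignment named character, gene -> group label.
#' @slot method character(1), description of the grouping rule.
#' @export
setClass("GeneGroups",
  representation(assignment = "character", method = "character"))

## ---------------------------------------------------------------------------
## Sequence results
## ---------------------------------------------------------------------------

#' OpenReadingFrame: a forward-strand ATG..stop open reading frame
#'
#' Coordinates are 1-based and inclusive (`lengthBp = end - start + 1`); the
#' stop codon is included in the frame and in `lengthBp`. A none-found result
#' has `lengthBp = 0` and `NA` coordinates.
#'
#' @slot start integer(1), 1-based index of the A of ATG.
#' @slot end integer(1), 1-based index of the last base of the stop codon.
#' @slot lengthBp integer(1), frame length in bases (divisible by 3).
#' @export
setClass("OpenReadingFrame",
  representation(start = "integer", end = "integer", lengthBp = "integer"))

setValidity("OpenReadingFrame", function(object) {
  msg <- character()
  if (object@lengthBp > 0) {
    if (is.na(object@start) || is.na(object@end))
      msg <- c(msg, "coordinates required when lengthBp > 0")
    else if (object@lengthBp != object@end - object@start + 1L)
      msg <- c(msg, "lengthBp must equal end - start + 1")
    if (object@lengthBp %% 3L != 0L)
      msg <- c(msg, "lengthBp must be divisible by 3")
  }
  if (length(msg)) msg else TRUE
})
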