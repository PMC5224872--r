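## Data-quality gate: before any spectral or Cosinor analysis, the series
## must show serial structure (non-randomness) in its autocorrelation
## diagram. The PACF is computed as a reported diagnostic only.

## Accept a ValveSeries, a bare numeric vector (unit spacing assumed), or a
## list(times=, values=); return complete-case time/value vectors.
asTY <- function(series) {
  if (is(series, "ValveSeries")) {
    t <- series@times; y <- series@values
  } else if (is.list(series) && all(c("times", "values") %in% names(series))) {
    t <- series$times; y <- series$values
  } else {
    y <- as.numeric(series); t <- seq_along(y) - 1
  }
  keep <- !is.na(y)
  list(t = t[keep], y = y[keep])
}

seriesValues <- function(series) asTY(series)$y

#' Autocorrelation-based quality check
#'
#' Computes the ACF and PACF up to `maxLag` with the white-noise 95% band
#' `+/- 1.96 / sqrt(n)`. The series is declared non-random when at least 5%
#' of lags beyond lag 0 exceed the band AND the maximum `|ACF|` beyond lag 3
#' exceeds twice the band. A zero-variance series is degenerate and fails.
#'
#' @param series a [ValveSeries-class] or numeric vector (>= 48 samples).
#' @param maxLag largest lag examined (default 72, capped below `n/2`).
#' @return a [QualityReport-class]; `passes` gates downstream analysis.
#' @export
qualityCheck <- function(series, maxLag = 72) {
  y <- asTY(series)$y
  n <- length(y)
  if (n < 48) stop("insufficient data: at least 48 samples required")
  maxLag <- min(maxLag, floor(n / 2) - 1L)
  band <- 1.96 / sqrt(n)
  if (sd(y) == 0) {
    z <- rep(0, maxLag)
    return(new("QualityReport", acf = z, pacf = z, band = band,
               nonrandom = FALSE, passes = FALSE))
  }
  a <- as.numeric(acf(y, lag.max = maxLag, plot = FALSE)$acf)[-1]
  p <- as.numeric(pacf(y, lag.max = maxLag, plot = FALSE)$acf)
  fracOut <- mean(abs(a) > band)
  tailMax <- max(abs(a[-(1:3)]))
  nonrandom <- fracOut >= 0.05 && tailMax > 2 * band
  new("QualityReport", acf = a, pacf = p, band = band,
      nonrandom = nonrandom, passes = nonrandom)
}
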