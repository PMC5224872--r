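## Lomb-Scargle periodogram over a period grid, with a false-alarm
## significance threshold. Implements the classic tau-offset form normalized
## by the sample variance, which tolerates missing samples and uneven
## spacing; power at a pure tone of amplitude A approaches n A^2 / (4 s^2).

#' Lomb-Scargle periodogram
#'
#' Variance-normalized Lomb-Scargle power over a grid of trial periods. The
#' significance threshold converts a familywise false-alarm probability of
#' `alpha` into a power level via the exponential null distribution of the
#' normalized power with the independent-frequency approximation `M = n`:
#' `z = -log(1 - (1 - alpha)^(1/M))`. Significant periods are grid local
#' maxima with power above the threshold, in decreasing power order.
#'
#' @param series a [ValveSeries-class] or numeric vector (>= 48 samples);
#'   missing values are dropped with their timestamps.
#' @param periods trial-period grid in hours (default 2-36 h by 0.1 h).
#' @param alpha familywise false-alarm probability (default 0.05, i.e. the
#'   95% "noise limit").
#' @return a [PeriodogramResult-class].
#' @export
lombScargle <- function(series, periods = seq(2, 36, by = 0.1), alpha = 0.05) {
  ty <- asTY(series)
  t <- ty$t; y <- ty$y
  n <- length(y)
  if (!length(periods)) stop("empty period grid")
  if (n < 48) stop("insufficient data: at least 48 samples required")
  if (sd(y) == 0) stop("zero-variance series: periodogram undefined")
  yc <- y - mean(y)
  s2 <- sum(yc^2) / (n - 1)

  power <- vapply(2 * pi / periods, function(w) {
    tauOff <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    ct <- cos(w * (t - tauOff)); st <- sin(w * (t - tauOff))
    0.5 * (sum(yc * ct)^2 / sum(ct^2) + sum(yc * st)^2 / sum(st^2)) / s2
  }, numeric(1))

  threshold <- -log(1 - (1 - alpha)^(1 / n))
  k <- length(power)
  isMax <- rep(FALSE, k)
  if (k >= 3)
    isMax[2:(k - 1)] <- power[2:(k - 1)] > power[1:(k - 2)] &
      power[2:(k - 1)] >= power[3:k]
  if (k >= 2) {
    isMax[1] <- power[1] > power[2]
    isMax[k] <- power[k] > power[k - 1]
  } else isMax[1] <- TRUE
  sig <- which(isMax & power > threshold)
  sig <- sig[order(power[sig], decreasing = TRUE)]
  new("PeriodogramResult", periods = periods, power = power,
      threshold = threshold, significantPeriods = periods[sig])
}
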