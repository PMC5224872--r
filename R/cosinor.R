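## Cosinor rhythmometry. The model Y(t) = A cos(2 pi t / tau + phi) + M + e(t)
## is linearized at a fixed trial period tau as
##   Y = M + beta cos(w t) + gamma sin(w t),  w = 2 pi / tau,
## with beta = A cos(phi), gamma = -A sin(phi), and fitted by ordinary least
## squares; A = sqrt(beta^2 + gamma^2), phi = atan2(-gamma, beta).

cosinorDesign <- function(t, tau) {
  w <- 2 * pi / tau
  cbind(intercept = 1, c = cos(w * t), s = sin(w * t))
}

cosinorSSE <- function(t, y, tau) {
  X <- cosinorDesign(t, tau)
  fit <- lm.fit(X, y)
  sum(fit$residuals^2)
}

#' Fit a single-component Cosinor model at a fixed trial period
#'
#' Estimates amplitude, acrophase and mesor by linearized least squares, the
#' percent rhythm `PR = 100 (1 - SS_resid / SS_total)`, the zero-amplitude
#' F-test (`H0: beta = gamma = 0`, `F(2, n - 3)`), the elliptic validation
#' test (joint 95% confidence region of `(beta, gamma)`; the rhythm is
#' supported when the region excludes the origin), and a Halberg-style 95%
#' confidence interval for the period (computed when the amplitude test is
#' significant).
#'
#' @param series a [ValveSeries-class] or numeric vector.
#' @param tau trial period in hours (0 < tau < observation span).
#' @param level confidence level of the elliptic test and period CI.
#' @param periodCI compute the Halberg period CI (set FALSE to skip).
#' @return a [CosinorFit-class].
#' @export
fitCosinor <- function(series, tau, level = 0.95, periodCI = TRUE) {
  ty <- asTY(series)
  t <- ty$t; y <- ty$y
  n <- length(y)
  if (tau <= 0) stop("tau must be positive")
  span <- diff(range(t))
  if (tau >= span)
    stop("tau must be smaller than the observation span (regressors collinear)")
  if (span < 2 * tau)
    warning("fewer than 2 full cycles of data at this trial period")

  X <- cosinorDesign(t, tau)
  fit <- lm.fit(X, y)
  b <- fit$coefficients
  res <- fit$residuals
  sse <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  pr <- if (sst > 0) max(0, min(100, 100 * (1 - sse / sst))) else 0
  A <- sqrt(b["c"]^2 + b["s"]^2)
  phi <- wrapAcrophase(atan2(-b["s"], b["c"]))

  df2 <- n - 3L
  sigma2 <- sse / df2
  Fstat <- if (sigma2 > 0) ((sst - sse) / 2) / sigma2 else Inf
  pAmp <- pf(Fstat, 2, df2, lower.tail = FALSE)
  # joint confidence ellipse of (beta, gamma): origin excluded iff the Wald
  # quadratic form exceeds 2 F_{2, n-3; level} (equivalent to the F-test)
  XtXinv <- chol2inv(chol(crossprod(X)))
  Vbg <- sigma2 * XtXinv[2:3, 2:3]
  wald <- if (sigma2 > 0)
    drop(t(b[2:3]) %*% solve(Vbg, b[2:3])) else Inf
  ellipse <- wald > 2 * qf(level, 2, df2)

  tauCI <- c(NA_real_, NA_real_)
  if (periodCI && is.finite(pAmp) && pAmp < 1 - level)
    tauCI <- halbergCI(list(times = t, values = y), tau, level = level)
  new("CosinorFit", tau = tau, amplitude = unname(A), acrophase = unname(phi),
      mesor = unname(b["intercept"]), pr = pr, pAmplitude = unname(pAmp),
      ellipseExcludesOrigin = unname(ellipse), residuals = unname(res),
      tauCI = tauCI, n = n)
}

#' Halberg-style confidence interval for the Cosinor period
#'
#' Profiles the residual sum of squares of the linearized Cosinor fit over a
#' grid of trial periods around `tau` and returns the contiguous region where
#' `SSE(tau') <= SSE_min (1 + qf(level, 1, n - 4) / (n - 4))` (four estimated
#' quantities: mesor, two linear coefficients and the period itself). When
#' the region reaches the grid edge the interval is clamped with a warning.
#'
#' @param series a [ValveSeries-class] or numeric vector.
#' @param tau point estimate of the period (h).
#' @param level confidence level (default 0.95).
#' @param halfWidth half-width of the profiled grid (h).
#' @param step grid step (h).
#' @return numeric(2): lower and upper period bounds (contain `tau`).
#' @export
halbergCI <- function(series, tau, level = 0.95, halfWidth = 3, step = 0.02) {
  ty <- asTY(series)
  t <- ty$t; y <- ty$y
  n <- length(y)
  grid <- seq(max(step, tau - halfWidth), tau + halfWidth, by = step)
  sse <- vapply(grid, function(tt) cosinorSSE(t, y, tt), numeric(1))
  iMin <- which.min(sse)
  df <- n - 4L
  cut <- sse[iMin] * (1 + qf(level, 1, df) / df)
  ok <- sse <= cut
  # contiguous region around the profile minimum
  lo <- iMin; while (lo > 1 && ok[lo - 1]) lo <- lo - 1
  hi <- iMin; while (hi < length(grid) && ok[hi + 1]) hi <- hi + 1
  if (lo == 1 || hi == length(grid))
    warning("period CI reaches the profiling grid edge; interval clamped")
  c(min(grid[lo], tau), max(grid[hi], tau))
}
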