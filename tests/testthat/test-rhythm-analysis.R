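# Quality gate, periodogram, Cosinor, validation chain, actograms.

test_that("quality gate passes periodic signal, fails noise and constants", {
  s <- cosineSeries(days = 15)
  q <- qualityCheck(s$values)
  expect_true(q@passes)
  expect_gt(q@acf[24], 0.9)  # near-unit autocorrelation at one full period

  const <- rep(50, 360)
  expect_false(qualityCheck(const)@passes)

  fails <- vapply(1:100, function(i) {
    set.seed(i)
    !qualityCheck(rnorm(360))@passes
  }, logical(1))
  expect_gte(mean(fails), 0.9)

  expect_error(qualityCheck(rnorm(30)), "insufficient")
})

test_that("periodogram matches an independent reference on an uneven fixture", {
  # reference values computed once with scipy.signal.lombscargle (classic
  # Scargle form) divided by the sample variance, on this exact fixture
  t <- (0:59)[(0:59) %% 7 != 3]
  y <- 50 + 20 * cos(2 * pi * t / 24 + 1) + 4 * sin(2 * pi * t / 7.3)
  pg <- lombScargle(list(times = t, values = y),
                    periods = c(6, 7.3, 12, 20.6, 24, 30))
  expect_equal(powerSpectrum(pg)$power,
               c(0.0275106, 1.32829556, 0.51903172, 13.65613893,
                 23.76753808, 10.03146532),
               tolerance = 1e-7)
})

test_that("periodogram finds a pure tone at its true period", {
  s <- cosineSeries(days = 15)
  pg <- lombScargle(s$values)
  expect_equal(significantPeriods(pg)[1], 24.0, tolerance = 0.1 + 1e-9)
  expect_error(lombScargle(rep(3, 360)), "zero-variance")
  expect_error(lombScargle(s$values, periods = numeric()), "empty")
})

test_that("periodogram familywise false alarm on white noise is controlled", {
  hits <- vapply(1:200, function(i) {
    set.seed(1000 + i)
    length(significantPeriods(lombScargle(rnorm(360)))) > 0
  }, logical(1))
  expect_lte(mean(hits), 0.10)
})

test_that("Cosinor recovers exact parameters on noiseless data", {
  s <- cosineSeries(days = 10, mesor = 50,
                    components = data.frame(period = 24, amplitude = 20,
                                            acrophase = 0))
  f <- fitCosinor(list(times = s$times, values = s$values), 24)
  expect_equal(amplitude(f), 20, tolerance = 1e-9)
  expect_equal(mesor(f), 50, tolerance = 1e-9)
  expect_equal(acrophase(f), 0, tolerance = 1e-9)
  expect_equal(percentRhythm(f), 100, tolerance = 1e-9)
  expect_lt(f@pAmplitude, 1e-12)
  expect_true(f@ellipseExcludesOrigin)
  expect_lt(abs(mean(f@residuals)), 1e-9)

  # orthogonal frequency over whole cycles: no spurious amplitude
  f12 <- fitCosinor(list(times = s$times, values = s$values), 12,
                    periodCI = FALSE)
  expect_lt(amplitude(f12), 1e-9)
  expect_gt(f12@pAmplitude, 0.05)
})

test_that("Cosinor errors on impossible trial periods", {
  s <- cosineSeries(days = 3)
  expect_error(fitCosinor(s$values, -2), "positive")
  expect_error(fitCosinor(s$values, 100), "span")
  expect_warning(fitCosinor(list(times = 0:47, values = s$values[1:48]), 24),
                 "2 full cycles")
})

test_that("linearized fit agrees with brute-force SSE minimization", {
  set.seed(99)
  for (rep in 1:10) {
    n <- sample(50:100, 1)
    tau <- runif(1, 8, 30)
    t <- sort(runif(n, 0, 5 * tau))
    y <- runif(1, 20, 60) +
      runif(1, 5, 20) * cos(2 * pi * t / tau + runif(1, -pi, pi)) +
      rnorm(n, 0, 3)
    f <- fitCosinor(list(times = t, values = y), tau, periodCI = FALSE)
    bf <- bruteForceCosinor(t, y, tau)
    expect_equal(amplitude(f), bf$A, tolerance = 1e-6)
    expect_equal(mesor(f), bf$M, tolerance = 1e-6)
    expect_equal(acrophase(f), bf$phi, tolerance = 1e-5)
  }
})

test_that("amplitude estimate is unbiased and the elliptic test matches the F-test", {
  set.seed(7)
  aHat <- numeric(200)
  for (i in 1:200) {
    t <- 0:359
    y <- 50 + 10 * cos(2 * pi * t / 24 + 0.5) + rnorm(360, 0, 10)
    f <- fitCosinor(list(times = t, values = y), 24, periodCI = FALSE)
    aHat[i] <- amplitude(f)
    # the two validation routes are computed from the same linear model and
    # must agree case by case
    expect_identical(f@ellipseExcludesOrigin, f@pAmplitude < 0.05)
  }
  expect_equal(mean(aHat), 10, tolerance = 0.05 * 10)
})

test_that("period CI contains the estimate and narrows as noise vanishes", {
  widths <- vapply(c(8, 4, 1), function(sdv) {
    s <- cosineSeries(days = 15, noiseSd = sdv, seed = 21)
    ci <- halbergCI(list(times = s$times, values = s$values), 24)
    expect_lte(ci[1], 24); expect_gte(ci[2], 24)
    ci[2] - ci[1]
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("period CI covers the generating period at moderate noise", {
  cover <- vapply(1:100, function(i) {
    s <- cosineSeries(days = 15, noiseSd = 10, seed = 300 + i,
                      components = data.frame(period = 24, amplitude = 10,
                                              acrophase = 0.3))
    pk <- significantPeriods(lombScargle(s$values))[1]
    ci <- halbergCI(list(times = s$times, values = s$values), pk)
    ci[1] <= 24 && 24 <= ci[2]
  }, logical(1))
  expect_gte(mean(cover), 0.9)
})

test_that("full validation recovers both free-running components", {
  panel <- generateValvePanel(ddPreset(seed = 2))
  rep <- validateRhythm(meanSeries(panel))
  expect_true(isRhythmic(rep))
  taus <- periodHours(rep)
  expect_equal(taus[1], 20.6, tolerance = 0.5)
  expect_equal(taus[2], 12.5, tolerance = 0.5)
  expect_identical(rhythmClass(rep), "circadian")
})

test_that("validation declares pure noise arrhythmic and gives the reason", {
  set.seed(12)
  rep <- validateRhythm(rnorm(360, 50, 5))
  expect_false(isRhythmic(rep))
  expect_identical(rhythmClass(rep), "arrhythmic")
  expect_match(rep@reason, "quality|periodicity")
  short <- validateRhythm(rnorm(30))
  expect_false(isRhythmic(short))
  expect_match(short@reason, "insufficient")
})

test_that("reinjection does not hallucinate secondary components", {
  nComp <- vapply(1:100, function(i) {
    s <- cosineSeries(days = 15, noiseSd = 10, seed = 500 + i,
                      components = data.frame(period = 24, amplitude = 15,
                                              acrophase = -1))
    length(validatedFits(validateRhythm(s$values)))
  }, numeric(1))
  expect_gte(mean(nComp == 1), 0.9)
})

test_that("residual extraction removes the fitted component's spectral peak", {
  s <- cosineSeries(days = 15, components = data.frame(
    period = c(20.6, 12.5), amplitude = c(12, 8), acrophase = c(0, 1)))
  f <- fitCosinor(list(times = s$times, values = s$values), 20.6,
                  periodCI = FALSE)
  pgRes <- lombScargle(list(times = s$times, values = f@residuals))
  at <- function(pg, tau) powerSpectrum(pg)$power[
    which.min(abs(powerSpectrum(pg)$period_h - tau))]
  expect_lt(at(pgRes, 20.6), pgRes@threshold)
  expect_gt(at(pgRes, 12.5), pgRes@threshold)
})

test_that("period classification uses the 20-28 h circadian band inclusively", {
  expect_identical(classifyPeriod(c(24, 12.5, 20, 28, 19.9, 28.1, 36)),
                   c("circadian", "ultradian", "circadian", "circadian",
                     "ultradian", "infradian", "infradian"))
  expect_error(classifyPeriod(0), "positive")
})

test_that("population summary counts rhythmic individuals consistently", {
  panel <- generateValvePanel(valveConfig(nIndividuals = 1, nDays = 15,
                                          noiseSd = 5, seed = 31))
  ps <- populationSummary(panel)
  expect_equal(pctRhythmic(ps), 100)
  expect_equal(length(individualReports(ps)), 1)
  expect_true(isRhythmic(groupReport(ps)))

  nullPanel <- generateValvePanel(valveConfig(nIndividuals = 5, nDays = 15,
                                              noiseSd = 8,
                                              fractionArrhythmic = 1,
                                              seed = 32))
  expect_lte(pctRhythmic(populationSummary(nullPanel)), 20)
})

test_that("actogram binarizes against each day's mean with ties white", {
  expect_error(actogram(rep(50, 48)), NA)
  a <- actogram(rep(50, 72), doublePlot = TRUE)
  expect_false(any(actogramMatrix(a)))  # constant: all ties, all white

  # 24 h square wave, high during hours 0-11: same black band every row
  y <- rep(c(rep(80, 12), rep(20, 12)), 6)
  g <- actogramMatrix(actogram(y))
  expect_true(all(g[, 1:12]) && !any(g[, 13:24]))
  expect_true(all(g[, 25:36]) && !any(g[, 37:48]))

  # invariance under adding a constant
  s <- cosineSeries(days = 4, noiseSd = 5, seed = 41)
  g1 <- actogramMatrix(actogram(s$values))
  g2 <- actogramMatrix(actogram(s$values + 17))
  expect_identical(g1, g2)

  # each double-plot row spans 48 h of hourly bins
  expect_equal(ncol(g1), 48)
  expect_equal(nrow(g1), 3)
})

test_that("actogram flags padded partial trailing days", {
  y <- c(rep(c(rep(80, 12), rep(20, 12)), 3), rep(80, 5))
  a <- actogram(y)
  expect_true(a@partialDayPadded)
})

test_that("phase-locked entrained series keeps a stable actogram band", {
  panel <- generateValvePanel(ldPreset(seed = 6))
  g <- actogramMatrix(actogram(meanSeries(panel)))
  # position of the daily black band (its center of mass) must not drift
  center <- apply(g[, 1:24], 1, function(r) mean(which(r)))
  expect_lt(max(center) - min(center), 2)
})
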