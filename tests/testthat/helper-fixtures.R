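# Shared fixtures built in code.

# Noiseless multi-component Cosinor series on an hourly grid.
cosineSeries <- function(days = 15, mesor = 50, components = data.frame(
                           period = 24, amplitude = 20, acrophase = 0),
                         noiseSd = 0, seed = NULL, intervalH = 1) {
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, by = intervalH, length.out = round(days * 24 / intervalH))
  y <- rep(mesor, length(t))
  for (k in seq_len(nrow(components)))
    y <- y + components$amplitude[k] *
      cos(2 * pi * t / components$period[k] + components$acrophase[k])
  if (noiseSd > 0) y <- y + rnorm(length(t), 0, noiseSd)
  list(times = t, values = y)
}

# Independent brute-force Cosinor oracle: minimize SSE over (A, phi, M)
# directly, by coarse grid search refined with Nelder-Mead. Never touches
# the linearized path.
bruteForceCosinor <- function(t, y, tau) {
  sse <- function(p) sum((y - (p[1] * cos(2 * pi * t / tau + p[2]) + p[3]))^2)
  grid <- expand.grid(A = seq(0, 2 * diff(range(y)), length.out = 15),
                      phi = seq(-pi, pi, length.out = 25),
                      M = seq(min(y), max(y), length.out = 15))
  vals <- apply(grid, 1, sse)
  start <- as.numeric(grid[which.min(vals), ])
  fit <- optim(start, sse, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
  fit <- optim(fit$par, sse, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
  p <- fit$par
  if (p[1] < 0) { p[1] <- -p[1]; p[2] <- p[2] + pi }
  p[2] <- (p[2] + pi) %% (2 * pi) - pi
  list(A = p[1], phi = p[2], M = p[3], sse = fit$value)
}
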