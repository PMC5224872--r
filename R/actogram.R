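## Double-plotted actograms: each row shows two consecutive days; bins with
## activity strictly above that day's 24-h mean are black, ties and values
## below are white.

#' Build a (double-plotted) binary actogram grid
#'
#' The series is cut into days of 24 h from the first timestamp and each day
#' into bins of `binHours`; every bin is binarized against its own day's
#' mean (strictly above = TRUE/black; ties = FALSE/white, so the grid is
#' invariant to adding a constant to the whole series). With
#' `doublePlot = TRUE`, row d concatenates day d and day d+1. A trailing
#' partial day is padded with missing bins and flagged.
#'
#' @param series a [ValveSeries-class] or numeric vector (hourly or finer).
#' @param doublePlot concatenate consecutive day pairs per row (default TRUE).
#' @param binHours bin width in hours (default 1).
#' @return an [ActogramGrid-class].
#' @export
actogram <- function(series, doublePlot = TRUE, binHours = 1) {
  ty <- asTY(series)
  t <- ty$t - ty$t[1]
  y <- ty$y
  nBins <- round(24 / binHours)
  day <- floor(t / 24) + 1L
  bin <- floor((t %% 24) / binHours) + 1L
  nDays <- max(day)
  vals <- matrix(NA_real_, nrow = nDays, ncol = nBins)
  cnt <- matrix(0L, nrow = nDays, ncol = nBins)
  for (i in seq_along(y)) {
    d <- day[i]; b <- bin[i]
    vals[d, b] <- if (cnt[d, b] == 0L) y[i] else vals[d, b] + y[i]
    cnt[d, b] <- cnt[d, b] + 1L
  }
  vals <- vals / ifelse(cnt == 0L, NA, cnt)
  partial <- any(is.na(vals[nDays, ]))
  dayMean <- rowMeans(vals, na.rm = TRUE)
  black <- vals > dayMean  # strict: ties are white
  if (doublePlot) {
    if (nDays < 2) stop("double plotting requires at least 2 days of data")
    grid <- cbind(black[-nDays, , drop = FALSE], black[-1, , drop = FALSE])
    rownames(grid) <- sprintf("day%02d-%02d", seq_len(nDays - 1), 2:nDays)
  } else {
    grid <- black
    rownames(grid) <- sprintf("day%02d", seq_len(nDays))
  }
  colnames(grid) <- sprintf("h%02d", seq_len(ncol(grid)) - 1)
  new("ActogramGrid", grid = grid, binHours = binHours,
      doublePlot = doublePlot, partialDayPadded = partial)
}

#' Plot an actogram grid
#'
#' @param x an [ActogramGrid-class].
#' @param main plot title.
#' @return invisibly, `x`.
#' @export
plotActogram <- function(x, main = "Actogram") {
  stopifnot(is(x, "ActogramGrid"))
  g <- x@grid
  z <- t(apply(g, 2, rev))  # image() draws row 1 at the bottom
  graphics::image(x = seq_len(ncol(g)) * x@binHours, y = seq_len(nrow(g)),
                  z = ifelse(is.na(z), 0, z * 1),
                  col = c("white", "black"), xlab = "time (h)",
                  ylab = "2-day window", main = main, useRaster = TRUE)
  invisible(x)
}

#' Write an actogram grid as a TSV matrix
#'
#' Cells are 1 (black, above the daily mean), 0 (white) or NA (missing).
#'
#' @param x an [ActogramGrid-class].
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeActogram <- function(x, path) {
  stopifnot(is(x, "ActogramGrid"))
  write.table(x@grid * 1, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
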