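## Comparative-Ct (2^-ddCt) relative quantification and the statistics run
## on the resulting relative quantities.

#' Relative quantification by the comparative-Ct method
#'
#' Normalizes each sample against the reference gene
#' (`dCt[g,s] = Ct[g,s] - Ct[ref,s]`), subtracts the calibrator baseline
#' (`ddCt[g,s] = dCt[g,s] - mean(dCt[g, calibrator samples])`) and reports
#' `RQ = E^-ddCt` (efficiency `E = 2` by default). With the default
#' calibrator, the baseline is the mean dCt over all samples of each
#' sample's regime, so the geometric mean RQ over each regime is 1 per gene.
#'
#' @param ct a [CtMatrix-class].
#' @param reference reference-gene row name (default: the matrix's first
#'   registered reference gene).
#' @param calibrator `"regime"` (per-regime mean dCt baseline, default),
#'   `"all"` (global mean), or a character vector of sample ids.
#' @param efficiency amplification efficiency `E` (default 2).
#' @return an [RQMatrix-class] (reference genes excluded from the rows).
#'   Samples with a missing reference Ct are dropped with a warning.
#' @export
relativeQuantity <- function(ct, reference = NULL, calibrator = "regime",
                             efficiency = 2) {
  stopifnot(is(ct, "CtMatrix"))
  if (is.null(reference)) reference <- ct@referenceGenes[1]
  if (is.na(reference) || !reference %in% rownames(ct))
    stop("reference gene not present in the matrix")
  ctA <- SummarizedExperiment::assay(ct, "ct")
  refCt <- ctA[reference, ]
  drop <- is.na(refCt)
  if (any(drop)) {
    warning(sprintf("%d sample(s) dropped: missing reference Ct", sum(drop)))
    ct <- ct[, !drop]
    ctA <- ctA[, !drop, drop = FALSE]
    refCt <- refCt[!drop]
  }
  targets <- setdiff(rownames(ctA), ct@referenceGenes)
  dct <- sweep(ctA[targets, , drop = FALSE], 2, refCt, "-")
  regime <- SummarizedExperiment::colData(ct)$regime
  if (identical(calibrator, "regime")) {
    ddct <- dct
    for (r in unique(regime)) {
      idx <- regime == r
      ddct[, idx] <- dct[, idx, drop = FALSE] -
        rowMeans(dct[, idx, drop = FALSE], na.rm = TRUE)
    }
    calDesc <- "mean dCt over all samples of each regime"
  } else if (identical(calibrator, "all")) {
    ddct <- dct - rowMeans(dct, na.rm = TRUE)
    calDesc <- "mean dCt over all samples"
  } else {
    idx <- colnames(dct) %in% calibrator
    if (!any(idx)) stop("no calibrator samples found in the matrix")
    ddct <- dct - rowMeans(dct[, idx, drop = FALSE], na.rm = TRUE)
    calDesc <- sprintf("mean dCt over %d named calibrator samples", sum(idx))
  }
  rq <- efficiency^(-ddct)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(rq = rq),
    rowData = SummarizedExperiment::rowData(ct)[targets, , drop = FALSE],
    colData = SummarizedExperiment::colData(ct))
  new("RQMatrix", se, calibrator = calDesc)
}

#' Reference-gene stability screen
#'
#' Scores each candidate housekeeping gene by the standard deviation of its
#' Ct across samples plus the mean SD of its pairwise Ct differences against
#' the other candidates; lower is more stable. A transparent minimal
#' criterion in the spirit of pairwise-variation screens.
#'
#' @param ct a [CtMatrix-class].
#' @param candidates character, candidate gene row names (>= 2).
#' @return data.frame (`gene`, `sdCt`, `pairwiseSd`, `score`) sorted by
#'   increasing score (most stable first; ties keep input order).
#' @export
referenceStability <- function(ct, candidates) {
  stopifnot(is(ct, "CtMatrix"))
  if (length(candidates) < 2) stop("at least 2 candidate genes are required")
  ctA <- SummarizedExperiment::assay(ct, "ct")
  if (ncol(ctA) < 2) stop("at least 2 samples are required")
  miss <- setdiff(candidates, rownames(ctA))
  if (length(miss)) stop("candidates not in matrix: ", paste(miss, collapse = ", "))
  sdCt <- apply(ctA[candidates, , drop = FALSE], 1, sd, na.rm = TRUE)
  pw <- vapply(candidates, function(a) {
    others <- setdiff(candidates, a)
    mean(vapply(others, function(b) sd(ctA[a, ] - ctA[b, ], na.rm = TRUE),
                numeric(1)))
  }, numeric(1))
  out <- data.frame(gene = candidates, sdCt = unname(sdCt),
                    pairwiseSd = unname(pw),
                    score = unname(sdCt + pw), stringsAsFactors = FALSE)
  out[order(out$score), , drop = FALSE]
}

## Holm-Sidak step-down adjustment of a vector of p-values.
holmSidak <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

#' Per-gene timepoint comparisons with normality/homoscedasticity screening
#'
#' For each gene, relative quantities are compared across timepoint groups:
#' Shapiro-Wilk (on per-group centred residuals) and Levene screens at 0.05
#' choose between one-way ANOVA and Kruskal-Wallis; pairwise comparisons
#' (Welch t or Wilcoxon) are Holm-Sidak adjusted. Genes with a degenerate
#' design (a group with fewer than 2 values, or zero variance overall) are
#' flagged and skipped.
#'
#' @param rq an [RQMatrix-class].
#' @param groupBy colData column defining the groups (default
#'   `"timepoint_label"`).
#' @param regime optional regime filter (`"LD"`/`"DD"`).
#' @param alpha screening level for the normality/homoscedasticity tests.
#' @return list with `tests` (per-gene data.frame: test used, statistic,
#'   p-value, flag) and `pairwise` (per-gene data.frame of adjusted pairwise
#'   p-values).
#' @export
timepointComparison <- function(rq, groupBy = "timepoint_label",
                                regime = NULL, alpha = 0.05) {
  stopifnot(is(rq, "RQMatrix"))
  cd <- SummarizedExperiment::colData(rq)
  keep <- if (is.null(regime)) rep(TRUE, ncol(rq)) else cd$regime == regime
  m <- SummarizedExperiment::assay(rq, "rq")[, keep, drop = FALSE]
  grp <- factor(cd[[groupBy]][keep])
  if (nlevels(grp) < 2) stop("at least 2 groups are required")
  tests <- vector("list", nrow(m))
  pairs <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    gene <- rownames(m)[i]
    y <- as.numeric(m[i, ])
    ok <- !is.na(y)
    yi <- y[ok]; gi <- droplevels(grp[ok])
    sizes <- table(gi)
    if (nlevels(gi) < 2 || any(sizes < 2) || sd(yi) == 0) {
      tests[[i]] <- data.frame(gene = gene, test = NA_character_,
                               statistic = NA_real_, p = NA_real_,
                               flag = "degenerate", stringsAsFactors = FALSE)
      next
    }
    resid <- yi - ave(yi, gi)
    normal <- tryCatch(shapiro.test(resid)$p.value > alpha,
                       error = function(e) FALSE)
    homosc <- tryCatch(
      car::leveneTest(yi ~ gi)[1, "Pr(>F)"] > alpha,
      error = function(e) FALSE)
    if (normal && homosc) {
      fit <- aov(yi ~ gi)
      tab <- anova(fit)
      tests[[i]] <- data.frame(gene = gene, test = "anova",
                               statistic = tab$`F value`[1], p = tab$`Pr(>F)`[1],
                               flag = "", stringsAsFactors = FALSE)
      pfun <- function(a, b) tryCatch(
        stats::t.test(yi[gi == a], yi[gi == b])$p.value,
        error = function(e) NA_real_)
    } else {
      kw <- kruskal.test(yi, gi)
      tests[[i]] <- data.frame(gene = gene, test = "kruskal-wallis",
                               statistic = unname(kw$statistic), p = kw$p.value,
                               flag = "", stringsAsFactors = FALSE)
      pfun <- function(a, b) tryCatch(
        suppressWarnings(stats::wilcox.test(yi[gi == a], yi[gi == b])$p.value),
        error = function(e) NA_real_)
    }
    cmb <- utils::combn(levels(gi), 2)
    praw <- apply(cmb, 2, function(ab) pfun(ab[1], ab[2]))
    pairs[[i]] <- data.frame(gene = gene, group1 = cmb[1, ], group2 = cmb[2, ],
                             p_adjusted = holmSidak(praw),
                             stringsAsFactors = FALSE)
  }
  list(tests = do.call(rbind, tests),
       pairwise = do.call(rbind, pairs[!vapply(pairs, is.null, logical(1))]))
}
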