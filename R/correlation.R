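## Spearman co-expression matrices and correlation-based gene grouping.

#' Pairwise Spearman correlation of relative quantities within a regime
#'
#' Computes Spearman's rho and its p-value for every gene pair on per-sample
#' relative quantities of the requested regime, with average-rank tie
#' handling (p-values from [stats::cor.test], exact for small tie-free n).
#' Genes constant across the regime's samples have undefined correlations and
#' are reported as `NA` against every partner.
#'
#' @param rq an [RQMatrix-class].
#' @param regime `"LD"` or `"DD"` (ignored with a warning when the matrix has
#'   a single regime and `regime` is `NULL`).
#' @return a [CorrelationMatrix-class].
#' @export
spearmanMatrix <- function(rq, regime = NULL) {
  stopifnot(is(rq, "RQMatrix"))
  cd <- SummarizedExperiment::colData(rq)
  keep <- if (is.null(regime)) rep(TRUE, ncol(rq)) else cd$regime == regime
  m <- SummarizedExperiment::assay(rq, "rq")[, keep, drop = FALSE]
  nS <- ncol(m)
  if (nS < 5) stop("at least 5 samples are required in the regime")
  g <- nrow(m)
  rho <- matrix(NA_real_, g, g, dimnames = list(rownames(m), rownames(m)))
  p <- rho
  constant <- apply(m, 1, function(x) sd(x, na.rm = TRUE) == 0)
  for (i in seq_len(g)) {
    if (constant[i]) next
    rho[i, i] <- 1; p[i, i] <- 0
    for (j in seq_len(g)) {
      if (j <= i || constant[j]) next
      ok <- complete.cases(m[i, ], m[j, ])
      ct <- suppressWarnings(
        cor.test(m[i, ok], m[j, ok], method = "spearman"))
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  new("CorrelationMatrix", rho = rho, p = p, n = as.integer(nS))
}

#' Group genes by positive significant co-expression
#'
#' Builds a graph with an edge between two genes when their Spearman rho is
#' positive, significant at `alpha`, and at least `rhoFloor`; groups are the
#' connected components, labelled in order of first gene appearance (so the
#' output is deterministic and permutation-equivariant up to labels). Genes
#' with no qualifying partner form singleton groups.
#'
#' @param corr a [CorrelationMatrix-class].
#' @param alpha significance level for an edge (default 0.05).
#' @param rhoFloor minimum rho for an edge (default 0.25, just below the
#'   weakest within-group coefficient such screens typically retain).
#' @return a [GeneGroups-class].
#' @export
correlationGroups <- function(corr, alpha = 0.05, rhoFloor = 0.25) {
  stopifnot(is(corr, "CorrelationMatrix"))
  genes <- rownames(corr@rho)
  g <- length(genes)
  adj <- !is.na(corr@rho) & !is.na(corr@p) &
    corr@rho > 0 & corr@rho >= rhoFloor & corr@p < alpha
  diag(adj) <- FALSE
  # connected components by breadth-first search
  comp <- rep(NA_integer_, g)
  cur <- 0L
  for (i in seq_len(g)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  assignment <- setNames(paste0("G", comp), genes)
  new("GeneGroups", assignment = assignment,
      method = sprintf("connected components of {rho > 0, rho >= %.3g, p < %.3g}",
                       rhoFloor, alpha))
}

#' Format a correlation matrix as an upper-triangle table with stars
#'
#' Mirrors the usual published layout: upper triangle only, coefficients
#' prefixed with significance stars (`*` p<0.05, `**` p<0.01, `***` p<0.001).
#'
#' @param corr a [CorrelationMatrix-class].
#' @param digits coefficient digits (default 3).
#' @return character matrix (empty strings on/below the diagonal).
#' @export
formatCorrelationTable <- function(corr, digits = 3) {
  stopifnot(is(corr, "CorrelationMatrix"))
  g <- nrow(corr@rho)
  out <- matrix("", g, g, dimnames = dimnames(corr@rho))
  for (i in seq_len(g)) for (j in seq_len(g)) {
    if (j <= i || is.na(corr@rho[i, j])) next
    stars <- if (corr@p[i, j] < 0.001) "***"
      else if (corr@p[i, j] < 0.01) "**"
      else if (corr@p[i, j] < 0.05) "*" else ""
    out[i, j] <- paste0(stars, format(round(corr@rho[i, j], digits)))
  }
  out
}
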