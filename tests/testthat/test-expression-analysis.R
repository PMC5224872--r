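# Comparative-Ct quantification, stability screen, group comparisons,
# Spearman matrices and correlation grouping.

makeCt <- function(ct, timepoints = NULL, regime = "LD", reference = "EF1") {
  # small hand-built CtMatrix from a genes x samples matrix
  n <- ncol(ct)
  if (is.null(timepoints)) timepoints <- rep("ZT1", n)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(ct = ct),
    colData = S4Vectors::DataFrame(
      sample_id = colnames(ct), timepoint_label = timepoints,
      time_h = as.numeric(gsub("[^0-9.]", "", timepoints)),
      regime = rep(regime, n), row.names = colnames(ct)))
  new("CtMatrix", se, referenceGenes = reference)
}

test_that("relative quantities follow the 2^-ddCt closed form", {
  ct <- matrix(c(20, 21, 22, 23,   # geneA: dCt = 5,5,5,5 -> RQ = 1
                 19, 21, 21, 24,   # geneB: dCt = 4,5,4,6
                 15, 16, 17, 18),  # EF1
               nrow = 3, byrow = TRUE,
               dimnames = list(c("geneA", "geneB", "EF1"),
                               paste0("s", 1:4)))
  rq <- relativeQuantity(makeCt(ct))
  m <- SummarizedExperiment::assay(rq, "rq")
  expect_equal(unname(m["geneA", ]), rep(1, 4))
  # geneB calibrator mean dCt = 4.75; dCt = 4 -> RQ = 2^0.75
  expect_equal(unname(m["geneB", "s1"]), 2^0.75)
  expect_equal(unname(m["geneB", "s4"]), 2^-1.25)
  # calibrator normalization: per-gene geometric mean over the regime is 1
  expect_equal(exp(rowMeans(log(m))), c(geneA = 1, geneB = 1))
  expect_true(all(m > 0))
})

test_that("samples missing the reference Ct are dropped with a warning", {
  ct <- matrix(c(20, 21, 22, 19, 21, 21, 15, NA, 17), nrow = 3, byrow = TRUE,
               dimnames = list(c("geneA", "geneB", "EF1"), paste0("s", 1:3)))
  expect_warning(rq <- relativeQuantity(makeCt(ct)), "dropped")
  expect_equal(ncol(rq), 2)
  expect_error(relativeQuantity(makeCt(ct), reference = "absent"),
               "reference")
})

test_that("a generator gain of one Ct yields a unit-amplitude log2 rhythm", {
  cfg <- expressionConfig(ctNoiseSd = 0, withinGroupRho = 0, gainCt = 1,
                          referenceNoiseSd = 0, seed = 8)
  rq <- relativeQuantity(generateCtMatrix(cfg))
  lg <- log2(SummarizedExperiment::assay(rq, "rq"))["CgCry1", ]
  tH <- SummarizedExperiment::colData(rq)$time_h
  # noiseless round trip: log2(RQ) traces the unit-amplitude group latent
  expect_equal(unname(lg), cos(2 * pi * (tH - 9) / 24), tolerance = 1e-9)
})

test_that("stability screen ranks flat candidates above rhythmic ones", {
  set.seed(13)
  n <- 24
  t <- rep(seq(1, 22, 3), each = 3)
  ct <- rbind(EF1 = 18 + rnorm(n, 0, 0.05),
              GADPH = 20 + rnorm(n, 0, 0.05),
              rhythmicRef = 19 + cos(2 * pi * t / 24) + rnorm(n, 0, 0.05),
              flat = rep(21, n))
  colnames(ct) <- paste0("s", 1:n)
  cm <- makeCt(ct, reference = "EF1")
  rank <- referenceStability(cm, c("EF1", "GADPH", "rhythmicRef"))
  expect_identical(rank$gene[3], "rhythmicRef")

  # a perfectly constant candidate scores 0 against another constant
  ct2 <- rbind(a = rep(20, 10), b = rep(21, 10))
  colnames(ct2) <- paste0("s", 1:10)
  r2 <- referenceStability(makeCt(ct2, reference = "a"), c("a", "b"))
  expect_equal(r2$score, c(0, 0))
  expect_error(referenceStability(cm, "EF1"), "2 candidate")
})

test_that("timepoint comparison controls size and detects large shifts", {
  tp <- rep(c("ZT1", "ZT7", "ZT13", "ZT19"), each = 9)
  nSim <- 200
  rej <- logical(nSim)
  set.seed(17)
  for (i in seq_len(nSim)) {
    m <- matrix(2^rnorm(36, 0, 0.5), nrow = 1,
                dimnames = list("g", paste0("s", 1:36)))
    rqSe <- SummarizedExperiment::SummarizedExperiment(
      assays = list(rq = m),
      colData = S4Vectors::DataFrame(sample_id = colnames(m),
                                     timepoint_label = tp,
                                     time_h = rep(c(1, 7, 13, 19), each = 9),
                                     regime = rep("LD", 36),
                                     row.names = colnames(m)))
    rq <- new("RQMatrix", rqSe, calibrator = "test")
    rej[i] <- timepointComparison(rq)$tests$p < 0.05
  }
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.09)

  # one group shifted by 5 SD: essentially always detected
  set.seed(18)
  hit <- vapply(1:20, function(i) {
    y <- rnorm(36, 10, 1); y[tp == "ZT13"] <- y[tp == "ZT13"] + 5
    m <- matrix(y, nrow = 1, dimnames = list("g", paste0("s", 1:36)))
    rqSe <- SummarizedExperiment::SummarizedExperiment(
      assays = list(rq = m),
      colData = S4Vectors::DataFrame(sample_id = colnames(m),
                                     timepoint_label = tp,
                                     time_h = rep(c(1, 7, 13, 19), each = 9),
                                     regime = rep("LD", 36),
                                     row.names = colnames(m)))
    res <- timepointComparison(new("RQMatrix", rqSe, calibrator = "test"))
    res$tests$p < 0.05 &&
      any(res$pairwise$p_adjusted[res$pairwise$group1 == "ZT13" |
                                    res$pairwise$group2 == "ZT13"] < 0.05)
  }, logical(1))
  expect_true(all(hit))
})

test_that("degenerate genes are flagged and skipped, not tested", {
  tp <- rep(c("ZT1", "ZT13"), each = 3)
  m <- matrix(rep(2, 6), nrow = 1, dimnames = list("flat", paste0("s", 1:6)))
  rqSe <- SummarizedExperiment::SummarizedExperiment(
    assays = list(rq = m),
    colData = S4Vectors::DataFrame(sample_id = colnames(m),
                                   timepoint_label = tp,
                                   time_h = rep(c(1, 13), each = 3),
                                   regime = rep("LD", 6),
                                   row.names = colnames(m)))
  res <- timepointComparison(new("RQMatrix", rqSe, calibrator = "test"))
  expect_identical(res$tests$flag, "degenerate")
  expect_true(is.na(res$tests$p))
})

test_that("Spearman matrix is symmetric, unit-diagonal and rank-invariant", {
  rq <- relativeQuantity(generateCtMatrix(expressionConfig(seed = 23)))
  cm <- spearmanMatrix(rq, regime = "LD")
  rho <- spearmanRho(cm)
  expect_equal(rho, t(rho))
  expect_equal(unname(diag(rho)), rep(1, nrow(rho)))
  expect_true(all(abs(rho) <= 1 + 1e-12))
  expect_equal(cm@n, 72L)

  # strictly monotone per-gene transform leaves rho unchanged
  m <- SummarizedExperiment::assay(rq, "rq")
  se2 <- SummarizedExperiment::SummarizedExperiment(
    assays = list(rq = exp(m)),
    colData = SummarizedExperiment::colData(rq))
  cm2 <- spearmanMatrix(new("RQMatrix", se2, calibrator = "x"), regime = "LD")
  expect_equal(spearmanRho(cm2), rho)
})

test_that("constant genes are reported as missing correlations", {
  m <- rbind(a = c(1, 2, 3, 4, 5, 6), b = rep(2, 6), c = c(2, 1, 4, 3, 6, 5))
  colnames(m) <- paste0("s", 1:6)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(rq = m),
    colData = S4Vectors::DataFrame(sample_id = colnames(m),
                                   timepoint_label = rep("ZT1", 6),
                                   time_h = rep(1, 6),
                                   regime = rep("LD", 6),
                                   row.names = colnames(m)))
  cm <- spearmanMatrix(new("RQMatrix", se, calibrator = "x"))
  expect_true(all(is.na(spearmanRho(cm)["b", ])))
  expect_false(is.na(spearmanRho(cm)["a", "c"]))
})

test_that("grouping splits an ideal block-diagonal matrix into its blocks", {
  g <- paste0("g", 1:5)
  rho <- matrix(0, 5, 5, dimnames = list(g, g))
  rho[1:3, 1:3] <- 0.8; rho[4:5, 4:5] <- 0.8; diag(rho) <- 1
  p <- matrix(1e-6, 5, 5, dimnames = list(g, g)); diag(p) <- 0
  cm <- new("CorrelationMatrix", rho = rho, p = p, n = 20L)
  a <- groupAssignment(correlationGroups(cm))
  expect_equal(length(unique(a)), 2)
  expect_equal(length(unique(a[1:3])), 1)
  expect_equal(length(unique(a[4:5])), 1)
  expect_false(a[1] == a[4])
})

test_that("grouping is permutation-equivariant and handles singletons", {
  rq <- relativeQuantity(generateCtMatrix(expressionConfig(seed = 29,
                                                           regime = "DD")))
  cm <- spearmanMatrix(rq, regime = "DD")
  a <- groupAssignment(correlationGroups(cm))
  perm <- c(7, 2, 9, 4, 1, 10, 3, 8, 5, 6)
  cmP <- new("CorrelationMatrix", rho = cm@rho[perm, perm],
             p = cm@p[perm, perm], n = cm@n)
  aP <- groupAssignment(correlationGroups(cmP))
  # same partition regardless of gene order (labels may differ)
  for (i in 1:9) for (j in (i + 1):10) {
    gi <- names(aP)[i]; gj <- names(aP)[j]
    expect_identical(unname(aP[i] == aP[j]), unname(a[gi] == a[gj]))
  }
  # a lone gene forms its own group
  single <- new("CorrelationMatrix",
                rho = matrix(1, 1, 1, dimnames = list("g1", "g1")),
                p = matrix(0, 1, 1, dimnames = list("g1", "g1")), n = 10L)
  expect_equal(length(groupAssignment(correlationGroups(single))), 1)
})

test_that("the default free-running panel recovers the 6+4 gene partition", {
  ctm <- generateCtMatrix(expressionConfig(seed = 1, regime = "DD"))
  rq <- relativeQuantity(ctm)
  cm <- spearmanMatrix(rq, regime = "DD")
  groups <- correlationGroups(cm)
  a <- groupAssignment(groups)
  truth <- SummarizedExperiment::rowData(ctm)$group[
    match(names(a), SummarizedExperiment::rowData(ctm)$gene)]
  expect_equal(sort(as.vector(table(a))), c(4L, 6L))
  expect_true(all((a == a[1]) == (truth == truth[1])))
})

test_that("correlation tables format with conventional significance stars", {
  rho <- matrix(c(1, 0.9, 0.9, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  p <- matrix(c(0, 5e-4, 5e-4, 0), 2, 2, dimnames = dimnames(rho))
  tab <- formatCorrelationTable(new("CorrelationMatrix", rho = rho, p = p,
                                    n = 30L))
  expect_identical(tab["a", "b"], "***0.9")
  expect_identical(tab["b", "a"], "")
})
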