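## Synthetic qPCR Ct generator.
##
## Expression is generated in Ct space so the comparative-Ct stage is
## exercised end-to-end. Each target gene g in group G follows
##   Ct[g,s] = baseline_g - gain_g * L_G(t_s) - shared[G,s] + eps[g,s]
## with a 24 h cosine latent L_G(t) = cos(2 pi (t - phase_G) / 24), a
## per-sample group-level random effect shared[G,s], and i.i.d. Gaussian
## measurement noise. The shared-effect SD is solved so that the expected
## within-group Pearson correlation of -dCt matches `withinGroupRho`.
## Reference genes are flat: constant mean Ct plus small noise.

defaultClockGenes <- function() {
  data.frame(
    gene = c("Cg6-4photolyase", "CgCry1", "CgpCry", "CgTim", "CgClock",
             "CgPeriod", "CgCry2", "CgBmal", "CgRev-erb", "CgROR"),
    group = c(rep("A", 6), rep("B", 4)),
    stringsAsFactors = FALSE)
}

#' SyntheticExpressionConfig: parameters of the Ct-matrix generator
#'
#' @slot genes data.frame with columns `gene` and `group` (every target gene
#'   belongs to exactly one group).
#' @slot timepoints numeric, sampling times in ZT/CT hours.
#' @slot nReplicates integer(1), animals per timepoint.
#' @slot groupPhaseH named numeric, acrophase (h) of each group's latent.
#' @slot gainCt numeric(1), Ct units of latent swing per unit latent (a gain
#'   of 1 means one Ct cycle, i.e. a two-fold expression swing).
#' @slot baselineCt numeric, per-gene baseline Ct (recycled).
#' @slot withinGroupRho numeric(1), target within-group Pearson correlation of
#'   `-dCt` across samples; the shared-effect SD is solved from it.
#' @slot ctNoiseSd numeric(1), SD of per-well measurement noise (Ct units).
#' @slot referenceGene character(1), name of the housekeeping gene row.
#' @slot referenceCt numeric(1), its constant mean Ct.
#' @slot referenceNoiseSd numeric(1), its (small) noise SD.
#' @slot regime character(1), `"LD"` or `"DD"`; controls ZT vs CT labels.
#' @slot seed integer(1), RNG seed.
#' @export
setClass("SyntheticExpressionConfig",
  representation(genes = "data.frame", timepoints = "numeric",
                 nReplicates = "integer", groupPhaseH = "numeric",
                 gainCt = "numeric", baselineCt = "numeric",
                 withinGroupRho = "numeric", ctNoiseSd = "numeric",
                 referenceGene = "character", referenceCt = "numeric",
                 referenceNoiseSd = "numeric", regime = "character",
                 seed = "integer"))

setValidity("SyntheticExpressionConfig", function(object) {
  msg <- character()
  if (!length(object@timepoints)) msg <- c(msg, "timepoints must be non-empty")
  if (!all(c("gene", "group") %in% names(object@genes)))
    msg <- c(msg, "genes needs columns gene and group")
  else if (anyDuplicated(object@genes$gene))
    msg <- c(msg, "every gene must appear exactly once")
  if (object@nReplicates < 1L) msg <- c(msg, "nReplicates must be >= 1")
  if (!all(unique(object@genes$group) %in% names(object@groupPhaseH)))
    msg <- c(msg, "groupPhaseH must name every group")
  if (object@withinGroupRho < 0 || object@withinGroupRho >= 1)
    msg <- c(msg, "withinGroupRho must lie in [0, 1)")
  if (!object@regime %in% c("LD", "DD")) msg <- c(msg, "regime must be LD or DD")
  if (length(msg)) msg else TRUE
})

#' Build an expression-generator configuration
#'
#' Defaults emulate a clock-gene panel: ten target genes in two groups (six
#' and four genes) sampled at 8 timepoints 3 h apart with 9 animals each
#' (72 samples), group acrophases 12 h apart, and one flat reference gene
#' (`EF1`).
#'
#' @param genes data.frame (`gene`, `group`).
#' @param timepoints ZT/CT sampling hours.
#' @param nReplicates animals per timepoint.
#' @param groupPhaseH named numeric, per-group acrophase (h).
#' @param gainCt latent-to-Ct gain (Ct units).
#' @param baselineCt per-gene baseline Ct, recycled.
#' @param withinGroupRho target within-group Pearson correlation of `-dCt`.
#' @param ctNoiseSd measurement-noise SD (Ct units).
#' @param referenceGene,referenceCt,referenceNoiseSd housekeeping-gene row.
#' @param regime `"LD"` or `"DD"`.
#' @param seed RNG seed.
#' @return a [SyntheticExpressionConfig-class].
#' @export
expressionConfig <- function(genes = defaultClockGenes(),
                             timepoints = c(1, 4, 7, 10, 13, 16, 19, 22),
                             nReplicates = 9,
                             groupPhaseH = c(A = 9, B = 21),
                             gainCt = 1,
                             baselineCt = 22 + 0.4 * seq_len(nrow(genes)),
                             withinGroupRho = 0.70,
                             ctNoiseSd = 0.65,
                             referenceGene = "EF1", referenceCt = 18,
                             referenceNoiseSd = 0.08,
                             regime = "LD", seed = 1L) {
  new("SyntheticExpressionConfig", genes = genes, timepoints = timepoints,
      nReplicates = as.integer(nReplicates), groupPhaseH = groupPhaseH,
      gainCt = gainCt, baselineCt = rep_len(baselineCt, nrow(genes)),
      withinGroupRho = withinGroupRho, ctNoiseSd = ctNoiseSd,
      referenceGene = referenceGene, referenceCt = referenceCt,
      referenceNoiseSd = referenceNoiseSd, regime = regime,
      seed = as.integer(seed))
}

## SD of the group-level shared effect implied by the target correlation.
## With signal variance s2 = gain^2 * var(L) and noise variance e2, the
## within-group correlation is (s2 + v) / (s2 + v + e2) for shared variance v;
## inverting gives v = (rho * e2 - (1 - rho) * s2) / (1 - rho), floored at 0.
sharedEffectSd <- function(rho, signalVar, noiseVar) {
  v <- (rho * noiseVar - (1 - rho) * signalVar) / (1 - rho)
  sqrt(max(v, 0))
}

#' Generate a synthetic Ct matrix
#'
#' @param config a [SyntheticExpressionConfig-class].
#' @return a [CtMatrix-class] whose rowData records each gene's true group
#'   (`NA` for the reference gene).
#' @export
generateCtMatrix <- function(config) {
  validObject(config)
  set.seed(config@seed)
  tp <- config@timepoints
  nRep <- config@nReplicates
  timeH <- rep(tp, each = nRep)
  nS <- length(timeH)
  prefix <- if (config@regime == "LD") "ZT" else "CT"
  tpLabel <- sprintf("%s%d", prefix, rep(tp, each = nRep))
  sampleId <- sprintf("%s_%s%02d_r%d", config@regime, prefix,
                      rep(tp, each = nRep), rep(seq_len(nRep), length(tp)))

  groups <- unique(config@genes$group)
  latent <- sapply(groups, function(g)
    cos(2 * pi * (timeH - config@groupPhaseH[g]) / 24))
  colnames(latent) <- groups
  signalVar <- config@gainCt^2 * mean(apply(latent, 2, function(x)
    sum((x - mean(x))^2) / length(x)))
  sharedSd <- sharedEffectSd(config@withinGroupRho, signalVar,
                             config@ctNoiseSd^2)
  shared <- matrix(if (sharedSd > 0) rnorm(nS * length(groups), 0, sharedSd)
                   else 0, nrow = nS, ncol = length(groups),
                   dimnames = list(NULL, groups))

  genes <- config@genes$gene
  ct <- matrix(NA_real_, nrow = nrow(config@genes) + 1L, ncol = nS,
               dimnames = list(c(genes, config@referenceGene), sampleId))
  for (i in seq_along(genes)) {
    g <- config@genes$group[i]
    eps <- if (config@ctNoiseSd > 0) rnorm(nS, 0, config@ctNoiseSd) else 0
    ct[i, ] <- config@baselineCt[i] - config@gainCt * latent[, g] -
      shared[, g] + eps
  }
  ct[nrow(ct), ] <- config@referenceCt +
    if (config@referenceNoiseSd > 0) rnorm(nS, 0, config@referenceNoiseSd) else 0
  ct <- pmax(ct, 0.1)  # Ct is a cycle count, strictly positive

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(ct = ct),
    rowData = S4Vectors::DataFrame(
      gene = rownames(ct),
      group = c(config@genes$group, NA_character_),
      is_reference = c(rep(FALSE, length(genes)), TRUE)),
    colData = S4Vectors::DataFrame(
      sample_id = sampleId, timepoint_label = tpLabel, time_h = timeH,
      regime = rep(config@regime, nS),
      replicate = rep(seq_len(nRep), length(tp)), row.names = sampleId))
  new("CtMatrix", se, referenceGenes = config@referenceGene)
}
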