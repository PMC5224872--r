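## Plain-text exchange formats: tidy CSV for valve panels and Ct matrices,
## TSV for periodograms and correlation tables, JSON for rhythm reports and
## gene groups, FASTA (+ BED-like truth TSV) for promoter sets.

#' Write a valve panel as tidy CSV
#'
#' Columns: `individual_id`, `time_h`, `regime`, `opening_pct`.
#'
#' @param panel a [ValveActivityPanel-class].
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeValvePanel <- function(panel, path) {
  stopifnot(is(panel, "ValveActivityPanel"))
  ids <- colnames(panel@activity)
  df <- data.frame(
    individual_id = rep(ids, each = length(panel@times)),
    time_h = rep(panel@times, length(ids)),
    regime = rep(panel@regime, length(ids)),
    opening_pct = as.vector(panel@activity))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a valve panel from CSV
#'
#' Accepts the tidy dialect written by [writeValvePanel()] or, with
#' `wide = TRUE`, a wide table whose first columns are `time_h` and `regime`
#' followed by one column per individual.
#'
#' @param path input file.
#' @param wide is the file in wide (time x individuals) layout?
#' @return a [ValveActivityPanel-class].
#' @export
readValvePanel <- function(path, wide = FALSE) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (wide) {
    meta <- c("time_h", "regime")
    ids <- setdiff(names(df), meta)
    act <- as.matrix(df[, ids, drop = FALSE])
    return(new("ValveActivityPanel", times = df$time_h, activity = act,
               regime = df$regime))
  }
  ids <- unique(df$individual_id)
  times <- sort(unique(df$time_h))
  act <- matrix(NA_real_, length(times), length(ids),
                dimnames = list(NULL, ids))
  regime <- character(length(times))
  for (id in ids) {
    sub <- df[df$individual_id == id, ]
    idx <- match(sub$time_h, times)
    act[idx, id] <- sub$opening_pct
    regime[idx] <- sub$regime
  }
  new("ValveActivityPanel", times = times, activity = act, regime = regime)
}

#' Write a Ct matrix as tidy CSV
#'
#' Columns: `sample_id`, `gene`, `timepoint_label`, `regime`, `ct`.
#'
#' @param ct a [CtMatrix-class].
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeCtMatrix <- function(ct, path) {
  stopifnot(is(ct, "CtMatrix"))
  m <- SummarizedExperiment::assay(ct, "ct")
  cd <- SummarizedExperiment::colData(ct)
  df <- data.frame(
    sample_id = rep(colnames(m), each = nrow(m)),
    gene = rep(rownames(m), ncol(m)),
    timepoint_label = rep(cd$timepoint_label, each = nrow(m)),
    regime = rep(cd$regime, each = nrow(m)),
    ct = as.vector(m))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a Ct matrix from tidy CSV
#'
#' @param path input file in the dialect of [writeCtMatrix()].
#' @param referenceGenes character, housekeeping gene names present in the
#'   file.
#' @return a [CtMatrix-class]. `time_h` is parsed from the numeric part of
#'   `timepoint_label`.
#' @export
readCtMatrix <- function(path, referenceGenes = "EF1") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  samples <- unique(df$sample_id)
  genes <- unique(df$gene)
  m <- matrix(NA_real_, length(genes), length(samples),
              dimnames = list(genes, samples))
  m[cbind(match(df$gene, genes), match(df$sample_id, samples))] <- df$ct
  first <- df[!duplicated(df$sample_id), ]
  first <- first[match(samples, first$sample_id), ]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(ct = m),
    colData = S4Vectors::DataFrame(
      sample_id = samples, timepoint_label = first$timepoint_label,
      time_h = as.numeric(gsub("[^0-9.]", "", first$timepoint_label)),
      regime = first$regime, row.names = samples))
  new("CtMatrix", se, referenceGenes = intersect(referenceGenes, genes))
}

cosinorFitAsList <- function(fit) {
  list(tau_h = fit@tau, amplitude = fit@amplitude,
       acrophase_rad = fit@acrophase, mesor = fit@mesor,
       percent_rhythm = fit@pr, p_amplitude = fit@pAmplitude,
       ellipse_excludes_origin = fit@ellipseExcludesOrigin,
       tau_ci_h = fit@tauCI, n = fit@n)
}

rhythmReportAsList <- function(report) {
  list(individual_id = report@individualId, rhythmic = report@rhythmic,
       classification = report@classification, reason = report@reason,
       validated = lapply(report@validated, cosinorFitAsList))
}

#' Write rhythm reports as JSON
#'
#' @param x a [RhythmReport-class] or [PopulationRhythmReport-class].
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeRhythmReport <- function(x, path) {
  obj <- if (is(x, "PopulationRhythmReport")) {
    list(population = rhythmReportAsList(x@groupReport),
         pct_rhythmic = x@pctRhythmic,
         pct_circadian_among_rhythmic = x@pctCircadianAmongRhythmic,
         individuals = lapply(x@perIndividual, rhythmReportAsList))
  } else rhythmReportAsList(x)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write a periodogram as TSV
#'
#' Columns: `period_h`, `power`, `threshold`.
#'
#' @param pg a [PeriodogramResult-class].
#' @param path output file.
#' @return invisibly, the path.
#' @export
writePeriodogram <- function(pg, path) {
  stopifnot(is(pg, "PeriodogramResult"))
  write.table(data.frame(period_h = pg@periods, power = pg@power,
                         threshold = pg@threshold),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a promoter set as FASTA plus a BED-like ground-truth TSV
#'
#' @param promoters the list returned by [generatePromoters()].
#' @param fastaPath FASTA output file.
#' @param truthPath TSV output file (`sequence_id`, `offset`, `motif`).
#' @return invisibly, `fastaPath`.
#' @export
writePromoters <- function(promoters, fastaPath, truthPath) {
  Biostrings::writeXStringSet(promoters$sequences, fastaPath)
  write.table(promoters$truth, truthPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(fastaPath)
}

#' Write relative quantities as tidy CSV
#'
#' Columns: `gene`, `sample_id`, `rq`.
#'
#' @param rq an [RQMatrix-class].
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeRQMatrix <- function(rq, path) {
  stopifnot(is(rq, "RQMatrix"))
  m <- SummarizedExperiment::assay(rq, "rq")
  df <- data.frame(gene = rep(rownames(m), ncol(m)),
                   sample_id = rep(colnames(m), each = nrow(m)),
                   rq = as.vector(m))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write gene groups as JSON
#'
#' @param groups a [GeneGroups-class].
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeGeneGroups <- function(groups, path) {
  stopifnot(is(groups, "GeneGroups"))
  jsonlite::write_json(list(method = groups@method,
                            assignment = as.list(groups@assignment)),
                       path, auto_unbox = TRUE)
  invisible(path)
}
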