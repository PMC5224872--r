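## Synthetic promoter generator: random-background sequences with E-box
## motifs written at known offsets upstream of a transcription start site.
## Coordinate convention: TSS = +1 (there is no position 0); an offset names
## the motif's 5'-most base, so offset -1 is the base immediately upstream of
## the TSS.

#' SyntheticPromoterConfig: parameters of the promoter generator
#'
#' @slot nSequences integer(1).
#' @slot lengthBp integer(1), promoter (upstream) length in bases.
#' @slot transcriptBp integer(1), downstream stub after the TSS so the TSS is
#'   an interior base.
#' @slot plantedMotifs data.frame with columns `sequence_id` (1-based index)
#'   and `offset` (negative bp of the motif's 5' base relative to the TSS).
#' @slot motif character(1), motif to plant (default the canonical E-box).
#' @slot backgroundGc numeric(1), background GC fraction.
#' @slot excludeMotif logical(1); when TRUE the background is scrubbed of
#'   chance motif occurrences (for negative controls).
#' @slot seed integer(1).
#' @export
setClass("SyntheticPromoterConfig",
  representation(nSequences = "integer", lengthBp = "integer",
                 transcriptBp = "integer", plantedMotifs = "data.frame",
                 motif = "character", backgroundGc = "numeric",
                 excludeMotif = "logical", seed = "integer"))

setValidity("SyntheticPromoterConfig", function(object) {
  msg <- character()
  if (object@nSequences < 1L) msg <- c(msg, "nSequences must be >= 1")
  if (object@lengthBp < nchar(object@motif))
    msg <- c(msg, "lengthBp must be at least the motif length")
  pm <- object@plantedMotifs
  if (nrow(pm)) {
    if (!all(c("sequence_id", "offset") %in% names(pm)))
      msg <- c(msg, "plantedMotifs needs columns sequence_id and offset")
    else {
      if (any(pm$offset > -1 | pm$offset < -object@lengthBp))
        msg <- c(msg, "planted offsets must lie in [-lengthBp, -1]")
      if (any(pm$sequence_id < 1 | pm$sequence_id > object@nSequences))
        msg <- c(msg, "plantedMotifs sequence_id out of range")
    }
  }
  if (object@backgroundGc < 0 || object@backgroundGc > 1)
    msg <- c(msg, "backgroundGc must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Build a promoter-generator configuration
#'
#' @param nSequences number of promoter records.
#' @param lengthBp upstream window length (bp).
#' @param plantedMotifs data.frame (`sequence_id`, `offset`), offsets negative.
#' @param motif motif string (default `"CACGTG"`).
#' @param backgroundGc background GC fraction.
#' @param transcriptBp downstream stub length.
#' @param excludeMotif scrub chance background occurrences of the motif.
#' @param seed RNG seed.
#' @return a [SyntheticPromoterConfig-class].
#' @export
promoterConfig <- function(nSequences = 3, lengthBp = 2000,
                           plantedMotifs = data.frame(sequence_id = integer(),
                                                      offset = integer()),
                           motif = "CACGTG", backgroundGc = 0.35,
                           transcriptBp = 50, excludeMotif = FALSE,
                           seed = 1L) {
  new("SyntheticPromoterConfig", nSequences = as.integer(nSequences),
      lengthBp = as.integer(lengthBp), transcriptBp = as.integer(transcriptBp),
      plantedMotifs = plantedMotifs, motif = motif,
      backgroundGc = backgroundGc, excludeMotif = excludeMotif,
      seed = as.integer(seed))
}

## Replace chance occurrences of the motif by mutating their third base;
## repeated until the string is motif-free (bounded, since each pass
## destroys all current occurrences).
scrubMotif <- function(x, motif) {
  for (pass in 1:20) {
    hits <- gregexpr(motif, x, fixed = TRUE)[[1]]
    if (hits[1] == -1L) return(x)
    swap <- c(A = "C", C = "T", G = "A", T = "G")
    for (h in hits) {
      pos <- h + 2L
      substr(x, pos, pos) <- swap[[substr(x, pos, pos)]]
    }
  }
  x
}

#' Generate synthetic promoter sequences with planted E-boxes
#'
#' Each record is `lengthBp` bases of random background upstream of a TSS
#' plus a short downstream stub; the motif is written with its 5' base at
#' each planted (negative) offset. Chance background occurrences of the motif
#' are permitted unless `excludeMotif`; any found inside the upstream window
#' are returned as `collisions`.
#'
#' @param config a [SyntheticPromoterConfig-class].
#' @return a list with `sequences` (a [Biostrings::DNAStringSet] whose
#'   `mcols()$tss` gives the 1-based TSS index), `truth` (data.frame
#'   `sequence_id`, `offset`, `motif` of the plants) and `collisions`
#'   (data.frame of unplanted in-window occurrences).
#' @export
generatePromoters <- function(config) {
  validObject(config)
  set.seed(config@seed)
  gc <- config@backgroundGc
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  totalLen <- config@lengthBp + config@transcriptBp
  tss <- config@lengthBp + 1L
  seqs <- character(config@nSequences)
  for (i in seq_len(config@nSequences)) {
    s <- paste(sample(names(probs), totalLen, replace = TRUE, prob = probs),
               collapse = "")
    if (config@excludeMotif) s <- scrubMotif(s, config@motif)
    seqs[i] <- s
  }
  pm <- config@plantedMotifs
  for (k in seq_len(nrow(pm))) {
    i <- pm$sequence_id[k]
    pos <- tss + pm$offset[k]  # offset -1 -> base tss - 1
    end <- pos + nchar(config@motif) - 1L
    substr(seqs[i], pos, end) <- config@motif
  }
  dss <- Biostrings::DNAStringSet(seqs)
  names(dss) <- sprintf("promoter%02d", seq_len(config@nSequences))
  S4Vectors::mcols(dss)$tss <- rep(tss, config@nSequences)

  truth <- data.frame(sequence_id = names(dss)[pm$sequence_id],
                      offset = pm$offset,
                      motif = rep(config@motif, nrow(pm)),
                      stringsAsFactors = FALSE)
  hits <- scanEbox(dss, windowBp = config@lengthBp, motif = config@motif)
  key <- paste(hits$sequence_id, hits$offset)
  planted <- paste(truth$sequence_id, truth$offset)
  collisions <- hits[!key %in% planted, , drop = FALSE]
  list(sequences = dss, truth = truth, collisions = collisions)
}
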