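## Sequence-level utilities: longest-ORF accounting on oriented cDNA,
## translation, and E-box scanning in promoter windows upstream of a TSS.

asDnaString <- function(x) {
  if (is(x, "DNAString")) return(x)
  if (is.character(x)) return(Biostrings::DNAString(x))
  stop("expected a DNAString or a character sequence")
}

#' Find the longest forward-strand open reading frame
#'
#' Scans all three forward frames for ATG..stop frames (cDNA from oriented
#' RACE products; no reverse-strand search). The stop codon is included in
#' the reported length. Ties are broken by the smallest start index.
#'
#' @param x a [Biostrings::DNAString] or character sequence (A/C/G/T/N).
#' @return an [OpenReadingFrame-class]; when no ORF exists, one with
#'   `lengthBp = 0` and `NA` coordinates (test with [orfFound()]).
#' @export
findLongestOrf <- function(x) {
  s <- toupper(as.character(asDnaString(x)))
  n <- nchar(s)
  if (n < 6) stop("sequence too short for an ORF (need >= 6 bases)")
  best <- c(start = NA_integer_, len = 0L)
  stops <- c("TAA", "TAG", "TGA")
  for (frame in 0:2) {
    starts <- seq.int(1L + frame, n - 2L, by = 3L)
    codons <- substring(s, starts, starts + 2L)
    open <- NA_integer_  # index (in codons) of the earliest unclosed ATG
    for (j in seq_along(codons)) {
      if (is.na(open) && codons[j] == "ATG") open <- j
      else if (!is.na(open) && codons[j] %in% stops) {
        len <- (j - open + 1L) * 3L
        if (len > best["len"]) best <- c(start = starts[open], len = len)
        open <- NA_integer_
      }
    }
  }
  if (best["len"] == 0L)
    return(new("OpenReadingFrame", start = NA_integer_, end = NA_integer_,
               lengthBp = 0L))
  new("OpenReadingFrame", start = unname(best["start"]),
      end = unname(best["start"] + best["len"] - 1L),
      lengthBp = unname(best["len"]))
}

#' Was an ORF found?
#' @param orf an [OpenReadingFrame-class].
#' @return logical(1).
#' @export
orfFound <- function(orf) orf@lengthBp > 0L

#' Codon count of an ORF (stop slot included)
#'
#' Reports `lengthBp / 3`, the "encoded amino acids" convention that counts
#' the stop-codon slot (a 3945 bp frame gives 1315); the biological protein
#' length excluding the stop is `codonCount - 1`, as returned by
#' [translateOrf()].
#'
#' @param orf an [OpenReadingFrame-class], or a frame length in bases.
#' @return integer codon count.
#' @export
codonCount <- function(orf) {
  len <- if (is(orf, "OpenReadingFrame")) orf@lengthBp else as.integer(orf)
  if (length(len) != 1L || is.na(len) || len <= 0L)
    stop("a found ORF (positive length) is required")
  if (len %% 3L != 0L) stop("ORF length must be divisible by 3")
  len %/% 3L
}

#' Translate an ORF to its protein sequence
#'
#' Standard genetic code; the stop codon is excluded from the returned
#' string, so the protein length is `codonCount(orf) - 1`. Codons containing
#' `N` translate to `X`.
#'
#' @param orf an [OpenReadingFrame-class] located on `x`.
#' @param x the sequence the ORF was found in.
#' @return character(1) amino-acid string.
#' @export
translateOrf <- function(orf, x) {
  if (!orfFound(orf)) stop("cannot translate: no ORF found")
  dna <- Biostrings::subseq(asDnaString(x), orf@start, orf@end)
  aa <- as.character(Biostrings::translate(dna, if.fuzzy.codon = "X"))
  if (!endsWith(aa, "*")) stop("ORF does not end in a stop codon")
  body <- substr(aa, 1L, nchar(aa) - 1L)
  if (grepl("*", body, fixed = TRUE)) stop("internal stop codon: invalid ORF")
  body
}

#' Scan for E-box motifs upstream of transcription start sites
#'
#' Exact-match scan of the window `[TSS - windowBp, TSS - 1]` of each record
#' (truncated at the sequence start when shorter). Offsets are negative and
#' name the motif's 5'-most base relative to the TSS (= +1; no position 0).
#' The canonical E-box CACGTG is its own reverse complement, so scanning one
#' strand is strand-complete for it.
#'
#' @param seqs a [Biostrings::DNAStringSet]; TSS positions are taken from
#'   `mcols(seqs)$tss` unless given via `tss`. A single [Biostrings::DNAString]
#'   or character sequence is also accepted together with `tss`.
#' @param tss optional integer vector of 1-based TSS indices, recycled.
#' @param windowBp upstream window length (default 2000 bp).
#' @param motif motif string (default `"CACGTG"`).
#' @return data.frame with columns `sequence_id`, `start`, `end` (1-based
#'   in-sequence coordinates), `motif` and `offset` (bp relative to TSS).
#' @export
scanEbox <- function(seqs, tss = NULL, windowBp = 2000, motif = "CACGTG") {
  if (!is(seqs, "DNAStringSet")) {
    seqs <- Biostrings::DNAStringSet(as.character(asDnaString(seqs)))
    if (is.null(names(seqs))) names(seqs) <- "seq1"
  }
  if (is.null(tss)) tss <- S4Vectors::mcols(seqs)$tss
  if (is.null(tss)) stop("TSS positions are required (tss argument or mcols(seqs)$tss)")
  tss <- rep_len(as.integer(tss), length(seqs))
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    lo <- max(1L, tss[i] - as.integer(windowBp))
    hi <- tss[i] - 1L
    if (hi < lo) next
    win <- Biostrings::subseq(seqs[[i]], lo, hi)
    m <- Biostrings::matchPattern(motif, win)
    if (!length(m)) next
    st <- Biostrings::start(m) + lo - 1L
    out[[i]] <- data.frame(sequence_id = names(seqs)[i], start = st,
                           end = st + nchar(motif) - 1L, motif = motif,
                           offset = st - tss[i], stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(sequence_id = character(), start = integer(),
                      end = integer(), motif = character(), offset = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}
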