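#' GC content of nucleotide sequences
#'
#' Fraction (G + C) / (A + C + G + T). Ambiguity codes and N are excluded
#' from both numerator and denominator; a sequence with no unambiguous
#' bases returns `NA_real_`.
#'
#' @param seq A `DNAStringSet`, `DNAString`, or character vector.
#' @return Numeric vector of GC fractions in \[0, 1\] (or `NA`).
#' @export
gc_content <- function(seq) {
  if (is.character(seq)) seq <- Biostrings::DNAStringSet(toupper(seq))
  if (methods::is(seq, "DNAString")) seq <- Biostrings::DNAStringSet(seq)
  if (any(Biostrings::width(seq) == 0L)) {
    data_error("gc_content: empty sequence")
  }
  counts <- Biostrings::letterFrequency(seq, letters = c("A", "C", "G", "T"))
  gc <- counts[, "G"] + counts[, "C"]
  denom <- rowSums(counts)
  ifelse(denom > 0, gc / denom, NA_real_)
}

#' N50 of a set of contig lengths
#'
#' The length of the contig at which the cumulative sum of lengths, sorted
#' descending, first reaches half the total. Always equals the length of
#' some contig and is invariant to input order.
#'
#' @param lengths Vector of positive contig lengths (bp).
#' @return N50 in bp.
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0L) data_error("n50: empty length list")
  if (any(lengths <= 0)) data_error("n50: non-positive length")
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1L]]
}

#' Whole-assembly summary statistics
#'
#' Total size, contig count, N50, and pooled GC. GC is pooled over all
#' unambiguous bases of the assembly (equivalently, the length-weighted mean
#' of per-contig GC over unambiguous bases), not a per-contig average.
#'
#' @param contigs Named `DNAStringSet`.
#' @return One-row `data.frame` with `total_size`, `n_contigs`, `n50`,
#'   `gc_percent` (percent, full precision).
#' @export
assembly_stats <- function(contigs) {
  if (length(contigs) == 0L) data_error("assembly_stats: no contigs")
  counts <- Biostrings::letterFrequency(contigs,
                                        letters = c("A", "C", "G", "T"))
  tot <- colSums(counts)
  denom <- sum(tot)
  gc_pct <- if (denom > 0) 100 * (tot[["G"]] + tot[["C"]]) / denom else
    NA_real_
  data.frame(
    total_size = sum(Biostrings::width(contigs)),
    n_contigs = length(contigs),
    n50 = n50(Biostrings::width(contigs)),
    gc_percent = gc_pct)
}
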