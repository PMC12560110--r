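# Independent oracles and small data constructors used across the suite.
# The oracles deliberately avoid the package's own code paths: the SAM
# pileup is a line-by-line CIGAR walk, and the protein-search oracle
# re-implements hit selection around per-pair alignments.

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
               replace = TRUE), collapse = "")
}

# iid residue substitutions at rate d
mutate_protein <- function(seq, d) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  v <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(v)) < d)
  for (i in hit) v[i] <- sample(setdiff(aa, v[i]), 1)
  paste(v, collapse = "")
}

# iid substitutions at rate d; returns the mutated character string
mutate_dna <- function(seq, d) {
  v <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(v)) < d)
  for (i in hit) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  paste(v, collapse = "")
}

dna_set <- function(...) {
  x <- c(...)
  Biostrings::DNAStringSet(x)
}

aa_set <- function(...) {
  x <- c(...)
  Biostrings::AAStringSet(x)
}

# --- SAM construction and an independent hand pileup ------------------

sam_header <- function(lens) {
  c("@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", names(lens), lens))
}

sam_line <- function(qname, flag, rname, pos, mapq, cigar, seqlen) {
  sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
          qname, flag, rname, pos, mapq, cigar,
          strrep("A", seqlen), strrep("F", seqlen))
}

write_sam <- function(lens, read_lines, path = tempfile(fileext = ".sam")) {
  writeLines(c(sam_header(lens), read_lines), path)
  path
}

# Oracle pileup: walks each alignment line's CIGAR, counting M/=/X and D
# as reference-consuming and covered; honors the primary/duplicate/MAPQ
# filters by inspecting FLAG bits directly.
oracle_pileup <- function(sam_path, lens, min_mapq = 0) {
  tracks <- lapply(lens, function(n) integer(n))
  for (ln in readLines(sam_path)) {
    if (startsWith(ln, "@")) next
    f <- strsplit(ln, "\t")[[1]]
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) > 0L) next      # unmapped
    if (bitwAnd(flag, 256L) > 0L) next    # secondary
    if (bitwAnd(flag, 1024L) > 0L) next   # duplicate
    if (bitwAnd(flag, 2048L) > 0L) next   # supplementary
    if (as.integer(f[5]) < min_mapq) next
    rname <- f[3]
    ref_pos <- as.integer(f[4])
    ops <- regmatches(f[6], gregexpr("[0-9]+[MIDNSHP=X]", f[6]))[[1]]
    for (op in ops) {
      n <- as.integer(sub("[A-Z=]$", "", op))
      type <- sub("^[0-9]+", "", op)
      if (type %in% c("M", "=", "X", "D")) {
        tracks[[rname]][ref_pos:(ref_pos + n - 1L)] <-
          tracks[[rname]][ref_pos:(ref_pos + n - 1L)] + 1L
        ref_pos <- ref_pos + n
      } else if (type == "N") {
        ref_pos <- ref_pos + n
      }
      # I, S, H, P consume no reference
    }
  }
  tracks
}

# --- protein-search oracle --------------------------------------------

# Best qualifying hit by brute per-pair alignment with independent
# threshold logic (coverage, score floor, tie-breaks).
oracle_best_hit <- function(query, targets, min_cov = 70, min_score = 50) {
  data(BLOSUM62, package = "Biostrings", envir = environment())
  best <- NULL
  for (tid in sort(names(targets))) {
    aln <- Biostrings::pairwiseAlignment(
      query, targets[[tid]], type = "local",
      substitutionMatrix = BLOSUM62, gapOpening = 11, gapExtension = 1)
    pat <- Biostrings::pattern(aln)
    cov <- 100 * (IRanges::end(pat) - IRanges::start(pat) + 1) /
      length(query)
    sc <- Biostrings::score(aln)
    id <- Biostrings::pid(aln, type = "PID1")
    if (cov < min_cov || sc < min_score) next
    if (is.null(best) || sc > best$score ||
        (sc == best$score && id > best$identity)) {
      best <- list(subject_id = tid, score = sc, identity = id,
                   coverage = cov)
    }
  }
  best
}
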