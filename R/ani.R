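#' ANIb parameters
#'
#' Fragmentation, hit-filtering and alignment-scoring parameters for
#' fragment-based average nucleotide identity. The defaults follow the
#' ANIb convention: 1020-bp fragments, hits kept when identity is at
#' least 30% and at least 70% of the fragment aligns. Local alignment
#' scoring is match +2, mismatch -3, gap open -5, gap extend -2.
#' Candidate reference loci are located by shared exact `seed_k`-mers
#' sampled every `seed_stride` bp along the fragment; set
#' `exhaustive = TRUE` to skip seeding and align each fragment against
#' every full reference sequence (slower, used as an internal check of the
#' seeding approximation).
#'
#' @param fragment_bp Fragment length, bp (default 1020).
#' @param min_identity Minimum hit identity, percent (default 30).
#' @param min_frag_cov Minimum fragment coverage, percent (default 70).
#' @param seed_k Seed k-mer size (default 15).
#' @param seed_stride Spacing of seed k-mers along the fragment (default 25).
#' @param pad Reference window padding around the seeded locus, bp
#'   (default 200).
#' @param match,mismatch,gap_open,gap_ext Alignment scores (defaults
#'   2, -3, 5, 2; gap parameters are penalties).
#' @param exhaustive Align against full reference sequences instead of
#'   seeded windows (default `FALSE`).
#' @return A list of class `ani_params`.
#' @export
ani_params <- function(fragment_bp = 1020L, min_identity = 30,
                       min_frag_cov = 70, seed_k = 15L, seed_stride = 25L,
                       pad = 200L, match = 2, mismatch = -3, gap_open = 5,
                       gap_ext = 2, exhaustive = FALSE) {
  stopifnot(fragment_bp > 0, min_identity > 0, min_identity <= 100,
            min_frag_cov > 0, min_frag_cov <= 100, seed_k >= 8)
  structure(list(fragment_bp = as.integer(fragment_bp),
                 min_identity = min_identity, min_frag_cov = min_frag_cov,
                 seed_k = as.integer(seed_k),
                 seed_stride = as.integer(seed_stride),
                 pad = as.integer(pad), match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_ext = gap_ext,
                 exhaustive = isTRUE(exhaustive)),
            class = "ani_params")
}

ani_subst_matrix <- function(params) {
  Biostrings::nucleotideSubstitutionMatrix(
    match = params$match, mismatch = params$mismatch, baseOnly = FALSE,
    type = "DNA")
}

#' Cut a genome into consecutive fragments
#'
#' Each contig is cut into consecutive non-overlapping windows of
#' `fragment_bp`; a terminal remainder shorter than `fragment_bp` is kept
#' as its own fragment. Fragment names are `contig_id:start-end`.
#'
#' @param contigs Named `DNAStringSet`.
#' @param fragment_bp Fragment length (default 1020).
#' @return Named `DNAStringSet` of fragments.
#' @export
fragment_genome <- function(contigs, fragment_bp = 1020L) {
  if (length(contigs) == 0L) data_error("fragment_genome: empty assembly")
  frags <- list()
  for (cid in names(contigs)) {
    n <- Biostrings::width(contigs[cid])
    starts <- seq.int(1L, n, by = fragment_bp)
    ends <- pmin(starts + fragment_bp - 1L, n)
    f <- Biostrings::DNAStringSet(contigs[[cid]],
                                  start = starts, end = ends)
    names(f) <- sprintf("%s:%d-%d", cid, starts, ends)
    frags[[cid]] <- f
  }
  do.call(c, unname(frags))
}

# Rolling 2-bit k-mer hashes of a DNA sequence: position i gets the base-4
# value of the k-mer starting there (NA when it contains a non-ACGT letter).
# 4^15 ~ 1.07e9, exactly representable in doubles.
kmer_hashes <- function(seq, k) {
  x <- as.character(seq)
  codes <- match(strsplit(x, "", fixed = TRUE)[[1L]],
                 c("A", "C", "G", "T")) - 1L
  n <- length(codes)
  if (n < k) return(numeric(0))
  m <- n - k + 1L
  h <- numeric(m)
  for (j in 0:(k - 1L)) {
    h <- h + codes[(1L + j):(m + j)] * 4^(k - 1L - j)
  }
  h
}

# Sorted k-mer position index of one reference strand, for exact-seed
# lookup by binary search.
kmer_index <- function(seq, k) {
  h <- kmer_hashes(seq, k)
  pos <- which(!is.na(h))
  hv <- h[pos]
  ord <- order(hv)
  list(hash = hv[ord], pos = pos[ord])
}

# Reference positions whose k-mer equals any query hash; returns the
# alignment diagonals (ref_pos - seed_start).
seed_hits <- function(index, seed_hashes, seed_starts) {
  if (length(index$hash) == 0L) return(integer(0))
  hi <- findInterval(seed_hashes, index$hash)
  lo <- findInterval(seed_hashes - 0.5, index$hash)
  out <- integer(0)
  for (i in which(hi > lo)) {
    out <- c(out, index$pos[(lo[i] + 1L):hi[i]] - seed_starts[i])
  }
  out
}

# Candidate reference windows for one fragment on one subject strand:
# shared seed k-mer diagonals, grouped into loci.
seed_windows <- function(diags, subject_len, frag_len, pad,
                         max_clusters = 3L) {
  if (length(diags) == 0L) return(NULL)
  diags <- sort(diags)
  brk <- c(0L, which(diff(diags) > 50L), length(diags))
  clusters <- lapply(seq_len(length(brk) - 1L), function(j)
    diags[(brk[j] + 1L):brk[j + 1L]])
  support <- vapply(clusters, length, integer(1))
  clusters <- clusters[order(support, decreasing = TRUE)]
  clusters <- clusters[seq_len(min(max_clusters, length(clusters)))]
  do.call(rbind, lapply(clusters, function(cl) {
    c(start = max(1L, min(cl) + 1L - pad),
      end = min(subject_len, max(cl) + frag_len + pad))
  }))
}

# Per-contig, per-strand k-mer indexes (and strand sequences) for a
# reference genome; built once and reused across fragments.
ani_ref_index <- function(reference, params) {
  lapply(stats::setNames(names(reference), names(reference)),
         function(cid) {
    fwd <- reference[[cid]]
    rev <- Biostrings::reverseComplement(fwd)
    list(fwd_seq = fwd, rev_seq = rev,
         fwd_idx = kmer_index(fwd, params$seed_k),
         rev_idx = kmer_index(rev, params$seed_k))
  })
}

#' Best local alignment of a fragment against a reference
#'
#' Locates candidate reference regions through shared exact seed k-mers on
#' both strands, extends each candidate with a Smith-Waterman local
#' alignment at the configured scoring, and reports the best hit. Identity
#' is identical columns over alignment columns; coverage is aligned
#' fragment bases over fragment length. A fragment with no seed match on
#' either strand is unaligned.
#'
#' @param fragment A `DNAString` or single-element `DNAStringSet`.
#' @param reference Named `DNAStringSet`.
#' @param params An [ani_params()] object.
#' @param ref_index Optional prebuilt reference seed index (internal reuse
#'   across the fragments of one genome); built on the fly when `NULL`.
#' @return One-row `data.frame`: `hit` (logical), `identity`, `coverage`,
#'   `score` (NA when unaligned).
#' @export
align_fragment <- function(fragment, reference, params = ani_params(),
                           ref_index = NULL) {
  if (methods::is(fragment, "DNAStringSet")) fragment <- fragment[[1L]]
  frag_len <- length(fragment)
  mat <- ani_subst_matrix(params)
  best <- NULL
  if (is.null(ref_index)) ref_index <- ani_ref_index(reference, params)
  full_scan <- params$exhaustive || frag_len <= params$seed_k
  seeded <- FALSE
  if (!full_scan) {
    seed_starts <- seq.int(1L, frag_len - params$seed_k + 1L,
                           by = params$seed_stride)
    fh <- kmer_hashes(fragment, params$seed_k)[seed_starts]
    keep <- !is.na(fh)
    seed_starts <- seed_starts[keep]
    fh <- fh[keep]
    seeded <- length(fh) > 0L
    # all seeds ambiguous: no candidate loci, fragment stays unaligned
  }
  for (cid in names(reference)) {
    for (strand in c("+", "-")) {
      ri <- ref_index[[cid]]
      subject <- if (strand == "+") ri$fwd_seq else ri$rev_seq
      wins <- if (full_scan) {
        rbind(c(start = 1L, end = length(subject)))
      } else if (!seeded) {
        NULL
      } else {
        idx <- if (strand == "+") ri$fwd_idx else ri$rev_idx
        diags <- seed_hits(idx, fh, seed_starts)
        seed_windows(diags, length(subject), frag_len, params$pad)
      }
      if (is.null(wins)) next
      for (j in seq_len(nrow(wins))) {
        win <- Biostrings::subseq(subject, wins[j, "start"],
                                  wins[j, "end"])
        aln <- Biostrings::pairwiseAlignment(
          fragment, win, type = "local", substitutionMatrix = mat,
          gapOpening = params$gap_open, gapExtension = params$gap_ext)
        sc <- Biostrings::score(aln)
        if (is.null(best) || sc > best$score) {
          pr <- Biostrings::pattern(aln)
          best <- list(
            score = sc,
            identity = Biostrings::pid(aln, type = "PID1"),
            coverage = 100 * (IRanges::end(pr) - IRanges::start(pr) + 1) /
              frag_len)
        }
      }
    }
  }
  if (is.null(best)) {
    data.frame(hit = FALSE, identity = NA_real_, coverage = NA_real_,
               score = NA_real_)
  } else {
    data.frame(hit = TRUE, identity = best$identity,
               coverage = best$coverage, score = best$score)
  }
}

#' Fragment-based average nucleotide identity (ANIb style)
#'
#' Fragments the query genome, aligns every fragment to the reference,
#' retains hits with identity >= `min_identity` and fragment coverage >=
#' `min_frag_cov`, and reports the mean identity of retained hits together
#' with the aligned fraction (retained / total fragments, percent). The
#' result is directional (query vs. a designated reference);
#' `symmetric = TRUE` averages both directions.
#'
#' @param query_contigs,ref_contigs Named `DNAStringSet` genomes.
#' @param params An [ani_params()] object.
#' @param symmetric Average the two directions (default `FALSE`).
#' @param query_id,ref_id Labels for the report.
#' @return One-row `data.frame`: `query_id`, `ref_id`, `ani_percent`
#'   (`NA` when no fragment is retained), `aligned_fraction`,
#'   `n_fragments`, `n_retained`.
#' @export
compute_ani <- function(query_contigs, ref_contigs, params = ani_params(),
                        symmetric = FALSE, query_id = "query",
                        ref_id = "reference") {
  if (length(query_contigs) == 0L || length(ref_contigs) == 0L) {
    data_error("compute_ani: empty genome")
  }
  one_direction <- function(q, r) {
    frags <- fragment_genome(q, params$fragment_bp)
    idx <- ani_ref_index(r, params)
    hits <- do.call(rbind, lapply(seq_along(frags), function(i)
      align_fragment(frags[[i]], r, params, ref_index = idx)))
    keep <- hits$hit & hits$identity >= params$min_identity &
      hits$coverage >= params$min_frag_cov
    list(ani = if (any(keep)) mean(hits$identity[keep]) else NA_real_,
         frac = 100 * sum(keep) / length(frags),
         n = length(frags), kept = sum(keep))
  }
  fwd <- one_direction(query_contigs, ref_contigs)
  if (symmetric) {
    rev <- one_direction(ref_contigs, query_contigs)
    data.frame(query_id = query_id, ref_id = ref_id,
               ani_percent = mean(c(fwd$ani, rev$ani)),
               aligned_fraction = mean(c(fwd$frac, rev$frac)),
               n_fragments = fwd$n + rev$n,
               n_retained = fwd$kept + rev$kept)
  } else {
    data.frame(query_id = query_id, ref_id = ref_id,
               ani_percent = fwd$ani, aligned_fraction = fwd$frac,
               n_fragments = fwd$n, n_retained = fwd$kept)
  }
}
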