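#' Read a FASTA file of contigs or proteins
#'
#' Reads nucleotide or amino-acid FASTA into a `DNAStringSet` /
#' `AAStringSet`. Record ids are taken from the header up to the first
#' whitespace, sequences are upper-cased, and input order is preserved.
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @param mode `"nt"` for nucleotide contigs, `"aa"` for proteins.
#' @return A named [Biostrings::DNAStringSet] (`mode = "nt"`) or
#'   [Biostrings::AAStringSet] (`mode = "aa"`).
#' @details Duplicate ids and empty sequences are hard errors naming the
#'   offending record: downstream classification keys every result on the
#'   contig id, so silent deduplication would corrupt reports.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">c1 a description", "acgt"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, mode = c("nt", "aa")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) data_error("FASTA file not found: %s", path)
  seqs <- if (mode == "nt") {
    Biostrings::readDNAStringSet(path)
  } else {
    Biostrings::readAAStringSet(path)
  }
  if (length(seqs) == 0L) data_error("FASTA file has no records: %s", path)
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    data_error("duplicate sequence id(s) in %s: %s", path,
               paste(dup, collapse = ", "))
  }
  empty <- ids[Biostrings::width(seqs) == 0L]
  if (length(empty) > 0L) {
    data_error("empty sequence(s) in %s: %s", path,
               paste(empty, collapse = ", "))
  }
  names(seqs) <- ids
  # case-fold: lowercase (soft-masked) bases are plain bases here
  up <- toupper(as.character(seqs))
  seqs <- if (mode == "nt") Biostrings::DNAStringSet(up) else
    Biostrings::AAStringSet(up)
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs A named `XStringSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Read a per-base depth table
#'
#' Reads a three-column TSV (`contig_id`, 1-based `pos`, `depth`) into one
#' integer depth track per assembly contig. Positions absent from the table
#' are depth 0; track lengths come from the companion assembly, so every
#' assembly contig gets a track even when the file never mentions it.
#'
#' @param path Path to the depth TSV (no header).
#' @param assembly Named `DNAStringSet`: the assembly the depths refer to.
#' @return Named list of integer vectors, one per assembly contig, each of
#'   length equal to the contig.
#' @export
read_depth_tsv <- function(path, assembly) {
  if (!file.exists(path)) data_error("depth TSV not found: %s", path)
  lens <- stats::setNames(Biostrings::width(assembly), names(assembly))
  tracks <- lapply(lens, function(n) integer(n))
  info <- file.info(path)
  if (is.na(info$size) || info$size == 0) return(tracks)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("contig_id", "pos", "depth"),
                           colClasses = c("character", "integer", "numeric"),
                           quote = "", comment.char = "")
  if (nrow(tab) == 0L) return(tracks)
  unknown <- setdiff(unique(tab$contig_id), names(lens))
  if (length(unknown) > 0L) {
    data_error("depth TSV references contig(s) absent from the assembly: %s",
               paste(unknown, collapse = ", "))
  }
  if (any(tab$depth < 0)) {
    bad <- tab$contig_id[which(tab$depth < 0)[1L]]
    data_error("negative depth for contig %s", bad)
  }
  over <- tab$pos < 1L | tab$pos > lens[tab$contig_id]
  if (any(over)) {
    bad <- tab[which(over)[1L], ]
    data_error("position %d out of range for contig %s (length %d)",
               bad$pos, bad$contig_id, lens[[bad$contig_id]])
  }
  for (cid in unique(tab$contig_id)) {
    sel <- tab$contig_id == cid
    v <- tracks[[cid]]
    v[tab$pos[sel]] <- as.integer(tab$depth[sel])
    tracks[[cid]] <- v
  }
  tracks
}

#' Write depth tracks as a per-base TSV
#'
#' Only positions with non-zero depth are written; [read_depth_tsv()]
#' restores the zero positions from the assembly.
#'
#' @param tracks Named list of integer depth vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_depth_tsv <- function(tracks, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (cid in names(tracks)) {
    v <- tracks[[cid]]
    nz <- which(v > 0L)
    if (length(nz) == 0L) next
    utils::write.table(
      data.frame(cid, nz, v[nz]), con, sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Compute per-base depth tracks from a SAM file
#'
#' Depth at a position is the number of primary, non-duplicate,
#' non-supplementary alignments with mapping quality at least `min_mapq`
#' whose reference span covers it. CIGAR `M`, `=`, `X` and `D` consume
#' reference, and deletion-spanned positions count as covered (samtools-style
#' breadth semantics); insertions and clips never contribute.
#'
#' @param path Path to a plain-text SAM file with `@SQ` headers.
#' @param assembly Named `DNAStringSet` the reads were mapped to.
#' @param min_mapq Minimum mapping quality (default 0: no filter).
#' @return Named list of integer depth vectors, one per assembly contig.
#' @export
depth_from_sam <- function(path, assembly, min_mapq = 0L) {
  if (!file.exists(path)) data_error("SAM file not found: %s", path)
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam))
  hdr <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
  unknown <- setdiff(names(hdr), names(assembly))
  if (length(unknown) > 0L) {
    data_error("SAM reference(s) absent from the assembly: %s",
               paste(unknown, collapse = ", "))
  }
  asm_lens <- stats::setNames(Biostrings::width(assembly), names(assembly))
  mism <- names(hdr)[hdr != asm_lens[names(hdr)]]
  if (length(mism) > 0L) {
    data_error("SAM @SQ length disagrees with the assembly for: %s",
               paste(mism, collapse = ", "))
  }
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(
      isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
      isDuplicate = FALSE, isSupplementaryAlignment = FALSE),
    mapqFilter = as.integer(min_mapq))
  ga <- GenomicAlignments::readGAlignments(bam, param = param)
  cov <- GenomicAlignments::coverage(ga)
  lens <- stats::setNames(Biostrings::width(assembly), names(assembly))
  tracks <- lapply(lens, function(n) integer(n))
  for (cid in names(cov)) {
    if (!cid %in% names(tracks)) next
    v <- as.integer(cov[[cid]])
    # coverage() vectors stop at the last alignment; pad with zeros
    tracks[[cid]][seq_along(v)] <- v
  }
  tracks
}

#' Read features from GFF3 or a tabular feature file
#'
#' GFF3 input goes through [rtracklayer::import()]; the column-9 `product`
#' attribute becomes the `product` column. The tabular fallback is a
#' header-less TSV with columns contig_id, start, end, strand, type,
#' product. Coordinates are 1-based inclusive in both formats.
#'
#' @param path Path to a `.gff`/`.gff3` file or a tabular feature TSV.
#' @return A `data.frame` with columns `contig_id`, `start`, `end`,
#'   `strand`, `ftype`, `product`. `product` is `""` when unannotated,
#'   never `NA`.
#' @export
read_features <- function(path) {
  if (!file.exists(path)) data_error("feature file not found: %s", path)
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path)
    md <- S4Vectors::mcols(gr)
    prod <- if ("product" %in% colnames(md)) as.character(md$product) else
      rep("", length(gr))
    prod[is.na(prod)] <- ""
    out <- data.frame(
      contig_id = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      ftype = as.character(md$type),
      product = prod,
      stringsAsFactors = FALSE)
  } else {
    out <- utils::read.table(
      path, sep = "\t", header = FALSE, quote = "", comment.char = "",
      col.names = c("contig_id", "start", "end", "strand", "ftype",
                    "product"),
      colClasses = c("character", "integer", "integer", "character",
                     "character", "character"))
    out$product[is.na(out$product)] <- ""
  }
  if (any(out$start < 1L | out$end < out$start)) {
    data_error("feature with invalid coordinates on contig %s",
               out$contig_id[which(out$start < 1L | out$end < out$start)[1L]])
  }
  out$strand[is.na(out$strand) | out$strand == "*"] <- "."
  out
}

#' Write features as GFF3
#'
#' @param features Feature `data.frame` as returned by [read_features()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features_gff3 <- function(features, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tsymcurate\t%s\t%d\t%d\t.\t%s\t.\tproduct=%s",
                     features$contig_id, features$ftype, features$start,
                     features$end,
                     ifelse(features$strand %in% c("+", "-"),
                            features$strand, "."),
                     gsub("[;=\t]", " ", features$product)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a taxonomy label table
#'
#' Header-less TSV of `contig_id<TAB>label`. A contig may appear at most
#' once; absence means no label (an explicit NONE state downstream).
#'
#' @param path Path to the taxonomy TSV.
#' @return `data.frame` with columns `contig_id`, `label`.
#' @export
read_taxonomy_tsv <- function(path) {
  if (!file.exists(path)) data_error("taxonomy TSV not found: %s", path)
  info <- file.info(path)
  if (is.na(info$size) || info$size == 0) {
    return(data.frame(contig_id = character(), label = character(),
                      stringsAsFactors = FALSE))
  }
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("contig_id", "label"),
                           colClasses = "character", quote = "",
                           comment.char = "")
  dup <- unique(tab$contig_id[duplicated(tab$contig_id)])
  if (length(dup) > 0L) {
    data_error("multiple taxonomy labels for contig(s): %s",
               paste(dup, collapse = ", "))
  }
  tab
}

#' Write a per-contig call report
#'
#' Writes any per-contig decision table (filter decisions, demux calls,
#' plasmid calls) as a TSV with a fixed header and rows in input order, so
#' re-running on the same input yields a byte-identical file.
#'
#' @param calls A `data.frame` of per-contig calls.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(calls, path) {
  stopifnot(is.data.frame(calls))
  ok <- tryCatch({
    utils::write.table(calls, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) data_error("cannot write report to %s", path)
  invisible(path)
}
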