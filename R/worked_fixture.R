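# A tiny deterministic dataset with hand-checkable outcomes for the filter,
# demux and plasmid rules, including the exact boundary cases (300 bp,
# 42.0% GC, 5.0x depth are all kept). Sequences are built from base-count
# blocks so every GC value is exact by construction; no randomness is used,
# and regeneration is byte-identical.

block_seq <- function(g, c, a, t) {
  paste0(strrep("G", g), strrep("C", c), strrep("A", a), strrep("T", t))
}

worked_fixture_tables <- function() {
  filter_contigs <- c(
    f_keep     = block_seq(72, 72, 128, 128),  # 400 bp, 36% GC
    f_len300   = block_seq(54, 54, 96, 96),    # 300 bp boundary, kept
    f_len299   = block_seq(54, 54, 96, 95),    # 299 bp -> LEN
    f_gc42     = block_seq(84, 84, 116, 116),  # 42.0% boundary, kept
    f_gc43     = block_seq(86, 86, 114, 114),  # 43.0% -> GC
    f_tax_host = block_seq(72, 72, 128, 128),  # host label -> TAX
    f_tax_none = block_seq(72, 72, 128, 128),  # no label -> TAX
    f_cov5     = block_seq(72, 72, 128, 128),  # 5.0x boundary, kept
    f_cov4     = block_seq(72, 72, 128, 128),  # 4x -> COV
    f_len_gc   = block_seq(50, 50, 50, 50))    # 200 bp, 50% -> LEN,GC
  filter_depth <- c(f_keep = 50, f_len300 = 50, f_len299 = 50, f_gc42 = 50,
                    f_gc43 = 50, f_tax_host = 50, f_tax_none = 50,
                    f_cov5 = 5, f_cov4 = 4, f_len_gc = 50)
  filter_labels <- data.frame(
    contig_id = c("f_keep", "f_len300", "f_len299", "f_gc42", "f_gc43",
                  "f_tax_host", "f_cov5", "f_cov4", "f_len_gc"),
    label = c("Cardinium", "Cardinium", "Cardinium", "Cardinium",
              "Cardinium", "host", "Cardinium", "Cardinium", "Cardinium"),
    stringsAsFactors = FALSE)

  demux_contigs <- c(
    d_above          = block_seq(180, 180, 320, 320),  # 1 kb, 36% GC
    d_below          = block_seq(180, 180, 320, 320),
    d_band_uniform   = block_seq(180, 180, 320, 320),
    d_band_localized = block_seq(180, 180, 320, 320))
  demux_tracks <- list(
    d_above = rep(400L, 1000L),
    d_below = rep(20L, 1000L),
    d_band_uniform = rep(200L, 1000L),
    d_band_localized = c(rep(2000L, 100L), rep(0L, 900L)))

  plasmid_contigs <- c(
    p_plasmid = block_seq(930, 930, 2070, 2070),    # 6 kb, 31% GC
    p_chrom = block_seq(3600, 3600, 6400, 6400),    # 20 kb, 36% GC
    p_small = block_seq(620, 620, 1380, 1380))      # 4 kb, 31% GC
  plasmid_features <- rbind(
    data.frame(contig_id = "p_plasmid",
               start = c(100L, 1200L, 2200L, 3000L, 3800L, 4600L, 5400L),
               end = c(1100L, 2100L, 2900L, 3700L, 4500L, 5300L, 5900L),
               strand = "+", ftype = "CDS",
               product = c("ParA family plasmid partitioning protein",
                           "ParB family partition protein",
                           "hypothetical protein", "hypothetical protein",
                           "hypothetical protein", "hypothetical protein",
                           "IS110 family transposase")),
    data.frame(contig_id = "p_chrom",
               start = c(100L, 1200L, 2300L, 3400L, 4500L),
               end = c(1100L, 2200L, 3300L, 4400L, 5500L),
               strand = "+", ftype = "CDS",
               product = c("30S ribosomal protein S3",
                           "DNA gyrase subunit B", "elongation factor Tu",
                           "hypothetical protein", "hypothetical protein")),
    data.frame(contig_id = "p_small",
               start = c(100L, 1200L), end = c(1100L, 1900L),
               strand = "+", ftype = "CDS",
               product = c("ParA family plasmid partitioning protein",
                           "hypothetical protein")))

  expected_filter <- data.frame(
    contig_id = names(filter_contigs),
    kept = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE,
             FALSE),
    reasons = c("", "", "LEN", "", "GC", "TAX", "TAX", "", "COV",
                "LEN,GC"),
    stringsAsFactors = FALSE)
  expected_demux <- data.frame(
    contig_id = names(demux_contigs),
    strain = c("A", "B", "A", "B"),
    rule_fired = c("ABOVE_BAND", "BELOW_BAND", "BAND_UNIFORM",
                   "BAND_LOCALIZED"),
    stringsAsFactors = FALSE)
  expected_plasmid <- data.frame(
    contig_id = names(plasmid_contigs),
    evaluated = c(TRUE, TRUE, FALSE),
    flagged = c(TRUE, FALSE, FALSE),
    traits_met = c("GC,PAR,CONTENT", "", ""),
    stringsAsFactors = FALSE)

  list(filter_contigs = filter_contigs, filter_depth = filter_depth,
       filter_labels = filter_labels, demux_contigs = demux_contigs,
       demux_tracks = demux_tracks, plasmid_contigs = plasmid_contigs,
       plasmid_features = plasmid_features,
       expected_filter = expected_filter,
       expected_demux = expected_demux,
       expected_plasmid = expected_plasmid)
}

#' Write the worked example dataset
#'
#' Writes a small fixed dataset whose filter, demux and plasmid outcomes
#' can be checked by hand (they are stored beside the inputs as
#' `expected_*.tsv`). Regeneration is deterministic and byte-identical; a
#' pre-built copy ships in `inst/extdata/worked_fixture`.
#'
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
make_worked_fixture <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tb <- worked_fixture_tables()

  write_fasta(Biostrings::DNAStringSet(tb$filter_contigs),
              file.path(dir, "filter_contigs.fasta"))
  tracks <- lapply(names(tb$filter_contigs), function(cid)
    rep(as.integer(tb$filter_depth[[cid]]),
        nchar(tb$filter_contigs[[cid]])))
  names(tracks) <- names(tb$filter_contigs)
  write_depth_tsv(tracks, file.path(dir, "filter_depth.tsv"))
  utils::write.table(tb$filter_labels, file.path(dir, "taxonomy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)

  write_fasta(Biostrings::DNAStringSet(tb$demux_contigs),
              file.path(dir, "demux_contigs.fasta"))
  write_depth_tsv(tb$demux_tracks, file.path(dir, "demux_depth.tsv"))

  write_fasta(Biostrings::DNAStringSet(tb$plasmid_contigs),
              file.path(dir, "plasmid_contigs.fasta"))
  write_features_gff3(tb$plasmid_features,
                      file.path(dir, "plasmid_features.gff3"))

  utils::write.table(tb$expected_filter,
                     file.path(dir, "expected_filter.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(tb$expected_demux,
                     file.path(dir, "expected_demux.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(tb$expected_plasmid,
                     file.path(dir, "expected_plasmid.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
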