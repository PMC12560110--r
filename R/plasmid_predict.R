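#' Plasmid-prediction parameters
#'
#' Trait thresholds for flagging plasmid-candidate contigs. Known
#' *Cardinium* plasmids sit around 31.5% GC against ~36% chromosomes, a
#' ~4.5-point gap; `gc_delta_min = 3` flags that depression with margin
#' while excluding ordinary chromosome contigs. Keyword lists are matched
#' case-insensitively as substrings of feature product strings; a feature
#' is "hypothetical" when its product contains "hypothetical" or is empty.
#'
#' @param min_len Minimum contig length evaluated, bp (default 5000).
#' @param gc_delta_min Minimum GC depression below pooled assembly GC, in
#'   percentage points (default 3).
#' @param partition_keywords Partitioning-gene product substrings.
#' @param housekeeping_keywords Housekeeping product substrings.
#' @param mge_keywords Mobile-genetic-element product substrings.
#' @param hypothetical_frac_min Minimum hypothetical-protein fraction for
#'   the gene-content trait (default 0.5).
#' @return A list of class `plasmid_params`.
#' @export
plasmid_params <- function(
    min_len = 5000L,
    gc_delta_min = 3.0,
    partition_keywords = c("parA", "parB", "partition"),
    housekeeping_keywords = c("ribosomal protein", "tRNA ligase",
                              "tRNA synthetase", "DNA polymerase",
                              "RNA polymerase", "gyrase",
                              "elongation factor", "chaperon"),
    mge_keywords = c("transposase", "integrase", "recombinase", "phage"),
    hypothetical_frac_min = 0.5) {
  stopifnot(min_len > 0, length(partition_keywords) > 0,
            length(housekeeping_keywords) > 0, length(mge_keywords) > 0)
  structure(list(min_len = as.integer(min_len), gc_delta_min = gc_delta_min,
                 partition_keywords = partition_keywords,
                 housekeeping_keywords = housekeeping_keywords,
                 mge_keywords = mge_keywords,
                 hypothetical_frac_min = hypothetical_frac_min),
            class = "plasmid_params")
}

keyword_hits <- function(products, keywords) {
  hit <- rep(FALSE, length(products))
  for (kw in keywords) {
    hit <- hit | grepl(kw, products, ignore.case = TRUE, fixed = FALSE)
  }
  hit
}

is_hypothetical <- function(products) {
  products == "" | grepl("hypothetical", products, ignore.case = TRUE)
}

#' Score one contig against the plasmid trait rules
#'
#' Three traits must all hold for a contig of at least `min_len` to be
#' flagged:
#' * `GC` — contig GC at least `gc_delta_min` percentage points below the
#'   pooled assembly GC;
#' * `PAR` — at least one partitioning-gene feature on the contig, and
#'   more than one partitioning feature across the whole assembly;
#' * `CONTENT` — no housekeeping features, together with either a
#'   hypothetical-protein fraction of at least `hypothetical_frac_min` or
#'   at least one mobile-element feature.
#'
#' Contigs below `min_len` are returned unevaluated (`flagged = FALSE`,
#' empty traits).
#'
#' @param contig A single-element named `DNAStringSet` (or `DNAString`
#'   plus `contig_id`).
#' @param features Feature `data.frame` restricted to this contig.
#' @param assembly_gc Pooled assembly GC, percent.
#' @param assembly_partition_copies Count of partitioning-keyword features
#'   in the whole assembly.
#' @param params A [plasmid_params()] object.
#' @param contig_id Contig id (defaults to `names(contig)`).
#' @return One-row `data.frame`: `contig_id`, `length`, `gc_percent`,
#'   `gc_delta`, `partition_hits`, `assembly_partition_copies`,
#'   `housekeeping_count`, `hypothetical_fraction`, `mge_count`,
#'   `traits_met` (comma-joined), `evaluated`, `flagged`.
#' @export
score_contig <- function(contig, features, assembly_gc,
                         assembly_partition_copies,
                         params = plasmid_params(),
                         contig_id = names(contig)) {
  stopifnot(inherits(params, "plasmid_params"))
  if (methods::is(contig, "DNAStringSet")) {
    stopifnot(length(contig) == 1L)
    len <- Biostrings::width(contig)
    gc_pct <- 100 * gc_content(contig)
  } else {
    len <- length(contig)
    gc_pct <- 100 * gc_content(Biostrings::DNAStringSet(
      as.character(contig)))
  }
  prods <- features$product
  n_par <- sum(keyword_hits(prods, params$partition_keywords))
  n_hk <- sum(keyword_hits(prods, params$housekeeping_keywords))
  n_mge <- sum(keyword_hits(prods, params$mge_keywords))
  hyp_frac <- if (length(prods) == 0L) 0 else
    mean(is_hypothetical(prods))
  gc_delta <- assembly_gc - gc_pct
  evaluated <- len >= params$min_len
  traits <- character(0)
  if (evaluated) {
    if (gc_delta >= params$gc_delta_min) traits <- c(traits, "GC")
    if (n_par >= 1L && assembly_partition_copies > 1L) {
      traits <- c(traits, "PAR")
    }
    if (n_hk == 0L &&
        (hyp_frac >= params$hypothetical_frac_min || n_mge >= 1L)) {
      traits <- c(traits, "CONTENT")
    }
  }
  data.frame(
    contig_id = contig_id %||% "contig",
    length = len,
    gc_percent = gc_pct,
    gc_delta = gc_delta,
    partition_hits = n_par,
    assembly_partition_copies = assembly_partition_copies,
    housekeeping_count = n_hk,
    hypothetical_fraction = hyp_frac,
    mge_count = n_mge,
    traits_met = paste(traits, collapse = ","),
    evaluated = evaluated,
    flagged = evaluated && all(c("GC", "PAR", "CONTENT") %in% traits),
    stringsAsFactors = FALSE)
}

#' Predict plasmid-candidate contigs in an assembly
#'
#' Scores every contig with [score_contig()] against the pooled assembly GC
#' and assembly-wide partitioning-gene count, then pools all flagged
#' contigs into a single multi-contig candidate (summed length, pooled GC).
#' Draft assemblies routinely split one plasmid across contigs; with no
#' linkage evidence available, one pooled candidate per assembly is
#' reported.
#'
#' @param assembly Named `DNAStringSet`.
#' @param features Feature `data.frame` for the whole assembly (see
#'   [read_features()]).
#' @param params A [plasmid_params()] object.
#' @return List with `calls` (per-contig score rows, input order) and
#'   `candidate` (`NULL`, or a one-row `data.frame` with `contig_ids`,
#'   `n_contigs`, `total_size`, `gc_percent`).
#' @export
predict_plasmids <- function(assembly, features,
                             params = plasmid_params()) {
  st <- assembly_stats(assembly)
  copies <- sum(keyword_hits(features$product, params$partition_keywords))
  calls <- do.call(rbind, lapply(names(assembly), function(cid) {
    score_contig(assembly[cid], features[features$contig_id == cid, ,
                                         drop = FALSE],
                 assembly_gc = st$gc_percent,
                 assembly_partition_copies = copies,
                 params = params, contig_id = cid)
  }))
  flagged <- calls$contig_id[calls$flagged]
  candidate <- NULL
  if (length(flagged) > 0L) {
    sub <- assembly[flagged]
    candidate <- data.frame(
      contig_ids = paste(flagged, collapse = ","),
      n_contigs = length(flagged),
      total_size = sum(Biostrings::width(sub)),
      gc_percent = assembly_stats(sub)$gc_percent,
      stringsAsFactors = FALSE)
  }
  list(calls = calls, candidate = candidate)
}
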