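#' Contig-filter parameters
#'
#' Thresholds for draft-assembly decontamination. Boundary semantics are
#' literal: a contig is removed when its length is strictly below
#' `min_len`, its GC strictly above `max_gc`, its mean depth strictly below
#' `min_cov`, or its taxonomy label is not `required_label` (no label
#' counts as a failure). Contigs sitting exactly on a threshold are kept.
#'
#' @param min_len Minimum length in bp (default 300).
#' @param max_gc Maximum GC in percent (default 42).
#' @param min_cov Minimum mean read depth (default 5).
#' @param required_label Taxonomy label a contig must carry
#'   (default `"Cardinium"`).
#' @return A list of class `filter_params`.
#' @export
filter_params <- function(min_len = 300L, max_gc = 42, min_cov = 5,
                          required_label = "Cardinium") {
  stopifnot(min_len > 0, max_gc > 0, min_cov > 0,
            nzchar(required_label))
  structure(list(min_len = as.integer(min_len), max_gc = max_gc,
                 min_cov = min_cov, required_label = required_label),
            class = "filter_params")
}

#' Apply contig-removal rules to an assembly
#'
#' The rules are disjunctive ("remove if any fires"); every fired rule is
#' recorded, not just the first. Rule codes: `LEN` (too short), `GC`
#' (GC too high), `TAX` (label missing or not the required taxon), `COV`
#' (mean depth too low). GC is compared on the percent scale at full
#' precision.
#'
#' @param contigs Named `DNAStringSet`.
#' @param summaries Coverage summaries from [summarize_depths()]; every
#'   contig must have one (a missing summary is a hard error).
#' @param labels Taxonomy `data.frame` (`contig_id`, `label`) or `NULL`;
#'   contigs absent from it are unlabeled.
#' @param params A [filter_params()] object.
#' @return `data.frame` with one row per contig in input order:
#'   `contig_id`, `length`, `gc_percent`, `mean_depth`, `label`, `kept`,
#'   `reasons` (comma-joined fired-rule codes, `""` when kept).
#' @export
apply_filters <- function(contigs, summaries, labels = NULL,
                          params = filter_params()) {
  stopifnot(inherits(params, "filter_params"))
  ids <- names(contigs)
  missing_sum <- setdiff(ids, summaries$contig_id)
  if (length(missing_sum) > 0L) {
    data_error("no coverage summary for contig(s): %s",
               paste(missing_sum, collapse = ", "))
  }
  mean_depth <- summaries$mean_depth[match(ids, summaries$contig_id)]
  lens <- Biostrings::width(contigs)
  gc_pct <- 100 * gc_content(contigs)
  lab <- if (is.null(labels) || nrow(labels) == 0L) rep(NA_character_,
                                                        length(ids)) else
    labels$label[match(ids, labels$contig_id)]
  fired <- cbind(
    LEN = lens < params$min_len,
    GC = !is.na(gc_pct) & gc_pct > params$max_gc,
    TAX = is.na(lab) | lab != params$required_label,
    COV = mean_depth < params$min_cov)
  reasons <- apply(fired, 1L, function(r)
    paste(colnames(fired)[r], collapse = ","))
  data.frame(
    contig_id = ids,
    length = lens,
    gc_percent = gc_pct,
    mean_depth = mean_depth,
    label = ifelse(is.na(lab), "NONE", lab),
    kept = !rowSums(fired) > 0,
    reasons = reasons,
    stringsAsFactors = FALSE)
}
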