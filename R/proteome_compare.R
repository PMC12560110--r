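#' Proteome-comparison parameters
#'
#' Scoring and thresholds for pairwise proteome comparison: local
#' alignment under BLOSUM62 with gap open 11 / extend 1, a hit counted as
#' "full-length (or nearly full-length)" when it covers at least
#' `full_length_min_cov` percent of the query, and a raw alignment-score
#' floor (`min_score`) below which a target does not count as a homolog.
#' A raw-score floor is used instead of an e-value because e-value
#' calibration depends on database size; 50 under BLOSUM62 is comfortably
#' above what unrelated proteins of these lengths reach by chance.
#'
#' @param full_length_min_cov Minimum query coverage, percent (default 70).
#' @param unique_min_len Length gate for unique-protein detection,
#'   residues; only proteins strictly longer are considered (default 100).
#' @param min_score Minimum raw alignment score for a hit (default 50).
#' @param gap_open,gap_ext Gap penalties (defaults 11, 1).
#' @return A list of class `compare_params`.
#' @export
compare_params <- function(full_length_min_cov = 70, unique_min_len = 100L,
                           min_score = 50, gap_open = 11, gap_ext = 1) {
  stopifnot(full_length_min_cov > 0, unique_min_len > 0, min_score > 0)
  structure(list(full_length_min_cov = full_length_min_cov,
                 unique_min_len = as.integer(unique_min_len),
                 min_score = min_score, gap_open = gap_open,
                 gap_ext = gap_ext),
            class = "compare_params")
}

blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# Local-align one query against every member of a target proteome.
# Returns per-target score, identity (PID1) and query coverage.
align_query_to_proteome <- function(query, targets, params) {
  mat <- blosum62_matrix()
  aln <- Biostrings::pairwiseAlignment(
    targets, query, type = "local", substitutionMatrix = mat,
    gapOpening = params$gap_open, gapExtension = params$gap_ext)
  sub <- Biostrings::subject(aln)  # aligned region on the query
  data.frame(
    subject_id = names(targets),
    score = Biostrings::score(aln),
    identity = Biostrings::pid(aln, type = "PID1"),
    query_coverage = 100 * (IRanges::end(sub) - IRanges::start(sub) + 1) /
      length(query),
    stringsAsFactors = FALSE)
}

#' Best full-length homolog of a protein in a target proteome
#'
#' Locally aligns the query against every target protein and returns the
#' highest-scoring hit among those covering at least
#' `full_length_min_cov`% of the query with score at least `min_score`.
#' Ties are broken by higher identity, then lexicographic subject id.
#' When no target qualifies, `NULL` is returned; report writers print
#' such absences as identity 0.00.
#'
#' @param query A single-element named `AAStringSet` (or `AAString`).
#' @param target_proteome Named `AAStringSet`.
#' @param params A [compare_params()] object.
#' @return One-row `data.frame` (`query_id`, `subject_id`,
#'   `identity_percent`, `query_coverage_percent`, `score`) or `NULL`.
#' @export
best_full_length_hit <- function(query, target_proteome,
                                 params = compare_params()) {
  query_id <- names(query) %||% "query"
  if (methods::is(query, "AAStringSet")) {
    stopifnot(length(query) == 1L)
    query_id <- names(query)
    query <- query[[1L]]
  }
  if (length(query) == 0L || length(target_proteome) == 0L) {
    data_error("best_full_length_hit: empty query or proteome")
  }
  hits <- align_query_to_proteome(query, target_proteome, params)
  ok <- hits$query_coverage >= params$full_length_min_cov &
    hits$score >= params$min_score
  if (!any(ok)) return(NULL)
  hits <- hits[ok, , drop = FALSE]
  hits <- hits[order(-hits$score, -hits$identity, hits$subject_id), ,
               drop = FALSE]
  data.frame(query_id = query_id %||% "query",
             subject_id = hits$subject_id[1L],
             identity_percent = hits$identity[1L],
             query_coverage_percent = hits$query_coverage[1L],
             score = hits$score[1L],
             stringsAsFactors = FALSE)
}

#' Best-hit identity table for a whole proteome
#'
#' One row per query protein; queries without a qualifying full-length hit
#' get identity and coverage 0 (the printed-report convention for absent
#' homologs) and an empty subject id.
#'
#' @param queries Named `AAStringSet`.
#' @param target_proteome Named `AAStringSet`.
#' @param params A [compare_params()] object.
#' @return `data.frame` with columns as in [best_full_length_hit()].
#' @export
homolog_table <- function(queries, target_proteome,
                          params = compare_params()) {
  do.call(rbind, lapply(names(queries), function(qid) {
    hit <- best_full_length_hit(queries[qid], target_proteome, params)
    if (is.null(hit)) {
      data.frame(query_id = qid, subject_id = "",
                 identity_percent = 0, query_coverage_percent = 0,
                 score = 0, stringsAsFactors = FALSE)
    } else {
      hit
    }
  }))
}

#' Proteins unique to a focal proteome
#'
#' Returns focal proteins strictly longer than `unique_min_len` residues
#' with no qualifying homolog (score >= `min_score` and query coverage >=
#' `full_length_min_cov`) in *any* of the other proteomes.
#'
#' @param focal_proteome Named `AAStringSet`.
#' @param other_proteomes List of named `AAStringSet`s (at least one).
#' @param params A [compare_params()] object.
#' @return Named `AAStringSet` of unique proteins (possibly empty).
#' @export
unique_proteins <- function(focal_proteome, other_proteomes,
                            params = compare_params()) {
  if (!is.list(other_proteomes) || length(other_proteomes) == 0L) {
    usage_error("unique_proteins: need at least one other proteome")
  }
  candidates <- focal_proteome[
    Biostrings::width(focal_proteome) > params$unique_min_len]
  if (length(candidates) == 0L) return(candidates)
  unique_flag <- vapply(names(candidates), function(qid) {
    for (other in other_proteomes) {
      if (!is.null(best_full_length_hit(candidates[qid], other, params))) {
        return(FALSE)
      }
    }
    TRUE
  }, logical(1))
  candidates[unique_flag]
}
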