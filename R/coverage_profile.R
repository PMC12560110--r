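# Window boundaries for a track of length n: consecutive blocks of
# window_bp; a terminal remainder >= window_bp/2 stands alone, a shorter one
# is merged into the previous window; a track shorter than window_bp/2 (or
# than one window, with nothing to merge into) is a single window.
window_bounds <- function(n, window_bp) {
  if (n <= window_bp) return(data.frame(start = 1L, end = n))
  starts <- seq.int(1L, n, by = window_bp)
  ends <- pmin(starts + window_bp - 1L, n)
  k <- length(starts)
  rem <- ends[k] - starts[k] + 1L
  if (k > 1L && rem < window_bp / 2) {
    ends[k - 1L] <- ends[k]
    starts <- starts[-k]; ends <- ends[-k]
  }
  data.frame(start = starts, end = ends)
}

gini_coefficient <- function(x) {
  n <- length(x)
  m <- mean(x)
  if (n <= 1L || m == 0) return(0)
  sx <- sort(x)
  # identity: G = (2 * sum(i * x_(i)) / (n * sum(x))) - (n + 1) / n
  (2 * sum(seq_len(n) * sx) / (n * sum(sx))) - (n + 1) / n
}

#' Summarize a per-base depth track
#'
#' Computes the per-contig coverage summary used by the filtering and
#' demultiplexing rules: mean and median depth, breadth (fraction of
#' positions with depth >= 1), and two window-based uniformity statistics
#' that replace visual inspection of read pileups. *Localization* is the
#' share of total depth mass falling in the `ceiling(top_q * n_windows)`
#' highest-mean windows (0 when the track is empty); a repeat that attracts
#' cross-mapping reads concentrates depth in few windows and drives it
#' toward 1, while uniform coverage keeps it near `top_q`. The Gini
#' coefficient of window mean depths is 0 iff all windows are equal.
#'
#' @param track Integer vector of per-base depths.
#' @param contig_id Contig id recorded in the summary row.
#' @param window_bp Window size in bp (default 500).
#' @param top_q Fraction of windows counted as the "top" set (default 0.1).
#' @return One-row `data.frame`: `contig_id`, `length`, `mean_depth`,
#'   `median_depth`, `breadth`, `n_windows`, `localization`, `gini`.
#' @export
coverage_summary <- function(track, contig_id = "contig", window_bp = 500L,
                             top_q = 0.1) {
  stopifnot(window_bp >= 1L, top_q > 0, top_q < 1)
  track <- as.numeric(track)
  if (length(track) == 0L) data_error("empty depth track for %s", contig_id)
  if (any(track < 0)) data_error("negative depth in track for %s", contig_id)
  wb <- window_bounds(length(track), as.integer(window_bp))
  csum <- cumsum(c(0, track))
  wsum <- csum[wb$end + 1L] - csum[wb$start]
  wlen <- wb$end - wb$start + 1L
  wmean <- wsum / wlen
  total <- sum(track)
  k <- ceiling(top_q * nrow(wb))
  loc <- if (total == 0) 0 else
    sum(wsum[order(wmean, decreasing = TRUE)[seq_len(k)]]) / total
  data.frame(
    contig_id = contig_id,
    length = length(track),
    mean_depth = mean(track),
    median_depth = stats::median(track),
    breadth = mean(track >= 1),
    n_windows = nrow(wb),
    localization = loc,
    gini = gini_coefficient(wmean))
}

#' Summarize every depth track of an assembly
#'
#' @param tracks Named list of integer depth vectors (see
#'   [read_depth_tsv()] / [depth_from_sam()]).
#' @inheritParams coverage_summary
#' @return `data.frame` with one [coverage_summary()] row per contig, in
#'   input order.
#' @export
summarize_depths <- function(tracks, window_bp = 500L, top_q = 0.1) {
  rows <- lapply(names(tracks), function(cid) {
    coverage_summary(tracks[[cid]], cid, window_bp = window_bp,
                     top_q = top_q)
  })
  do.call(rbind, rows)
}

#' Localized-coverage test
#'
#' A summary is "localized" when most depth sits in few windows while most
#' of the contig is bare: `localization >= loc_min` AND
#' `breadth <= breadth_max`. This is the numeric stand-in for spotting
#' repeat-inflated contigs in a pileup viewer.
#'
#' @param summary One-row (or multi-row) `data.frame` from
#'   [coverage_summary()], computed with the same window parameters.
#' @param loc_min Minimum localization (default 0.5).
#' @param breadth_max Maximum breadth (default 0.5).
#' @return Logical vector.
#' @export
is_localized <- function(summary, loc_min = 0.5, breadth_max = 0.5) {
  summary$localization >= loc_min & summary$breadth <= breadth_max
}
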