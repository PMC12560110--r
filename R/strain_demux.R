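#' Demultiplexing parameters
#'
#' Thresholds for assigning contigs of a joint coinfection assembly to the
#' high-density strain (A) or the low-density strain (B) from the mean
#' depth of a single-infection (strain A only) read set. Contigs with mean
#' depth inside `[band_lo, band_hi]` are ambiguous — shared mobile repeats
#' can inflate the apparent coverage of strain-B contigs into this band —
#' and are resolved by the coverage-uniformity rule instead of the plain
#' cutoff: localized coverage means the depth comes from a repeat, so the
#' contig goes to B. The band takes precedence over `high_cut` inside its
#' range; `high_cut` is retained as the nominal assignment threshold and
#' must sit within the band.
#'
#' @param high_cut Nominal strain-A depth cutoff (default 100).
#' @param band_lo,band_hi Manual-assessment band bounds (defaults 60, 350).
#' @param window_bp,top_q Window parameters passed to the uniformity
#'   statistics (defaults 500, 0.1).
#' @param loc_min,breadth_max Localization thresholds (defaults 0.5, 0.5);
#'   see [is_localized()].
#' @return A list of class `demux_params`.
#' @export
demux_params <- function(high_cut = 100, band_lo = 60, band_hi = 350,
                         window_bp = 500L, top_q = 0.1,
                         loc_min = 0.5, breadth_max = 0.5) {
  if (!(band_lo <= high_cut && high_cut <= band_hi)) {
    usage_error("demux_params: need band_lo <= high_cut <= band_hi")
  }
  structure(list(high_cut = high_cut, band_lo = band_lo, band_hi = band_hi,
                 window_bp = as.integer(window_bp), top_q = top_q,
                 loc_min = loc_min, breadth_max = breadth_max),
            class = "demux_params")
}

#' Classify one contig from its single-infection coverage summary
#'
#' Decision rule: mean depth above the band is strain A (`ABOVE_BAND`);
#' below the band, strain B (`BELOW_BAND`); inside the band, localized
#' coverage sends the contig to B (`BAND_LOCALIZED`, repeat-inflated) and
#' uniform coverage to A (`BAND_UNIFORM`). The rule always produces a
#' binary call.
#'
#' @param summary One-row `data.frame` from [coverage_summary()] computed
#'   with the same window parameters.
#' @param params A [demux_params()] object.
#' @return One-row `data.frame`: `contig_id`, `strain` (`"A"`/`"B"`),
#'   `rule_fired`, `mean_depth`, `localization`, `breadth`.
#' @export
classify_contig <- function(summary, params = demux_params()) {
  stopifnot(inherits(params, "demux_params"), nrow(summary) == 1L)
  m <- summary$mean_depth
  if (m > params$band_hi) {
    strain <- "A"; rule <- "ABOVE_BAND"
  } else if (m < params$band_lo) {
    strain <- "B"; rule <- "BELOW_BAND"
  } else if (is_localized(summary, params$loc_min, params$breadth_max)) {
    strain <- "B"; rule <- "BAND_LOCALIZED"
  } else {
    strain <- "A"; rule <- "BAND_UNIFORM"
  }
  data.frame(contig_id = summary$contig_id, strain = strain,
             rule_fired = rule, mean_depth = m,
             localization = summary$localization,
             breadth = summary$breadth, stringsAsFactors = FALSE)
}

#' Demultiplex a joint coinfection assembly
#'
#' Partitions every contig of the joint assembly into strain A or strain B
#' using depth tracks from the single-infection read set. The partition is
#' exhaustive and disjoint, and calls do not depend on contig order.
#'
#' @param assembly Named `DNAStringSet` (joint assembly).
#' @param depths Named list of single-infection depth tracks covering every
#'   assembly contig (zero-filled tracks allowed). Tracks for contigs not
#'   in the assembly are a hard error.
#' @param params A [demux_params()] object.
#' @return List with `calls` (one [classify_contig()] row per contig, input
#'   order), `strain_a` and `strain_b` (`DNAStringSet` partitions).
#' @export
demux_assembly <- function(assembly, depths, params = demux_params()) {
  stray <- setdiff(names(depths), names(assembly))
  if (length(stray) > 0L) {
    data_error("depth track(s) for contig(s) absent from assembly: %s",
               paste(stray, collapse = ", "))
  }
  missing <- setdiff(names(assembly), names(depths))
  if (length(missing) > 0L) {
    data_error("no depth track for contig(s): %s",
               paste(missing, collapse = ", "))
  }
  calls <- do.call(rbind, lapply(names(assembly), function(cid) {
    s <- coverage_summary(depths[[cid]], cid, window_bp = params$window_bp,
                          top_q = params$top_q)
    classify_contig(s, params)
  }))
  list(calls = calls,
       strain_a = assembly[calls$strain == "A"],
       strain_b = assembly[calls$strain == "B"])
}
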