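#' Parameters for the synthetic coinfection generator
#'
#' Defaults emulate the study system the curation pipeline assumes: a
#' high-density symbiont strain (A) and a low-density coinfecting strain
#' (B) diverged by ~10% substitutions, sharing identical transposase-like
#' repeat elements; host contigs at elevated GC; and a low-GC plasmid
#' carrying partitioning genes riding with strain A. Genome sizes are
#' scaled down to 200 kb (from the ~1 Mb genomes of real symbionts) to
#' keep simulation fast; the statistical structure — depth separation,
#' GC contrasts, shared repeats — is preserved at this scale.
#'
#' @param seed Integer seed; all randomness derives from it.
#' @param strainA_size,strainB_size Genome sizes in bp (default 200000).
#' @param divergence_AB Substitution fraction between the strains
#'   (default 0.10, giving an expected ANI near 90).
#' @param strainA_mean_depth,strainB_mean_depth Mean read depths of the
#'   strains in their respective read sets (defaults 300 and 10).
#' @param host_contigs Number of host contigs (default 5).
#' @param host_contig_size Host contig size in bp (default 10000).
#' @param host_gc Host GC fraction (default 0.45, above the 42% filter
#'   cutoff).
#' @param host_mean_depth Host depth in every read set (default 50).
#' @param symbiont_gc Symbiont chromosome GC fraction (default 0.36).
#' @param plasmid_size Plasmid size in bp (default 20000).
#' @param plasmid_gc Plasmid GC fraction (default 0.315).
#' @param split_plasmid Emit the plasmid as two contigs (default `FALSE`).
#' @param n_shared_repeats Number of repeat loci per strain (default 5).
#' @param repeat_size Repeat element length in bp (default 1000).
#' @param read_len Simulated read length in bp (default 150).
#' @param mean_contig_bp Target mean chromosome contig size (default
#'   10000).
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(seed = 1L, strainA_size = 200000L,
                       strainB_size = 200000L, divergence_AB = 0.10,
                       strainA_mean_depth = 300, strainB_mean_depth = 10,
                       host_contigs = 5L, host_contig_size = 10000L,
                       host_gc = 0.45, host_mean_depth = 50,
                       symbiont_gc = 0.36, plasmid_size = 20000L,
                       plasmid_gc = 0.315, split_plasmid = FALSE,
                       n_shared_repeats = 5L, repeat_size = 1000L,
                       read_len = 150L, mean_contig_bp = 10000L) {
  stopifnot(strainA_size > 0, strainB_size > 0, plasmid_size > 0,
            divergence_AB > 0, divergence_AB < 1,
            symbiont_gc > 0, symbiont_gc < 1,
            host_gc > 0, host_gc < 1, plasmid_gc > 0, plasmid_gc < 1,
            read_len > 0)
  structure(list(
    seed = as.integer(seed), strainA_size = as.integer(strainA_size),
    strainB_size = as.integer(strainB_size),
    divergence_AB = divergence_AB,
    strainA_mean_depth = strainA_mean_depth,
    strainB_mean_depth = strainB_mean_depth,
    host_contigs = as.integer(host_contigs),
    host_contig_size = as.integer(host_contig_size), host_gc = host_gc,
    host_mean_depth = host_mean_depth, symbiont_gc = symbiont_gc,
    plasmid_size = as.integer(plasmid_size), plasmid_gc = plasmid_gc,
    split_plasmid = isTRUE(split_plasmid),
    n_shared_repeats = as.integer(n_shared_repeats),
    repeat_size = as.integer(repeat_size), read_len = as.integer(read_len),
    mean_contig_bp = as.integer(mean_contig_bp)), class = "sim_params")
}

random_bases <- function(n, gc) {
  sample(c("A", "T", "G", "C"), n, replace = TRUE,
         prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
}

mutate_bases <- function(x, rate) {
  hit <- which(stats::runif(length(x)) < rate)
  alphabet <- c("A", "C", "G", "T")
  for (i in hit) {
    x[i] <- sample(setdiff(alphabet, x[i]), 1L)
  }
  x
}

# Non-overlapping insertion-point starts for n repeats of length rep_len in
# a genome of length size, drawn on a jittered grid so copies never collide.
repeat_starts <- function(size, n, rep_len) {
  if (n == 0L) return(integer(0))
  if (rep_len >= size || n * rep_len * 2L > size) {
    data_error("repeat configuration infeasible: %d copies of %d bp in %d bp",
               n, rep_len, size)
  }
  slot <- size %/% n
  starts <- vapply(seq_len(n), function(i) {
    lo <- (i - 1L) * slot + 1L
    hi <- i * slot - rep_len
    as.integer(sample(lo:hi, 1L))
  }, integer(1))
  starts
}

# Cut points: a jittered even grid keeps every contig within ~40% of the
# target mean so no chromosome contig falls under the filter length gate.
contig_bounds <- function(size, mean_bp) {
  k <- max(1L, as.integer(round(size / mean_bp)))
  if (k == 1L) return(data.frame(start = 1L, end = size))
  ideal <- round(seq(0, size, length.out = k + 1L))
  jit <- c(0, round(stats::runif(k - 1L, -0.3, 0.3) * mean_bp), 0)
  cuts <- as.integer(ideal + jit)
  data.frame(start = cuts[-(k + 1L)] + 1L, end = cuts[-1L])
}

# Lander-Waterman per-base depth: round(depth * len / read_len) reads of
# read_len placed uniformly (clipped at the contig end).
lw_track <- function(len, depth, read_len) {
  n_reads <- as.integer(round(depth * len / read_len))
  if (n_reads == 0L || depth == 0) return(integer(len))
  max_start <- max(1L, len - read_len + 1L)
  starts <- sample.int(max_start, n_reads, replace = TRUE)
  ends <- pmin(starts + read_len - 1L, len)
  delta <- integer(len + 1L)
  tab_s <- tabulate(starts, nbins = len)
  tab_e <- tabulate(ends + 1L, nbins = len + 1L)
  delta[seq_len(len)] <- tab_s
  delta <- delta - tab_e
  cumsum(delta[seq_len(len)])
}

# Map genome-coordinate repeat intervals onto a contig's local coordinates.
local_repeats <- function(bounds_row, rep_starts, rep_len) {
  s <- pmax(rep_starts, bounds_row$start)
  e <- pmin(rep_starts + rep_len - 1L, bounds_row$end)
  keep <- s <= e
  data.frame(start = s[keep] - bounds_row$start + 1L,
             end = e[keep] - bounds_row$start + 1L)
}

housekeeping_products <- c(
  "30S ribosomal protein S12", "50S ribosomal protein L2",
  "DNA gyrase subunit A", "elongation factor Tu",
  "DNA polymerase III subunit alpha", "chaperonin GroEL",
  "DNA-directed RNA polymerase subunit beta", "alanine--tRNA ligase")

#' Generate a synthetic coinfection dataset with ground truth
#'
#' Builds two symbiont genomes (B derived from A by iid substitutions at
#' `divergence_AB`, so the expected ANI is `(1 - d) * 100`), copies a
#' transposase-like repeat element verbatim into both at several loci,
#' appends a low-GC plasmid (carrying `parA`/`parB`) to the strain-A
#' complement and high-GC host contigs, cuts the chromosomes into contigs
#' at jittered breakpoints, and simulates per-base depth by uniform random
#' read placement. In the single-infection depth set (strain A and host
#' reads only), repeat-free strain-B contigs have depth identically 0,
#' while repeat-bearing intervals receive the strain-A mean depth — a
#' deterministic idealization of reads from strain-A repeat copies
#' cross-mapping onto strain B.
#'
#' @param params A [sim_params()] object.
#' @param out_dir Optional directory; when given, the dataset is written as
#'   `joint_assembly.fasta`, `single_infection_depth.tsv`,
#'   `coinfection_depth.tsv`, `features.gff3`, `taxonomy.tsv`,
#'   `truth.tsv`.
#' @return List with `assembly` (joint `DNAStringSet`), `single_depths`
#'   and `coinf_depths` (named lists of integer tracks), `features`,
#'   `taxonomy`, `truth` (`data.frame`s), `genomes` (uncut strain A / B /
#'   plasmid sequences, for ANI checks), and `params`.
#' @export
generate_community <- function(params = sim_params(), out_dir = NULL) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  p <- params

  genomeA <- random_bases(p$strainA_size, p$symbiont_gc)
  genomeB <- mutate_bases(genomeA, p$divergence_AB)
  if (p$strainB_size < p$strainA_size) {
    genomeB <- genomeB[seq_len(p$strainB_size)]
  } else if (p$strainB_size > p$strainA_size) {
    genomeB <- c(genomeB,
                 random_bases(p$strainB_size - p$strainA_size,
                              p$symbiont_gc))
  }
  repeat_el <- random_bases(p$repeat_size, p$symbiont_gc)
  repA <- repeat_starts(p$strainA_size, p$n_shared_repeats, p$repeat_size)
  repB <- repeat_starts(p$strainB_size, p$n_shared_repeats, p$repeat_size)
  for (s in repA) genomeA[s:(s + p$repeat_size - 1L)] <- repeat_el
  for (s in repB) genomeB[s:(s + p$repeat_size - 1L)] <- repeat_el

  boundsA <- contig_bounds(p$strainA_size, p$mean_contig_bp)
  boundsB <- contig_bounds(p$strainB_size, p$mean_contig_bp)

  contigs <- list(); truth <- list(); features <- list()
  single <- list(); coinf <- list()
  rep_local <- list()

  add_strain <- function(genome, bounds, rep_starts_g, prefix, label) {
    for (i in seq_len(nrow(bounds))) {
      cid <- sprintf("%s_%03d", prefix, i)
      b <- bounds[i, ]
      contigs[[cid]] <<- paste(genome[b$start:b$end], collapse = "")
      reps <- local_repeats(b, rep_starts_g, p$repeat_size)
      rep_local[[cid]] <<- reps
      truth[[cid]] <<- data.frame(contig_id = cid, truth = label,
                                  repeat_bearing = nrow(reps) > 0L)
      len <- b$end - b$start + 1L
      # annotation: housekeeping genes on a grid, transposases on repeats,
      # hypothetical proteins in between
      hk_starts <- seq.int(200L, max(200L, len - 1200L), by = 4000L)
      feats <- data.frame(
        contig_id = cid, start = hk_starts,
        end = pmin(hk_starts + 999L, len), strand = "+", ftype = "CDS",
        product = housekeeping_products[
          (seq_along(hk_starts) - 1L) %% length(housekeeping_products) + 1L])
      hyp_starts <- hk_starts + 2000L
      hyp_starts <- hyp_starts[hyp_starts + 500L <= len]
      if (length(hyp_starts) > 0L) {
        feats <- rbind(feats, data.frame(
          contig_id = cid, start = hyp_starts, end = hyp_starts + 500L,
          strand = "+", ftype = "CDS", product = "hypothetical protein"))
      }
      if (nrow(reps) > 0L) {
        feats <- rbind(feats, data.frame(
          contig_id = cid, start = reps$start, end = reps$end,
          strand = "+", ftype = "CDS",
          product = "IS3 family transposase"))
      }
      features[[cid]] <<- feats[order(feats$start), ]
    }
  }
  add_strain(genomeA, boundsA, repA, "A", "STRAIN_A")
  add_strain(genomeB, boundsB, repB, "B", "STRAIN_B")

  plasmid <- random_bases(p$plasmid_size, p$plasmid_gc)
  plasmid_parts <- if (p$split_plasmid) {
    cut <- as.integer(round(p$plasmid_size * 0.6))
    list(plasmidA_1 = plasmid[1:cut],
         plasmidA_2 = plasmid[(cut + 1L):p$plasmid_size])
  } else {
    list(plasmidA_1 = plasmid)
  }
  par_products <- c("ParA family plasmid partitioning protein",
                    "ParB family partition protein")
  for (i in seq_along(plasmid_parts)) {
    cid <- names(plasmid_parts)[i]
    seqv <- plasmid_parts[[i]]
    len <- length(seqv)
    contigs[[cid]] <- paste(seqv, collapse = "")
    rep_local[[cid]] <- data.frame(start = integer(0), end = integer(0))
    truth[[cid]] <- data.frame(contig_id = cid, truth = "PLASMID_A",
                               repeat_bearing = FALSE)
    feats <- data.frame(
      contig_id = cid, start = 100L, end = 1000L, strand = "+",
      ftype = "CDS",
      # split plasmid: one partitioning gene per part so each carries
      # partitioning evidence; whole plasmid: both genes on the contig
      product = par_products[if (p$split_plasmid) i else 1L])
    if (!p$split_plasmid) {
      feats <- rbind(feats, data.frame(
        contig_id = cid, start = 1100L, end = 1900L, strand = "+",
        ftype = "CDS", product = par_products[2L]))
    }
    hyp_starts <- seq.int(2100L, max(2100L, len - 700L), by = 1500L)
    hyp_starts <- hyp_starts[hyp_starts + 600L <= len]
    feats <- rbind(feats, data.frame(
      contig_id = cid, start = hyp_starts, end = hyp_starts + 600L,
      strand = "+", ftype = "CDS", product = "hypothetical protein"))
    feats <- rbind(feats, data.frame(
      contig_id = cid, start = max(1L, len - 500L), end = len,
      strand = "+", ftype = "CDS",
      product = "IS110 family transposase"))
    features[[cid]] <- feats
  }

  for (i in seq_len(p$host_contigs)) {
    cid <- sprintf("host_%02d", i)
    contigs[[cid]] <- paste(random_bases(p$host_contig_size, p$host_gc),
                            collapse = "")
    rep_local[[cid]] <- data.frame(start = integer(0), end = integer(0))
    truth[[cid]] <- data.frame(contig_id = cid, truth = "HOST",
                               repeat_bearing = FALSE)
  }

  truth <- do.call(rbind, truth); rownames(truth) <- NULL
  features <- do.call(rbind, features); rownames(features) <- NULL
  assembly <- Biostrings::DNAStringSet(unlist(contigs))

  depth_of <- function(cid, dataset) {
    lab <- truth$truth[truth$contig_id == cid]
    len <- nchar(contigs[[cid]])
    own <- switch(lab,
      STRAIN_A = p$strainA_mean_depth,
      PLASMID_A = p$strainA_mean_depth,
      HOST = p$host_mean_depth,
      STRAIN_B = if (dataset == "single") 0 else p$strainB_mean_depth)
    track <- lw_track(len, own, p$read_len)
    reps <- rep_local[[cid]]
    if (nrow(reps) > 0L) {
      # cross-mapping from the other strain's identical repeat copies
      cross <- if (lab == "STRAIN_B") p$strainA_mean_depth
               else if (lab == "STRAIN_A" && dataset == "coinf")
                 p$strainB_mean_depth else 0
      if (cross > 0) {
        for (j in seq_len(nrow(reps))) {
          idx <- reps$start[j]:reps$end[j]
          track[idx] <- track[idx] + as.integer(round(cross))
        }
      }
    }
    track
  }
  for (cid in names(contigs)) {
    single[[cid]] <- depth_of(cid, "single")
    coinf[[cid]] <- depth_of(cid, "coinf")
  }

  taxonomy <- data.frame(
    contig_id = truth$contig_id,
    label = ifelse(truth$truth == "HOST", "host", "Cardinium"),
    stringsAsFactors = FALSE)

  genomes <- list(
    strainA = Biostrings::DNAStringSet(
      stats::setNames(paste(genomeA, collapse = ""), "strainA")),
    strainB = Biostrings::DNAStringSet(
      stats::setNames(paste(genomeB, collapse = ""), "strainB")),
    plasmid = Biostrings::DNAStringSet(
      stats::setNames(paste(plasmid, collapse = ""), "plasmidA")))

  result <- list(assembly = assembly, single_depths = single,
                 coinf_depths = coinf, features = features,
                 taxonomy = taxonomy, truth = truth, genomes = genomes,
                 params = p)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(assembly, file.path(out_dir, "joint_assembly.fasta"))
    write_depth_tsv(single, file.path(out_dir,
                                      "single_infection_depth.tsv"))
    write_depth_tsv(coinf, file.path(out_dir, "coinfection_depth.tsv"))
    write_features_gff3(features, file.path(out_dir, "features.gff3"))
    utils::write.table(taxonomy, file.path(out_dir, "taxonomy.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    utils::write.table(truth, file.path(out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  result
}
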