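# a scaled-down community keeps these tests fast; the structural
# invariants under test do not depend on genome size
small_sim <- function(seed = 11, n_shared_repeats = 2L, ...) {
  sim_params(seed = seed, strainA_size = 40000L, strainB_size = 40000L,
             n_shared_repeats = n_shared_repeats, host_contigs = 2L,
             plasmid_size = 8000L, ...)
}

test_that("the community has the advertised composition and truth table", {
  sim <- generate_community(small_sim())
  expect_setequal(unique(sim$truth$truth),
                  c("STRAIN_A", "STRAIN_B", "PLASMID_A", "HOST"))
  expect_equal(sum(sim$truth$truth == "HOST"), 2L)
  expect_equal(sum(sim$truth$truth == "PLASMID_A"), 1L)
  expect_setequal(names(sim$assembly), sim$truth$contig_id)
  expect_setequal(names(sim$single_depths), names(sim$assembly))
  expect_setequal(names(sim$coinf_depths), names(sim$assembly))
  # tracks match contig lengths
  for (cid in names(sim$assembly)) {
    expect_length(sim$single_depths[[cid]],
                  Biostrings::width(sim$assembly[cid]))
  }
  # contigs reassemble into the uncut genomes
  a_ids <- sim$truth$contig_id[sim$truth$truth == "STRAIN_A"]
  expect_equal(paste(as.character(sim$assembly[a_ids]), collapse = ""),
               as.character(sim$genomes$strainA[[1]]))
  # each strain carries repeat loci (2 loci can straddle cut points, so
  # between 1 and 4 contigs per strain may bear repeat sequence)
  for (pre in c("A_", "B_")) {
    n_bearing <- sum(sim$truth$repeat_bearing[
      startsWith(sim$truth$contig_id, pre)])
    expect_gte(n_bearing, 1L)
    expect_lte(n_bearing, 4L)
  }
  # the repeat features are annotated as transposases
  expect_gt(sum(grepl("transposase", sim$features$product)), 0L)
})

test_that("generation is deterministic in the seed", {
  s1 <- generate_community(small_sim(seed = 7))
  s2 <- generate_community(small_sim(seed = 7))
  expect_identical(as.character(s1$assembly), as.character(s2$assembly))
  expect_identical(s1$single_depths, s2$single_depths)
  expect_identical(s1$features, s2$features)
  s3 <- generate_community(small_sim(seed = 8))
  expect_false(identical(as.character(s1$assembly),
                         as.character(s3$assembly)))
})

test_that("depth structure separates the strains in the single set", {
  sim <- generate_community(small_sim())
  means <- vapply(sim$single_depths, mean, numeric(1))
  tr <- sim$truth
  a_free <- tr$contig_id[tr$truth == "STRAIN_A"]
  b_free <- tr$contig_id[tr$truth == "STRAIN_B" & !tr$repeat_bearing]
  b_rep <- tr$contig_id[tr$truth == "STRAIN_B" & tr$repeat_bearing]
  expect_true(all(means[a_free] > 250))
  expect_true(all(means[b_free] == 0))
  # repeat-bearing B contigs get cross-mapped depth, localized in the
  # repeat interval
  expect_true(all(means[b_rep] > 0))
  sm <- summarize_depths(sim$single_depths[b_rep])
  expect_true(all(is_localized(sm)))
  # in the coinfection set every symbiont contig is covered
  co_means <- vapply(sim$coinf_depths, mean, numeric(1))
  expect_true(all(co_means[tr$contig_id[tr$truth != "HOST"]] > 0))
})

test_that("GC structure matches the configured contrasts", {
  sim <- generate_community(small_sim())
  tr <- sim$truth
  gc <- 100 * gc_content(sim$assembly)
  names(gc) <- names(sim$assembly)
  host <- tr$contig_id[tr$truth == "HOST"]
  plas <- tr$contig_id[tr$truth == "PLASMID_A"]
  chrom <- tr$contig_id[tr$truth %in% c("STRAIN_A", "STRAIN_B")]
  expect_true(all(gc[host] > 42))
  expect_true(all(gc[plas] < mean(gc[chrom])))
  expect_true(all(abs(gc[chrom] - 36) < 4))
})

test_that("divergence parameter controls the realized mismatch fraction", {
  # with no repeat overwriting, strain B is a pure iid mutant of strain A
  sim <- generate_community(small_sim(seed = 5, n_shared_repeats = 0L))
  a <- strsplit(as.character(sim$genomes$strainA[[1]]), "")[[1]]
  b <- strsplit(as.character(sim$genomes$strainB[[1]]), "")[[1]]
  expect_lt(abs(mean(a != b) - 0.10), 0.01)
})

test_that("written outputs round-trip through the package readers", {
  dir <- tempfile("sim")
  sim <- generate_community(small_sim(seed = 3), out_dir = dir)
  expect_setequal(list.files(dir),
                  c("joint_assembly.fasta", "single_infection_depth.tsv",
                    "coinfection_depth.tsv", "features.gff3",
                    "taxonomy.tsv", "truth.tsv"))
  asm <- read_fasta(file.path(dir, "joint_assembly.fasta"))
  expect_identical(as.character(asm), as.character(sim$assembly))
  tracks <- read_depth_tsv(file.path(dir, "single_infection_depth.tsv"),
                           asm)
  expect_identical(tracks[names(sim$single_depths)],
                   lapply(sim$single_depths, as.integer))
  tax <- read_taxonomy_tsv(file.path(dir, "taxonomy.tsv"))
  expect_equal(nrow(tax), length(asm))
})

test_that("infeasible repeat configurations are rejected", {
  expect_error(
    generate_community(sim_params(strainA_size = 5000,
                                  strainB_size = 5000,
                                  n_shared_repeats = 5,
                                  repeat_size = 1000)),
    "infeasible")
})
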