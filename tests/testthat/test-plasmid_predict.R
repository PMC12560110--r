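# assembly with one plasmid-like contig, one chromosome-like contig and
# one short contig; pooled GC sits well above the plasmid contig's GC
plasmid_case <- function() {
  tb <- worked_fixture_tables()
  list(asm = Biostrings::DNAStringSet(tb$plasmid_contigs),
       features = tb$plasmid_features)
}

test_that("keyword matching is case-insensitive substring matching", {
  prods <- c("ParA family plasmid partitioning protein",
             "parb-like protein", "chromosome partitioning protein",
             "30S ribosomal protein S3", "IS110 FAMILY TRANSPOSASE", "")
  expect_equal(keyword_hits(prods, c("parA", "parB", "partition")),
               c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(keyword_hits(prods, c("transposase")),
               c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(is_hypothetical(c("hypothetical protein", "", "gyrase")),
               c(TRUE, TRUE, FALSE))
})

test_that("a contig meeting all three traits is flagged", {
  cs <- plasmid_case()
  res <- predict_plasmids(cs$asm, cs$features)
  row <- res$calls[res$calls$contig_id == "p_plasmid", ]
  expect_true(row$flagged)
  expect_equal(row$traits_met, "GC,PAR,CONTENT")
  expect_gte(row$gc_delta, 3)
  expect_gte(row$partition_hits, 1)
  expect_gt(row$assembly_partition_copies, 1)
  expect_equal(row$housekeeping_count, 0)
})

test_that("housekeeping genes veto the gene-content trait", {
  cs <- plasmid_case()
  res <- predict_plasmids(cs$asm, cs$features)
  row <- res$calls[res$calls$contig_id == "p_chrom", ]
  expect_false(row$flagged)
  expect_false(grepl("CONTENT", row$traits_met))
  expect_gt(row$housekeeping_count, 0)
})

test_that("contigs below the length gate are left unevaluated", {
  cs <- plasmid_case()
  res <- predict_plasmids(cs$asm, cs$features)
  row <- res$calls[res$calls$contig_id == "p_small", ]
  expect_false(row$evaluated)
  expect_false(row$flagged)
  expect_equal(row$traits_met, "")
})

test_that("each trait is individually necessary", {
  cs <- plasmid_case()
  # GC off: raise the required depression beyond the actual delta
  res <- predict_plasmids(cs$asm, cs$features,
                          plasmid_params(gc_delta_min = 20))
  expect_false(any(res$calls$flagged))
  # PAR off: remove partitioning annotations
  feats <- cs$features
  feats$product <- sub("Par[AB] family.*", "hypothetical protein",
                       feats$product)
  res <- predict_plasmids(cs$asm, feats)
  expect_false(any(res$calls$flagged))
  # CONTENT off: put a housekeeping gene on the plasmid contig
  feats <- cs$features
  feats$product[feats$contig_id == "p_plasmid" &
                  feats$product == "hypothetical protein"][1] <-
    "DNA gyrase subunit A"
  feats$product[feats$contig_id == "p_plasmid"] <-
    sub("IS110 family transposase", "hypothetical protein",
        feats$product[feats$contig_id == "p_plasmid"])
  # now: 1 housekeeping present -> CONTENT cannot hold
  res <- predict_plasmids(cs$asm, feats)
  row <- res$calls[res$calls$contig_id == "p_plasmid", ]
  expect_false(row$flagged)
  expect_false(grepl("CONTENT", row$traits_met))
})

test_that("the PAR trait needs more than one partition copy assembly-wide", {
  cs <- plasmid_case()
  # keep a single parA on the plasmid contig, drop all other partition
  # annotations (including p_small's)
  feats <- cs$features
  is_par <- keyword_hits(feats$product, c("parA", "parB", "partition"))
  drop <- which(is_par)[-1]
  feats <- feats[-drop, ]
  res <- predict_plasmids(cs$asm, feats)
  row <- res$calls[res$calls$contig_id == "p_plasmid", ]
  expect_equal(row$assembly_partition_copies, 1)
  expect_false(grepl("PAR", row$traits_met))
  expect_false(row$flagged)
})

test_that("flagged contigs pool into one candidate with pooled GC", {
  cs <- plasmid_case()
  res <- predict_plasmids(cs$asm, cs$features)
  expect_equal(res$candidate$n_contigs, 1)
  expect_equal(res$candidate$contig_ids, "p_plasmid")
  expect_equal(res$candidate$total_size, 6000)
  expect_equal(res$candidate$gc_percent, 31)
  # no flags -> no candidate
  res2 <- predict_plasmids(cs$asm, cs$features,
                           plasmid_params(gc_delta_min = 20))
  expect_null(res2$candidate)
})

test_that("a plasmid split across two contigs pools into one candidate", {
  sim <- generate_community(sim_params(seed = 4, split_plasmid = TRUE))
  res <- predict_plasmids(sim$assembly, sim$features)
  flagged <- res$calls$contig_id[res$calls$flagged]
  expect_setequal(flagged, c("plasmidA_1", "plasmidA_2"))
  expect_equal(res$candidate$n_contigs, 2)
  expect_equal(res$candidate$total_size, 20000)
})
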