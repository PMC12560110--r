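Package: symcurate
Title: Curation of Endosymbiont Draft Genome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for curating draft assemblies of intracellular bacterial
    symbionts sequenced from whole-host DNA. Implements contig filtering on
    length, GC content, taxonomy labels and read depth; differential-coverage
    demultiplexing of two coinfecting strains using a single-infection read
    set, with window-based coverage-uniformity statistics to rescue contigs
    inflated by shared mobile repeats; trait-based plasmid prediction from
    GC depression, partitioning genes and gene-content profiles; ANIb-style
    average nucleotide identity by genome fragmentation and local alignment;
    pairwise proteome comparison (best full-length homolog identities and
    unique-protein detection); and a seeded synthetic coinfection generator
    with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    methods,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
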