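---
title: "Methods: curating coinfected endosymbiont assemblies with symcurate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: curating coinfected endosymbiont assemblies with symcurate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symcurate)
```

## The problem

Intracellular bacterial symbionts such as *Cardinium hertigii* cannot be
cultured, so their genomes are assembled from whole-insect sequencing
libraries. Three contamination/confounding layers must be removed from
such a draft assembly before analysis:

1. **Host and environmental contigs** mixed into the assembly.
2. **A co-resident second symbiont strain**: when two related strains
   infect the same host line, the assembler produces a joint assembly
   whose contigs belong to one strain or the other.
3. **Plasmids**, which should be reported separately from the chromosome.

`symcurate` turns the manual curation recipe for this situation into
deterministic, parameterized, testable rules, and ships a synthetic data
generator that reproduces the statistical structure of the problem so
every rule can be validated against a known ground truth.

## The curation model

### Contig filtering

A contig is removed when **any** rule fires (all fired rules are
reported):

| Code | Rule | Default |
|------|------|---------|
| `LEN` | length strictly below `min_len` | 300 bp |
| `GC`  | GC strictly above `max_gc` | 42% |
| `TAX` | taxonomy label missing or not `required_label` | `"Cardinium"` |
| `COV` | mean read depth strictly below `min_cov` | 5× |

The inequalities are strict: a 300-bp, 42.0%-GC, 5.0×-depth contig is
kept. The defaults describe the target organism — *Cardinium* chromosomes
sit near 36% GC while arthropod host sequence is typically above 42%, and
sub-5× contigs are unreliable assembly fragments.

### Coverage uniformity

Manual curation inspects read pileups to distinguish genuinely covered
contigs from contigs whose depth is inflated by a repeat. `symcurate`
replaces the visual check with two window statistics computed on 500-bp
windows (a terminal remainder of at least half a window stands alone;
shorter remainders merge into the previous window):

- **Localization**: the share of total depth mass in the
  `ceiling(top_q * n_windows)` highest-mean windows (`top_q = 0.1`). A
  uniform track gives ≈ `top_q`; a single repeat locus drives it toward 1.
  An all-zero track is defined as 0.
- **Gini coefficient** of window mean depths: 0 exactly when all windows
  are equal.

A contig is *localized* when localization ≥ 0.5 **and** breadth (fraction
of positions with depth ≥ 1) ≤ 0.5: most of the depth in few windows,
most of the contig bare.

### Strain demultiplexing

Two strains are separated using read depth from a **single-infection**
library (containing strain A only) mapped onto the joint assembly:

- mean depth **above** the 60–350× band → strain A (`ABOVE_BAND`);
- **below** the band → strain B (`BELOW_BAND`);
- **inside** the band, the uniformity rule decides: localized coverage
  means the depth comes from a shared repeat that attracted cross-mapping
  reads, so the contig goes to strain B (`BAND_LOCALIZED`); uniform
  coverage goes to strain A (`BAND_UNIFORM`).

The nominal single cutoff (`high_cut = 100`) is retained in
`demux_params()` and validated to sit inside the band, but the band takes
precedence within its range: the band exists precisely because the plain
cutoff misassigns repeat-inflated strain-B contigs whose apparent depth
exceeds it. This is the one place where two plausible readings of the
recipe conflict, and the band-precedence reading is the one that makes
the repeat problem solvable; it is therefore the implemented behavior.

### Plasmid prediction

Contigs of at least 5 kb are scored on three traits, all required:

- **GC**: contig GC at least 3 percentage points below the pooled
  assembly GC. Known *Cardinium* plasmids sit near 31.5% GC against ~36%
  chromosomes (a ~4.5-point gap), so 3 points flags the depression with
  margin.
- **PAR**: at least one partitioning-gene feature (`parA`/`parB`/
  `partition` product keywords) on the contig, and more than one such
  feature assembly-wide (a lone par gene is weak evidence).
- **CONTENT**: no housekeeping features, together with either a
  hypothetical-protein fraction ≥ 0.5 or at least one mobile-element
  feature (transposase/integrase/recombinase/phage).

Because draft assemblies routinely split a plasmid across contigs and no
linkage evidence is available, all flagged contigs are pooled into a
single candidate (summed length, pooled GC).

### Average nucleotide identity

`compute_ani()` implements fragment-based ANI (ANIb convention): the
query is cut into 1020-bp fragments, each fragment is locally aligned to
the reference (match +2, mismatch −3, gap open −5, extend −2, both
strands), and hits with identity ≥ 30% and fragment coverage ≥ 70% are
retained. ANI is the mean identity of retained hits; the aligned fraction
is the share of fragments retained. Identity counts identical columns
over alignment columns.

Alignment placement uses seed-and-extend: exact 15-mers sampled every
25 bp along the fragment are looked up in a precomputed sorted k-mer index
of each reference strand (a rolling base-4 hash; 4^15 ≈ 1.07e9 is exact
in doubles), matching positions are clustered by alignment diagonal
(gap > 50 splits clusters; the 3 best-supported clusters are kept), and
each cluster's window (±200 bp pad) is aligned with Smith–Waterman.
`ani_params(exhaustive = TRUE)` disables seeding and aligns each fragment
against the full reference; the test suite verifies the seeded result
against this oracle. At 15-mer seeds and 25-bp stride, a 1020-bp fragment
carries ~40 seeds, so at 10% divergence (15-mer survival ≈ 0.2) dozens of
seeds survive in expectation and missed fragments are rare.

### Proteome comparison

Protein homology uses local alignment under BLOSUM62 (gap open 11,
extend 1). A target counts as a *full-length* hit when it covers at least
70% of the query with raw score at least 50; a raw-score floor replaces
an e-value because e-value calibration depends on database size, and 50
under BLOSUM62 is comfortably above chance for proteins of these lengths.
Ties break by higher identity, then lexicographic subject id. A protein
is *unique* to a proteome when it is strictly longer than 100 residues
and has no qualifying hit in **any** other proteome. The search is
exhaustive all-pairs — no heuristic prefilter — so results are exactly
reproducible.

## The synthetic community generator

`generate_community()` builds the full curation scenario with ground
truth. Its defaults are the study conditions the pipeline assumes:

| Parameter | Default | Rationale |
|-----------|---------|-----------|
| `strainA_size`, `strainB_size` | 200 kb | scaled from ~1 Mb real genomes for runtime; structure preserved |
| `divergence_AB` | 0.10 | strain B is an iid mutant of A; expected ANI (1−d)·100 = 90 |
| `strainA_mean_depth` | 300× | high-density strain, above the 350-band only jointly with repeats |
| `strainB_mean_depth` | 10× | low-density strain (coinfection library only) |
| `symbiont_gc` / `host_gc` / `plasmid_gc` | 0.36 / 0.45 / 0.315 | chromosome vs host vs plasmid GC contrasts |
| `n_shared_repeats`, `repeat_size` | 5 × 1 kb | identical transposase-like elements copied verbatim into both strains |
| `host_contigs`, `host_contig_size`, `host_mean_depth` | 5 × 10 kb, 50× | our choice — not fixed by the study; 50× is above the 5× floor and below the band's upper edge |
| `mean_contig_bp` | 10 kb | jittered even-grid cutting (±30%), so no chromosome contig trips the length gate |
| `read_len` | 150 bp | depth via uniform read placement (Lander–Waterman) |

What the generator **emulates**: the depth separation between strains,
GC contrasts among chromosome/host/plasmid, identical shared repeats that
attract cross-mapping, a par-gene-bearing low-GC plasmid (optionally
split in two), housekeeping/hypothetical/transposase annotations, and
per-base depth noise from random read placement.

What it **does not** emulate: sequencing error, indels and rearrangements
between strains (divergence is substitution-only), GC-dependent coverage
bias, chimeric contigs and misassemblies, paired-end information, and
probabilistic cross-mapping — in the single-infection depth set, strain-B
repeat intervals receive the constant strain-A mean depth, a
deterministic idealization of reads from identical strain-A repeat
copies, and repeat-free strain-B contigs are exactly 0.

All randomness derives from `sim_params(seed = ...)`; the same seed gives
byte-identical outputs.

## Numerical choices

- GC is computed over unambiguous bases only (A/C/G/T); a sequence with
  none gives `NA`. Assembly GC is pooled over bases, not averaged over
  contigs.
- Window sums use a cumulative-sum scan; the Gini coefficient uses the
  sorted-index identity `G = 2·Σ i·x_(i) / (n·Σx) − (n+1)/n`, exact for
  equal inputs.
- K-mer hashes live in doubles (max 4^15 ≈ 1.07e9 < 2^53), so equality
  comparisons are exact; lookup is binary search over a sorted vector.
- SAM depth counts `M`/`=`/`X`/`D` CIGAR operations as covered
  (deletion-spanned positions count, samtools-style breadth semantics);
  insertions and clips never contribute; only primary, non-duplicate,
  non-supplementary alignments at or above `min_mapq` are counted.
- Reports are written with fixed headers and input-ordered rows, so
  re-running on identical input is byte-identical.

## Limitations

- The demux band (60–350×) and all thresholds are calibrated for the
  high/low-density coinfection regime with a ~30-fold density contrast;
  strains at comparable densities are not separable by depth alone.
- Plasmid prediction is rule-based and annotation-dependent: an
  unannotated assembly cannot satisfy the PAR or CONTENT traits, and a
  plasmid contig shorter than 5 kb is never evaluated.
- ANI seeding can miss fragments beyond ~25% divergence as exact 15-mer
  survival collapses; `exhaustive = TRUE` is the fallback at a large
  runtime cost.
- The raw-score floor of the proteome search is a fixed substitute for
  e-values; it is appropriate for the few-thousand-protein comparisons it
  was designed for, not for large-database searches.
- The generator validates recovery of its own idealized structure; real
  assemblies add error modes (chimeras, uneven coverage, diverged
  repeats) the simulation does not contain.
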