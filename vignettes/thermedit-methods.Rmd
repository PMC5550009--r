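---
title: "Detecting and quantifying A-to-I hyper-editing with thermedit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and quantifying A-to-I hyper-editing with thermedit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermedit)
library(dplyr)
```

## The problem

ADAR enzymes deaminate adenosine to inosine in double-stranded RNA, and
sequencers read inosine as guanosine, so A-to-I editing appears as A→G
mismatches between RNA-seq reads and the genome. ADAR tends to edit its
substrates at many nearby positions at once. The resulting *hyper-edited*
reads carry so many mismatches that ordinary aligners reject them, which is
precisely why hyper-edited regions are invisible to naive mismatch calling.
In poikilotherms such as *Drosophila*, editing activity and specificity
shift with ambient temperature, so a temperature-resolved analysis needs to
recover hyper-edited reads, quantify per-site editing levels, compare
conditions statistically, and characterise the structural context (the
dsRNA stems ADAR requires) of the edited sites. `thermedit` implements that
pipeline end to end, together with a synthetic-data generator that plants
known truth so every stage is testable without external sequencing data.

## Detection by transformed realignment

Reads that fail normal alignment within a mismatch budget form the
*unaligned pool*. For the editing mismatch type A→G the detector:

1. replaces every A with G in both the pooled reads and the reference, and
   realigns; a read that was unalignable because of dense A→G mismatches
   becomes a clean match in the collapsed alphabet;
2. requires a *unique* best transformed placement (ties are dropped and
   counted);
3. restores the original sequences and collects mismatches of the target
   type with base quality ≥ `quality_min`;
4. discards mismatches within `end_exclusion` bases of either read end,
   then keeps the read's mismatch run as a cluster only if at least
   `min_edits` mismatches remain and the genomic span from the first to the
   last mismatch (inclusive) covers at least 10% of the read length.

A strand-specific library implies that a read aligning to the plus strand
with A→G mismatches reports editing on the plus strand, while a read whose
plus-strand representation shows T→C mismatches reports A→G editing on the
minus strand; the detector runs both transformations and assigns site
strand accordingly. All 12 ordered mismatch types are run for QC
(`qc_mismatch_spectrum()`): in clean data A→G dominates the spectrum and
its sites split about 50/50 between strands, while artefact types
concentrate on one strand or at particular read positions.

Read-level clusters on the same contig and strand are merged into genomic
*regions* whenever they overlap or are separated by at most `max_gap = 20`
bases (gap counted as `next start − previous end − 1`, so a gap of exactly
20 merges and 21 does not). A region spans from the first base of its
upstream cluster to the last base of its downstream cluster.

### Parameter defaults and why

| parameter | default | meaning |
|---|---|---|
| `quality_min` | 30 (Phred) | minimum base quality of a counted mismatch; standard editing-pipeline practice |
| `min_edits` | 4 | minimum A→G mismatches per read cluster; "dense" clusters while keeping single reads informative |
| `end_exclusion` | 6 bases | read-end zone whose mismatches are ignored, harmonised with the quantification trim |
| `max_gap` | 20 bases | cluster-merge distance |
| `max_mm_per_100` | 4 | aligner mismatch budget per 100 read bases; reads beyond it feed the pool |

The end-exclusion rule is implemented by *excluding* the offending
mismatches and then applying the cluster rules to the remainder, rather
than by discarding any cluster that touches the zone; this keeps the
cluster invariant ("no counted mismatch near a read end") true by
construction and treats read ends consistently with the pileup trim. The
10% span rule uses the full read length, and the span is counted
inclusively (`last − first + 1`).

## Quantification

`pileup_sites()` counts, per site and sample, reads supporting the
reference A versus the edited G, oriented to the site strand (a
minus-strand site counts plus-reference T as A-support and C as
G-support). Bases within `trim = 6` bases of either read end or below
`quality_min` are ignored; bases that are neither A nor G are tallied
separately as `other` and never enter the editing level. The editing level
is `G / (A + G)`; the *editing index* of a site set is the pooled
`ΣG / Σ(A + G)` — the fraction of inosines among all expressed adenosines,
identically the coverage-weighted mean of the per-site levels (an identity
the tests assert). Pileups include both ordinary unique alignments and the
uniquely realigned hyper-edited reads; leaving the latter out would bias
editing levels downwards at exactly the most heavily edited sites, because
their reads are the ones ordinary alignment rejects.

Supported sites require at least 2 G-reads at a level of at least 1% in
some sample. Genomic-location annotation assigns exactly one category per
site with precedence CDS > 5'UTR/3'UTR > noncoding exon > intron >
intergenic, first transcript winning ties.

## Differential editing

Each site and condition pair forms a 2×2 table of G/A counts, tested with
the uncorrected Pearson chi-square (df = 1; equal to the squared
two-proportion z statistic). P-values are Benjamini–Hochberg adjusted
within the pair, and a site is called significant only when additionally
both conditions have coverage ≥ 50 and the absolute editing-level
difference exceeds 0.20. Pairwise testing (rather than an omnibus test
across three or more conditions) is used because the question asked of
every site is directional — *between which temperatures does editing
change* — and the coverage filter keeps expected counts large enough that
no continuity correction is warranted.

The gene-set bootstrap asks whether a target gene set is more edited than
expectation: the observed statistic is the pooled editing index of the
target genes, the null resamples `B` equally sized gene sets without
replacement from a control pool (by default the most-expressed 60% of
genes), and the one-sided add-one p-value is
`(1 + #{null ≥ observed}) / (B + 1)`, which is never zero and is uniform
under the null — a property the acceptance tests check by
Kolmogorov–Smirnov against 200 replicate p-values.

## Structure and conservation context

For each site (or region midpoint) a 40-nt window oriented to the site
strand is extracted, the site at position 20 (left of centre for even
widths). The window is aligned against the sequence within 2 kb on either
side, window excluded: in *antisense* mode against the reverse complement
of the same-strand flank — a hit means the flank can base-pair with the
edited region into a dsRNA stem — and in *sense* mode against the flank
as-is, the random-expectation control. The *edited* modes first substitute
G at every known edited position in the window (the sequencer-visible form
of inosine) and repeat the search; substitutions can only lower identity
against the unedited partner, which the tests assert.

The aligner is blastn-flavoured: 7-mer exact seeds, local extension with
match +2, mismatch −3, and affine gaps costing 2 to open plus 2 per gap
column. Each seed is extended by an exact Smith–Waterman (Gotoh) pass on a
padded segment around the seed diagonal; the pad (2× window + 10) exceeds
the furthest a profitable local alignment of a 40-nt window can wander, so
whenever a 7-nt exact seed lies on the optimal path the seeded score equals
the full Smith–Waterman score — an equivalence the test suite verifies
against an independent cell-by-cell DP oracle. In place of an E-value
cut-off a raw score floor of 14 (seven matched bases) is applied; at these
lengths anything weaker is far below the match thresholds anyway. A window
*matches* when the best local alignment reaches ≥ 70% identity (matches
over alignment columns) across ≥ 70% window coverage (aligned window
columns, gaps in the window excluded). Coverage is measured against the
40-nt window rather than the merged region length: it makes the flag
independent of how many clusters merged, and both quantities are derivable
from the reported alignment bounds.

`conservation_profile()` averages a per-base score track at offsets ±20
around sites (offsets follow the site strand), stratified into sites
supported by more than one event, single-event sites, and a seeded random
sample of reference adenosines of matched size as background.
`evofold_overlap()` reports the percentage of sites inside conserved-fold
intervals, rounded to two decimals.

## The synthetic-data generator

The generator encodes exactly the statistical structure the analysis
assumes, nothing more:

* a uniform-composition random genome (default contig `chrS1`) with genes
  tiled over `genic_fraction` of it, each with exons, introns and terminal
  UTRs;
* `n_clusters` editing clusters placed inside gene bodies, non-overlapping
  and separated by more than a read length; cluster strands are drawn
  exactly balanced and each cluster is hosted by a gene of its strand, so
  transcript strand and site strand agree and the QC strand split
  concentrates tightly around 50/50;
* per cluster, 6–10 sites spread over `cluster_span` (default 40 bases,
  ≥ 10% of the read length by construction) with a minimum spacing of 3 so
  sequence contexts never overlap; the planted bases are written into the
  genome, making every truth site a reference adenosine on its strand by
  construction;
* an ADAR-like context written around each site: G at −1 with probability
  0.05 (depletion) and at +1 with probability 0.35 (enrichment), other
  bases uniform;
* for `ir_fraction` of clusters, the reverse complement of the 40-nt
  cluster core copied to within 2 kb — a perfect inverted repeat;
* strand-balanced reads at `coverage`× depth; reads overlapping a cluster
  carry the cluster (transcript) strand, emulating a strand-specific
  library; each overlapped site is converted A→G on its strand with its
  per-condition rate; uniform sequencing errors (default 0.1% per base) are
  applied afterwards; qualities are constant Phred 40 — the error process
  is explicit rather than quality-driven;
* one master seed drives everything through per-stage sub-streams
  (`derive_seeds()`), so a fixed configuration is byte-reproducible.

Temperature regimes are expressed through the per-condition rates: a cold,
high-specificity regime is "fewer clusters, higher per-site rate" (e.g.
0.6–0.8) and a warm, promiscuous regime "more clusters, lower rate" (e.g.
0.2). Paired-end layout, GC bias, fragmentation models, splice-aware reads
and quality-driven errors are deliberately not modelled; passing tests
therefore demonstrate correctness of the *method* under its own
assumptions, not performance on real libraries, where alignment artefacts,
SNPs and coverage biases add failure modes the generator does not emulate.

## Problem sizes and numerical choices

The packaged tests exercise recovery on a 1 Mb genome with 200 planted
clusters (8 sites each) at 30× coverage and an 0.8 per-site rate — about
300,000 reads — where site-level sensitivity and precision against planted
truth reach ≥ 0.90 and ≥ 0.95; the 12-type QC spectrum runs on a 300 kb
study with 800 planted sites; index recovery uses ~5,000 aggregated reads
at a planted rate of 0.30 (recovered within ±0.02); differential
calibration uses 1,000 null sites at coverage 100 and power 200 sites at a
planted difference of 0.30. These sizes were chosen as the smallest at
which the binomial error bands in the checks are decisively narrower than
the effects being verified.

Other numerical choices: ungapped read alignment (indels are out of scope,
as is splice-aware placement); alignment uniqueness means strictly fewer
mismatches than the second-best placement; internal coordinates are
1-based closed throughout (the Bioconductor convention), converted to
0-based half-open only in the BED reader/writer, so there is a single
conversion point; ties in the structure aligner's traceback resolve
diagonal-first, which does not affect scores; degenerate inputs (empty
pools, empty cluster sets, zero-coverage sites, zero denominators) return
typed empty results or `NA` with the condition recorded rather than
errors, except where the contract is a hard precondition (unknown
condition labels, out-of-range genome queries, a control pool smaller than
the target set).

## Running the pipeline

```{r, eval = FALSE}
cfg <- sim_config(genome_length = 1e5, n_clusters = 20,
                  per_site_edit_rate = c(T18 = 0.6, T29 = 0.2), seed = 1)
res <- simulate_and_run(cfg)
res$evaluation                       # sensitivity / precision / index per condition
res$report$editing_index             # pooled index per condition
plot_motif(res$report$motif)
autoplot(res$report$differential)
```

`run_pipeline()` drives the same stages from files (FASTA, GTF, FASTQ,
optional site lists, conservation track and fold intervals) configured via
`run_config()` or a YAML file, writes every stage table as TSV plus the
verbatim config and a manifest (package version, seed, parameter hash),
and returns the report bundle; `simulate_and_run()` wraps it with the
generator and joins calls against planted truth at exact coordinates.

## Known limitations

* The embedded aligner is exact/near-exact and ungapped; it is a desk-scale
  stand-in for a production aligner and intentionally implements only the
  behavioural contract downstream stages consume (unique placement, an
  unaligned pool under a mismatch budget).
* Detection sensitivity at low per-site rates is intrinsically limited:
  a read must carry `min_edits` edits to witness a cluster, so sparse
  editing is better captured by the pileup stage over a known site list
  than by de-novo hyper-editing calls — the same asymmetry a warm,
  promiscuous editing regime produces in real data.
* The bootstrap conditions on the gene-to-site assignment produced by the
  annotation stage; genes without assigned sites never enter the pool.
* Conservation tracks are joined per base in memory; genome-scale tracks
  should be windowed before loading.
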