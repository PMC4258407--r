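---
title: "Methods: presence/absence inference for duplicated paralog loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: presence/absence inference for duplicated paralog loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paralocus)
```

## The analysis problem

A tandemly duplicated immune locus — the motivating case is the cattle
killer-cell immunoglobulin-like receptor (KIR) complex — consists of a few
large genomic blocks that arose by segmental duplication, each carrying
several paralogous genes whose sequences are often more than 90% identical
within a "group". Given short reads from a sample (possibly ancient DNA at
modest depth with sub-percent error), the question is which members of the
family the sample's genome actually carries. Because reads are shorter than
the distance between paralog-distinguishing positions, most of them align
equally well to several genes; naive coverage is therefore uninformative,
and the analysis has to be built on *unique mappability* and on
*gene-defining SNPs*.

`paralocus` implements that analysis as a reusable, tested pipeline, plus a
synthetic-locus generator that provides ground truth for every stage. All
coordinates are 0-based and half-open internally; human-readable reports
(variant TSVs) are 1-based.

## The synthetic locus generator

The generator is first-class, tested code: its output defines the
conditions under which the pipeline's guarantees are demonstrated.

* `generate_block()` draws a uniform random sequence and places
  non-overlapping gene models on it, one per paralog-group label. Each gene
  has 4–9 exons of 36–300 bp separated by 50–150 bp introns, and its
  spliced, strand-aware CDS is written as an intact open reading frame
  (ATG … stop), so `orf_integrity()` classifies generated genes as
  functional by construction. These layout constants are topology choices —
  only the existence of multi-exon, strand-mixed, ORF-bearing genes matters
  for the tests, not their exact sizes.
* `build_haplotype()` concatenates `n_copies` independently point-mutated
  copies of the block. Each copy receives `Binomial(L, divergence)`
  substitutions drawn uniformly over the three alternative bases; two
  copies mutated at rate *d* therefore differ at about *2d* of sites.
  Substitutions only — the quantities this package counts (SNPs,
  substitutions, p-distances) are defined on co-linear sequences, and
  keeping the generator indel-free keeps every comparison alignment-free.
* `inject_allelic_snps()` derives an allelic haplotype at an *exact*
  Hamming distance, emulating an allele pair that differs by a stated SNP
  count (the motivating locus pair differs by 1008 SNPs over its shared
  region; the acceptance run uses 500 over 40 kb, a comparable density).
* `delete_gene()` removes a gene's genomic span and shifts all downstream
  coordinates — the ground truth for absence calls.
* `tile_reads()` emits every 35-bp window from both strands at constant
  phred 30: the positive-control read set. Away from the reference ends its
  per-position depth is exactly 2 × 35.
* `sample_ancient_reads()` draws single-end reads uniformly over positions
  and strands. Lengths come from 36–70 bp with 70% of draws restricted to
  the modal 40–60 bp range, matching the read-length profile of the
  motivating ancient libraries (runs of 36/42/70 bp reads over ~40–60 bp
  inserts). Each base is substituted with probability `ancient_error_rate`
  (default 0.5%). Post-mortem C→T deamination is deliberately *not*
  modelled: the downstream method uses no damage model, so a uniform,
  configurable error rate is the right stand-in, and the true single-end
  error profile of such libraries is unknown — it is a parameter, not a
  guess.

What the generator does **not** emulate: indel variation, paired-end
insert-size structure, quality-score covariation with error, GC or damage
bias in coverage, and repeat families other than the block duplication
itself. Passing tests therefore demonstrate correctness of the algorithms
under substitution-only divergence with uniform coverage; on real data the
unique-coverage branch additionally faces coverage bias, which the decision
thresholds absorb but the tests do not exercise.

## The mapper

The mapper is an exact, ungapped, end-to-end aligner: for each read it
reports *every* placement on either strand with at most `max_mismatches`
(default 2) mismatches, sorted by (mismatches, reference id, position,
strand) and truncated at `max_hits_reported` with a flag. Uniqueness is
defined by best-score tie counting — `unique` iff exactly one placement
attains the read's minimum mismatch count — computed before truncation.
This is the deterministic analogue of an aligner's unique-mapping tag (the
SAM writer emits it as `XT:A:U`/`XT:A:R`), chosen over mapping-quality
thresholds because it is exactly reproducible and oracle-testable.

Candidate placements come from an exact k-mer index (default seed k = 13,
N never seeded) seeded at **every** read offset. With every-offset seeding,
a read of length *L* carrying at most *m* mismatches always contains a
clean k-window when *L* ≥ (m+1)k + m; at the defaults that bound is 41 bp,
which 35-bp tiles do not meet. The mapper therefore lowers the *effective*
seed to `floor((Lmin − m)/(m+1))` (clamped to ≥ 8) for short read sets, and
falls back to an exhaustive early-exit scan (in the same compiled code) for
any read still below the guarantee or containing N. The result is that
`map_reads()` hit sets provably equal a brute-force scan for every input —
the property the test suite asserts against an independent R oracle on
hundreds of random references.

Ungapped only: at 35–70 bp and substitution-level questions, indel-bearing
reads simply fail to map, which keeps the uniqueness definition exact. This
is a documented limitation, consistent with the generator producing no
indels.

## Coverage, pileup, consensus, variants

`depth_profile()` counts each read once at its best placement: multi-reads
at all tied best placements in the "normal/total" track (policy
`all_best`), and never in the unique track. `gene_coverage_pct()` is the
percentage of a gene's genomic span (first exon start to last exon end;
introns included, exon-only by flag — reports include the span because the
per-gene coverage of interest is length-based, but both modes are exposed
since the convention is not fixed) with selected depth ≥ `min_depth`.
Sample data use `min_depth = 1`. The deep-control convention of counting
only positions with depth > 1000 applies to replicated control sets; a
single both-strand tiling pass cannot exceed depth 2L = 70, so the
pipeline's control uses `min_depth = 1` and `control_min_depth` remains
available for users with deep controls.

`pileup()` excludes multi-mapping reads by default — including them lets
paralog cross-talk inflate variant frequencies — with `all_best` available
for the normal-coverage view. `call_snps()` applies the published cutoffs
verbatim and literally: a variant needs depth **strictly greater than** 5
and a maximal non-reference base at frequency **≥ 0.5001**; a site with two
alternatives tied at the maximum is not called. `cross_source_filter()`
masks positions where two alignments of the same reference disagree on the
majority base while the conflicting source is weakly covered (depth < 8 for
source A, < 500 for source B — the 454/Illumina convention).
`majority_consensus()` writes the base reaching 51% of the column depth;
sites where no base reaches 51% (including exact 50/50 ties and zero-depth
positions) fall back to the tie policy, which defaults to the reference
base precisely so that the output never needs an ambiguity code. The
original analysis did not state how exact ties were resolved; here the
policy is explicit, logged, and switchable to `first-alphabetical`.
Consensus of error-free tiles reproduces any input haplotype byte-exactly
and is idempotent — both are asserted.

`annotate_effects()` substitutes each called variant alone into its codon
of the spliced, strand-aware CDS under the standard genetic code
(synonymous / nonsynonymous / nonsense; positions outside exons are
intergenic/intronic; genes whose spliced CDS is not a multiple of three get
a warning and no effects).

## Presence/absence inference

The original analysis is qualitative; this package turns it into an
explicit decision rule with all constants exposed in
`presence_thresholds()` and logged in each call's rationale.

**Evidence 1 — unique coverage vs control.** The tiling control measures,
per gene, the unique coverage the locus structure permits. The sample's
unique coverage is compared to it: `present` when it reaches `cov_frac`
(default 0.5) of the control.

**Evidence 2 — gene-defining SNPs.** Sample reads hitting exactly one
paralog group are assigned to their best-matching group member
(within-group ties dropped, mirroring best-hit alignment); each member gets
a pileup in its own coordinates. A column *defines* a gene when the gene's
base set (the union over its alleles from both haplotypes, where a second
haplotype is supplied) is disjoint from every other member's bases —
columns that merely vary somewhere in the group carry no gene-specific
evidence, and counting them would make a deleted gene look present through
its paralog's reads. Each defining column is `consistent` (majority sample
base in the gene's allele set), `inconsistent`, or `uncovered`
(depth < `min_depth`, default 3); the three always partition the defining
set. The SNP branch calls `present` at ≥ `min_consistent` (default 2)
consistent sites with an inconsistent fraction ≤ `max_inconsistent_frac`
(default 0.2).

**Synthesis.** `present` if either branch fires (the SNP branch may fire
even when the control coverage is below `control_floor` = 1%, the fully
duplicated case where coverage is uninformative). `absent` requires three
things: the control predicts coverage but the sample shows less than
`absent_cov_frac` (default 0.25) of it; no consistent defining SNP; and
locus-wide adequate depth (at least half the reference covered by the
sample's normal track), so a merely shallow sample yields `indeterminate`,
never `absent`. Everything else is `indeterminate`.

Two of these constants deserve their provenance stated. `absent_cov_frac`
is half the presence bound: a present gene's reads tile essentially its
whole unique span (ratio ≈ 1), while the stray unique coverage a deleted
gene accrues — allelic SNPs of the surviving paralog occasionally
converging toward the deleted copy's sequence — stays near 0.1 under the
study conditions, so 0.25 separates the regimes with margin on both sides.
The adequacy guard is deliberately locus-wide rather than per-gene, because
a whole-family deletion legitimately empties its own span while the rest of
the locus stays covered. The full decision rule is exercised by a
ground-truth-recovery property over 20 random loci (2–3 blocks, 4–9 genes,
0–2 deletions, depth 15, error ≤ 1%) in the test suite.

## Locus diversity analytics

`dotplot_identity()` computes ungapped percent identity between all window
pairs (default 250 bp, step = window; step is free but quadratic in cost).
`window_identity_track()` slides a 500-bp window at step 1 along co-linear
blocks; positions where exactly one sequence has a gap score as mismatch,
so structural divergence appears as dips (columns where both have a gap
compare equal). `count_substitutions()` counts differing non-gap positions,
optionally within interval masks such as `exon_mask()`, tallying gap sites
separately. `ns_s_counts()` classifies each differing site by substituting
it alone into the first sequence's codon; sites in codons with more than
one difference are reported in a separate `multi_hit` column rather than
as NS or S, so `ns + s + multi_hit` always equals the number of differing
sites. `p_distance_matrix()` uses pairwise deletion of gap/N columns; it is
symmetric with zero diagonal, and deliberately no triangle-inequality claim
is made (p-distance is not a metric). The test suite cross-checks it
against an independent implementation (`ape::dist.dna`, model `"raw"`).

Motif analytics are pattern-based: `scan_itims()` reports every overlapping
V-x-Y-x-x-L (canonical ITIM) and V-x-F-x-x-L (the tyrosine-to-phenylalanine
disruption that attenuates inhibitory signalling); distinguishing
membrane-proximal from membrane-distal ITIMs requires the transmembrane
boundary from annotation and is left to the caller.
`classify_tm_adaptor()` applies the charged-residue rule — arginine in the
membrane-proximal flank implies Fcγ/CD3ζ-type adaptor pairing, lysine
within the transmembrane segment implies DAP10/DAP12-type — and reports
both with a warning if both are present. `orf_integrity()` classifies a
gene as functional iff its spliced CDS starts with ATG, ends with a stop,
has no internal stop, and has length divisible by three, locating every
defect otherwise (`lost_start`, `premature_stop`, `lost_stop`,
`frameshift`). Standard genetic code only.

All pairwise comparisons assume pre-aligned (or generator-co-linear) input;
multiple alignment itself is out of scope, and externally aligned input is
accepted as-is. `validate_haplotype_pair()` packages the headline
divergence quantities for an allele pair on shared coordinates — total SNP
count, per-block substitution and exon-SNP counts, functional-gene counts —
for validation against finished assemblies supplied as FASTA + BED.

## Problem sizes and determinism

The test suite and the acceptance script run the full pipeline on 40-kb
two-block loci (8 genes, 4 groups, ~2% pairwise inter-block divergence,
500-SNP allele pairs, depth-20 samples at 0.5% error, five seeds), the
ground-truth property on twenty 10–22-kb loci at depth 15, and the mapper
oracle on hundreds of references up to 5 kb — sizes at which every check
(including the brute-force oracles) completes in a couple of minutes on one
CPU while still exercising the duplication structure that makes the problem
hard. Every stochastic step takes an explicit integer seed; identical seeds
give byte-identical haplotypes, read sets, and results.

## Known limitations

* No indel calling or gapped alignment; indel-bearing reads drop out.
* No genotype likelihoods or base-quality-aware weighting — cutoffs are the
  published frequency/depth rules applied to raw counts.
* No copy-number estimation beyond presence/absence, and no detection of
  genes absent from the reference (the unmapped-read fraction is reported,
  nothing more).
* No damage-aware or GC-aware coverage normalisation.
* Presence thresholds were calibrated on the synthetic suite; real data
  with strong coverage bias may need `presence_thresholds()` adjusted, and
  every call carries its rationale to make that auditable.
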