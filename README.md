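# paralocus

Presence/absence inference and diversity analytics for tandemly duplicated
paralog loci from short (including ancient) sequencing reads.

## The problem

Immune-gene complexes such as the killer-cell immunoglobulin-like receptor
(KIR) locus of cattle consist of duplicated genomic blocks (~66 kb each)
carrying families of paralogous genes that are often more than 90%
identical. Deciding which members of such a family are present in a
short-read sample — for example an ancient genome sequenced at modest depth
from 36–70 bp fragments — is hard precisely because most reads map equally
well to several paralogs. `paralocus` implements the two complementary
lines of evidence used for this problem, wrapped in a fully synthetic test
harness so every stage is verifiable without external data:

1. **Unique-coverage comparison.** Reads are aligned ungapped to the
   reference haplotype reporting *all* best placements; a read is *unique*
   when exactly one placement attains its minimum mismatch count. Per-gene
   percent coverage by uniquely mapping reads is compared against a
   simulated positive control — error-free 35-bp tiles from both strands of
   the reference at phred 30 — which measures how much unique coverage the
   locus structure itself permits. A present gene tracks its control; a
   deleted gene collapses toward zero even though its paralog keeps the
   "normal" (multi-mapping) coverage high.
2. **Diagnostic-SNP consistency.** Reads that map exclusively to one
   paralog group are assigned to their best-matching group member, and the
   alignment columns whose base is unique to one gene (including allelic
   variants from a second haplotype where available) are scored as
   consistent / inconsistent / uncovered. Coverage is always accounted for,
   so missing data are never mistaken for a missing gene.

Around this core the package provides the standard machinery of such an
analysis as tidy, pipe-friendly functions: a synthetic-locus generator
(block duplication, allelic SNP injection, gene deletion, tiling and
ancient-DNA-like read simulation), a k-mer seed-and-verify read mapper with
an exhaustive-scan fallback that makes its hit sets provably equal to brute
force, depth profiles and sliding-window coverage tracks, pileups,
majority-rule consensus (51% rule, no ambiguity codes), variant calling at
the ≥ 50.01% frequency / > 5× coverage cutoffs with cross-source conflict
masking (< 8× / < 500×), dot-plot and sliding-window identity, substitution
and NS/S counting, p-distance matrices, ITIM motif scanning (V-x-Y-x-x-L
and its Y→F-disrupted form), transmembrane adaptor classification
(membrane-proximal arginine → Fcγ/CD3ζ type; transmembrane lysine →
DAP10/DAP12 type), and open-reading-frame integrity classification.

## Worked example

Simulate a two-block locus with eight genes in four paralog groups
(~2% pairwise inter-block divergence), derive an allelic haplotype 500 SNPs
away, delete one gene, sequence it ancient-DNA-style, and ask which genes
are present:

```r
library(paralocus)

blk <- generate_block(length = 20000, n_genes = 4,
                      group_labels = paste0("g", 1:4), seed = 1)
h1  <- build_haplotype(blk, n_copies = 2, divergence = 0.01, seed = 2)
h2  <- inject_allelic_snps(h1, n_snps = 500, seed = 3)
h1
#> <haplotype> H1: 40000 bp, 2 block(s), 8 gene(s)

sample <- delete_gene(h1, "gene02_A")
reads <- sample_ancient_reads(sample, sim_params(
  n_ancient_reads = n_reads_for_depth(nchar(sample$sequence), depth = 20),
  ancient_error_rate = 0.005, seed = 4))

run <- infer_presence(h1, reads, allelic = h2)
run
#> <presence_run> 8 gene(s): 7 present, 1 absent, 0 indeterminate
#>   reads: 15359 (99.7% mapped, 35.4% of mapped multi-mapping)
#> # A tibble: 8 × 6
#>   gene_id  status  unique_cov_pct control_cov_pct n_diag n_cons
#>   <chr>    <chr>            <dbl>           <dbl>  <int>  <int>
#> 1 gene01_A present         97.8              83.4     36     36
#> 2 gene02_A absent           0.374            78.6     28      0
#> 3 gene03_A present         95.9              84.7     35     35
#> 4 gene04_A present         92.6              75.6     34     34
#> 5 gene01_B present         94.2              83.4     36     36
#> 6 gene02_B present         92.6              78.6     28     28
#> 7 gene03_B present         96.7              84.7     35     35
#> 8 gene04_B present         95.0              75.6     34     34
```

Reading the table: `control_cov_pct` is the unique coverage the tiling
control achieves for each gene — below 100% because the duplicated blocks
erase unique mappability for part of every gene span. The deleted
`gene02_A` keeps essentially no unique coverage (0.4%) although its intact
paralog `gene02_B` does, and none of its 28 gene-defining SNPs is
confirmed, so it is called absent; every other gene is supported by both
branches. `tidy(run)` returns the full call table (including the per-call
rationale), `glance(run)` a one-row summary, and `autoplot(run)` /
`autoplot(run$sample_profile)` the coverage figures.

A thin command-line front end over the same functions lives at
`inst/cli/paralocus.R` (subcommands `simulate`, `map`, `presence`,
`locus-stats`).

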