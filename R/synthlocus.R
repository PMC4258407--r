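# synthetic locus generator: ground-truth haplotypes with block-duplication
# structure, allelic variants, gene deletions, and simulated read sets

STOP_CODONS <- c("TAA", "TAG", "TGA")

all_codons <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(b3 = b, b2 = b, b1 = b, stringsAsFactors = FALSE)
  paste0(g$b1, g$b2, g$b3)
}

NON_STOP_CODONS <- setdiff(all_codons(), STOP_CODONS)

# random open reading frame of `len` nt (len %% 3 == 0, len >= 9):
# ATG, then non-stop codons, then a stop codon
random_orf <- function(len) {
  stopifnot(len %% 3 == 0, len >= 9)
  n_mid <- len / 3 - 2
  paste0("ATG", paste(sample(NON_STOP_CODONS, n_mid, replace = TRUE),
                      collapse = ""),
         sample(STOP_CODONS, 1))
}

#' Construct a haplotype object
#'
#' A haplotype bundles a locus sequence with its duplication-block intervals
#' and gene models. Coordinates are 0-based, half-open throughout.
#'
#' @param hap_id Label for the haplotype.
#' @param sequence Nucleotide string over `{A,C,G,T}` (optionally `N`).
#' @param blocks Tibble with columns `block_id`, `start`, `end`.
#' @param genes Tibble with columns `gene_id`, `group`, `strand`, `status`
#'   and list-columns `exon_start`, `exon_end` (parallel integer vectors,
#'   sorted, non-overlapping).
#' @return An object of class `haplotype`.
#' @export
haplotype <- function(hap_id, sequence, blocks, genes) {
  h <- structure(list(hap_id = hap_id, sequence = toupper(sequence),
                      blocks = as_tibble(blocks), genes = as_tibble(genes)),
                 class = "haplotype")
  validate_haplotype(h)
  h
}

#' Validate haplotype invariants
#'
#' Checks sequence alphabet and length, block bounds, and that every gene
#' has at least one sorted, non-overlapping exon inside the sequence.
#'
#' @param h A [haplotype()] object.
#' @return `h`, invisibly; aborts on violation.
#' @export
validate_haplotype <- function(h) {
  n <- nchar(h$sequence)
  if (n == 0) abort("haplotype sequence must be non-empty")
  if (grepl("[^ACGTN]", h$sequence)) abort("sequence has non-ACGTN characters")
  if (nrow(h$blocks) > 0 &&
      any(h$blocks$start < 0 | h$blocks$end > n | h$blocks$start >= h$blocks$end)) {
    abort("block intervals must lie within the sequence")
  }
  for (i in seq_len(nrow(h$genes))) {
    es <- h$genes$exon_start[[i]]
    ee <- h$genes$exon_end[[i]]
    gid <- h$genes$gene_id[i]
    if (length(es) < 1 || length(es) != length(ee)) {
      abort(sprintf("gene %s: needs at least one exon interval", gid))
    }
    if (any(ee <= es)) abort(sprintf("gene %s: empty exon interval", gid))
    if (any(es < 0) || any(ee > n)) {
      abort(sprintf("gene %s: exon outside sequence", gid))
    }
    if (length(es) > 1 && any(es[-1] < ee[-length(ee)])) {
      abort(sprintf("gene %s: exons overlap or are unsorted", gid))
    }
  }
  invisible(h)
}

#' @export
print.haplotype <- function(x, ...) {
  cat(sprintf("<haplotype> %s: %d bp, %d block(s), %d gene(s)\n",
              x$hap_id, nchar(x$sequence), nrow(x$blocks), nrow(x$genes)))
  invisible(x)
}

#' Generate an ancestral locus block
#'
#' Builds a random sequence carrying `n_genes` non-overlapping multi-exon
#' gene models, one per group label (cycled). Each gene is written with an
#' intact open reading frame across its spliced exons (4-9 exons of
#' 36-300 bp separated by short introns), so the generated annotation is
#' functional by construction. Deterministic for a fixed seed.
#'
#' @param length Block length in bp; must be at least `n_genes * 2000`.
#' @param n_genes Number of genes to place.
#' @param group_labels Non-empty character vector of paralog-group labels,
#'   recycled across genes.
#' @param seed Integer seed.
#' @return A list with elements `sequence` (character) and `genes` (tibble
#'   of gene models in block coordinates).
#' @export
generate_block <- function(length, n_genes, group_labels, seed = 1L) {
  if (length(group_labels) < 1) abort("`group_labels` must be non-empty")
  check_scalar_number(n_genes, "n_genes", lower = 1)
  if (length < n_genes * 2000) {
    abort(sprintf("block length %d too small for %d genes (need >= %d)",
                  length, n_genes, n_genes * 2000))
  }
  withr::with_seed(seed, {
    chars <- sample(DNA_BASES, length, replace = TRUE)
    slot <- floor(length / n_genes)
    genes <- vector("list", n_genes)
    for (i in seq_len(n_genes)) {
      slot_start <- (i - 1L) * slot
      avail <- slot - 200L
      n_exons <- sample(4:9, 1)
      repeat {
        introns <- sample(50:150, n_exons - 1, replace = TRUE)
        per_exon_max <- min(300L, floor((avail - sum(introns)) / n_exons))
        if (per_exon_max >= 36L) break
        n_exons <- n_exons - 1L
        if (n_exons < 2L) abort("cannot lay out gene in slot")
      }
      exon_len <- sample(36:per_exon_max, n_exons, replace = TRUE)
      rem <- sum(exon_len) %% 3L
      if (rem > 0) {
        exon_len[n_exons] <- exon_len[n_exons] - rem
        if (exon_len[n_exons] < 36L) exon_len[n_exons] <- exon_len[n_exons] + 3L
      }
      span <- sum(exon_len) + sum(introns)
      gene_start <- slot_start + 100L + sample.int(avail - span + 1L, 1) - 1L
      starts <- integer(n_exons)
      pos <- gene_start
      for (e in seq_len(n_exons)) {
        starts[e] <- pos
        pos <- pos + exon_len[e] + if (e < n_exons) introns[e] else 0L
      }
      ends <- starts + exon_len
      strand <- sample(c("+", "-"), 1)
      orf <- random_orf(sum(exon_len))
      payload <- if (strand == "+") orf else revcomp(orf)
      idx <- unlist(mapply(seq, starts + 1L, ends, SIMPLIFY = FALSE))
      chars[idx] <- strsplit(payload, "")[[1]]
      genes[[i]] <- tibble(
        gene_id = sprintf("gene%02d", i),
        group = group_labels[((i - 1L) %% length(group_labels)) + 1L],
        strand = strand, status = "functional",
        exon_start = list(as.integer(starts)), exon_end = list(as.integer(ends)))
    }
    list(sequence = paste(chars, collapse = ""), genes = bind_rows(genes))
  })
}

# apply `n_sub` random substitutions to a sequence, uniform over the three
# alternative bases; returns the mutated character string
mutate_sequence <- function(sequence, n_sub) {
  if (n_sub == 0) return(sequence)
  chars <- strsplit(sequence, "")[[1]]
  pos <- sample.int(length(chars), n_sub)
  for (p in pos) {
    chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1)
  }
  paste(chars, collapse = "")
}

#' Build a haplotype from duplicated copies of an ancestral block
#'
#' Concatenates `n_copies` independently point-mutated copies of a block,
#' emulating a locus that arose by tandem duplication of an ancestral
#' segment. Each copy receives `Binomial(length, divergence)` substitutions
#' (no indels), gene models are carried over with per-copy suffixes, and
#' block intervals are recorded.
#'
#' @param block A `(sequence, genes)` list from [generate_block()].
#' @param n_copies Number of block copies (>= 1).
#' @param divergence Per-copy substitution rate per site, in `[0, 0.2]`.
#'   Two copies mutated at rate `d` differ pairwise at about `2 d` of sites.
#' @param seed Integer seed.
#' @param hap_id Label for the resulting haplotype.
#' @return A [haplotype()] with blocks named `A`, `B`, ... and genes
#'   suffixed `_A`, `_B`, ...
#' @export
build_haplotype <- function(block, n_copies, divergence, seed = 1L,
                            hap_id = "H1") {
  check_scalar_number(n_copies, "n_copies", lower = 1)
  check_scalar_number(divergence, "divergence", lower = 0, upper = 0.2)
  len <- nchar(block$sequence)
  withr::with_seed(seed, {
    seqs <- character(n_copies)
    gene_tabs <- vector("list", n_copies)
    blocks <- vector("list", n_copies)
    for (i in seq_len(n_copies)) {
      bid <- if (n_copies <= 26) LETTERS[i] else paste0("B", i)
      n_sub <- rbinom(1, len, divergence)
      seqs[i] <- mutate_sequence(block$sequence, n_sub)
      off <- (i - 1L) * len
      g <- block$genes
      g$gene_id <- paste0(g$gene_id, "_", bid)
      g$exon_start <- lapply(g$exon_start, `+`, off)
      g$exon_end <- lapply(g$exon_end, `+`, off)
      gene_tabs[[i]] <- g
      blocks[[i]] <- tibble(block_id = bid, start = off, end = off + len)
    }
    haplotype(hap_id, paste(seqs, collapse = ""), bind_rows(blocks),
              bind_rows(gene_tabs))
  })
}

#' Derive an allelic haplotype differing by an exact SNP count
#'
#' Returns a second haplotype differing from `h1` at exactly `n_snps`
#' positions (substitutions only; the gene organisation is untouched), the
#' way two alleles of the same locus differ by a stated number of SNPs.
#'
#' @param h1 A [haplotype()].
#' @param n_snps Number of substitutions; at most a tenth of the sequence.
#' @param seed Integer seed.
#' @param hap_id Label for the derived haplotype.
#' @return A [haplotype()] with Hamming distance exactly `n_snps` from `h1`.
#' @export
inject_allelic_snps <- function(h1, n_snps, seed = 1L, hap_id = "H2") {
  stopifnot(inherits(h1, "haplotype"))
  n <- nchar(h1$sequence)
  if (n_snps > n / 10) abort("`n_snps` exceeds a tenth of the haplotype length")
  withr::with_seed(seed, {
    haplotype(hap_id, mutate_sequence(h1$sequence, n_snps), h1$blocks, h1$genes)
  })
}

#' Delete a gene's genomic span from a haplotype
#'
#' Removes the sequence from the first exon start to the last exon end of
#' `gene_id`, shifts all downstream coordinates, and drops the gene from the
#' annotation — ground truth for absence calls.
#'
#' @param h A [haplotype()].
#' @param gene_id Gene to delete; unknown ids are an error.
#' @return A new [haplotype()] (hap_id suffixed `-del<gene>`).
#' @export
delete_gene <- function(h, gene_id) {
  stopifnot(inherits(h, "haplotype"))
  i <- match(gene_id, h$genes$gene_id)
  if (is.na(i)) abort(sprintf("unknown gene_id: %s", gene_id))
  s <- min(h$genes$exon_start[[i]])
  e <- max(h$genes$exon_end[[i]])
  span <- e - s
  shift <- function(x) x - pmin(pmax(x - s, 0L), span)
  sequence <- paste0(substr(h$sequence, 1, s), substring(h$sequence, e + 1))
  genes <- h$genes[-i, ]
  overlaps <- vapply(seq_len(nrow(genes)), function(j) {
    min(genes$exon_start[[j]]) < e && max(genes$exon_end[[j]]) > s
  }, logical(1))
  if (any(overlaps)) abort("deletion span overlaps another gene model")
  genes$exon_start <- lapply(genes$exon_start, shift)
  genes$exon_end <- lapply(genes$exon_end, shift)
  blocks <- h$blocks
  blocks$start <- shift(blocks$start)
  blocks$end <- shift(blocks$end)
  blocks <- blocks[blocks$end > blocks$start, ]
  haplotype(paste0(h$hap_id, "-del", gene_id), sequence, blocks, genes)
}

#' Tile error-free reads across a reference
#'
#' Emits every window of the tile length from the forward strand, and the
#' reverse complement of every window from the reverse strand, all at the
#' constant tile quality — the simulated positive-control read set. Exactly
#' `2 * (N - L + 1)` reads for a reference of length `N`.
#'
#' @param reference A [haplotype()] or a single sequence string.
#' @param p [sim_params()].
#' @return A tibble of reads: `read_id`, `bases`, `qual`, `truth_hap`,
#'   `truth_pos` (0-based leftmost reference position), `truth_strand`.
#' @export
tile_reads <- function(reference, p = sim_params()) {
  seqc <- as_sequence(reference)
  hap_id <- if (inherits(reference, "haplotype")) reference$hap_id else "ref"
  L <- p$tile_read_length
  n <- nchar(seqc)
  if (n < L) abort(sprintf("reference (%d bp) shorter than tile length %d", n, L))
  starts <- 0:(n - L)
  fwd <- substring(seqc, starts + 1L, starts + L)
  qual <- strrep(intToUtf8(p$tile_quality + 33L), L)
  tibble(
    read_id = c(sprintf("tile_f_%06d", starts), sprintf("tile_r_%06d", starts)),
    bases = c(fwd, revcomp(fwd)),
    qual = qual,
    truth_hap = hap_id,
    truth_pos = c(starts, starts),
    truth_strand = rep(c("+", "-"), each = length(starts)))
}

#' Sample ancient-DNA-like reads
#'
#' Draws `n_ancient_reads` single-end reads uniformly over positions and
#' strands. Read lengths come from the configured range, with most lengths
#' falling in the modal range (a draw from the modal range with probability
#' `ancient_mode_weight`, otherwise from the full range). Each base is
#' substituted with probability `ancient_error_rate`, uniformly over the
#' three alternatives. Deterministic per seed. Post-mortem deamination
#' damage is not modelled; the uniform error rate is the configurable
#' stand-in.
#'
#' @inheritParams tile_reads
#' @return A tibble of reads with truth-origin columns as in [tile_reads()].
#' @export
sample_ancient_reads <- function(reference, p = sim_params()) {
  seqc <- as_sequence(reference)
  hap_id <- if (inherits(reference, "haplotype")) reference$hap_id else "ref"
  n_ref <- nchar(seqc)
  n <- p$n_ancient_reads
  withr::with_seed(p$seed, {
    from_mode <- runif(n) < p$ancient_mode_weight
    lens <- integer(n)
    lens[from_mode] <- sample(seq(p$ancient_length_mode[1], p$ancient_length_mode[2]),
                              sum(from_mode), replace = TRUE)
    lens[!from_mode] <- sample(seq(p$ancient_length_range[1], p$ancient_length_range[2]),
                               sum(!from_mode), replace = TRUE)
    lens <- pmin(lens, n_ref)
    starts <- floor(runif(n, 0, n_ref - lens + 1))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    bases <- substring(seqc, starts + 1, starts + lens)
    bases[strand == "-"] <- revcomp(bases[strand == "-"])
    n_err <- rbinom(n, lens, p$ancient_error_rate)
    for (i in which(n_err > 0)) {
      chars <- strsplit(bases[i], "")[[1]]
      at <- sample.int(lens[i], n_err[i])
      for (j in at) chars[j] <- sample(setdiff(DNA_BASES, chars[j]), 1)
      bases[i] <- paste(chars, collapse = "")
    }
    tibble(read_id = sprintf("anc%06d", seq_len(n)),
           bases = bases,
           qual = strrep(intToUtf8(p$tile_quality + 33L), lens),
           truth_hap = hap_id,
           truth_pos = as.integer(starts),
           truth_strand = strand)
  })
}

#' Number of ancient reads needed for a target mean depth
#'
#' @param ref_len Reference length in bp.
#' @param depth Target mean depth.
#' @param mean_read_len Expected read length (default 50, the midpoint of
#'   the default modal length range).
#' @return An integer read count.
#' @export
n_reads_for_depth <- function(ref_len, depth, mean_read_len = 50) {
  as.integer(ceiling(ref_len * depth / mean_read_len))
}
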