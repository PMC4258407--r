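# pileup, frequency-threshold SNP calling, cross-source conflict filter,
# majority-rule consensus, coding-effect annotation

#' Pileup of base counts from ungapped mapped reads
#'
#' One column per covered position. Multi-mapping reads are excluded by
#' default (they inflate variant frequencies with paralog cross-talk); the
#' `"all_best"` policy includes them at all tied best placements for the
#' "normal coverage" view.
#'
#' @param mapped A `mapped_reads` tibble from [map_reads()].
#' @param reference The reference that was mapped against (a [haplotype()],
#'   a single sequence string, or a tibble from [read_fasta()]).
#' @param ref_id Reference id (needed when several were mapped).
#' @param multi_policy `"exclude"` (default) or `"all_best"`.
#' @return A tibble: `pos` (0-based), `ref`, `A`, `C`, `G`, `T`, `depth`;
#'   only positions with depth > 0.
#' @export
pileup <- function(mapped, reference, ref_id = NULL,
                   multi_policy = c("exclude", "all_best")) {
  multi_policy <- match.arg(multi_policy)
  refs <- as_reference_set(reference)
  ref_lengths <- attr(mapped, "ref_lengths")
  if (is.null(ref_id)) {
    if (length(refs) > 1) abort("several references; supply `ref_id`")
    # a single bare sequence adopts the mapping's reference name
    ref_id <- if (!is.null(ref_lengths) && length(ref_lengths) == 1)
      names(ref_lengths) else names(refs)[1]
  }
  seqc <- refs[[1]]
  n <- nchar(seqc)
  if (!is.null(ref_lengths) && !is.na(ref_lengths[ref_id]) &&
      unname(ref_lengths[ref_id]) != n) {
    abort("reference length disagrees with the mapping")
  }
  hits <- mapped[!is.na(mapped$ref_id) & mapped$ref_id == ref_id &
                   mapped$mismatches == mapped$best_mm, , drop = FALSE]
  if (multi_policy == "exclude") {
    hits <- hits[hits$uniqueness == "unique", , drop = FALSE]
  }
  if (nrow(hits) == 0) {
    return(tibble(pos = integer(), ref = character(), A = integer(),
                  C = integer(), G = integer(), T = integer(),
                  depth = integer()))
  }
  counts <- cpp_pileup(n, hits$bases, as.integer(hits$start),
                       hits$strand == "-")
  depth <- colSums(counts)
  covered <- which(depth > 0)
  tibble(pos = covered - 1L,
         ref = substring(seqc, covered, covered),
         A = counts[1, covered], C = counts[2, covered],
         G = counts[3, covered], T = counts[4, covered],
         depth = as.integer(depth[covered]))
}

#' Call SNPs with frequency and depth cutoffs
#'
#' Emits a variant where depth is strictly greater than `min_depth` and the
#' most frequent non-reference base reaches `min_alt_freq` of the depth
#' (defaults: the published >5x coverage and 50.01% frequency cutoffs). A
#' site with two non-reference bases tied at the maximum is not called.
#'
#' @param columns A [pileup()] tibble.
#' @param p [caller_params()].
#' @return A tibble of variants: `position` (0-based), `ref`, `alt`, `freq`,
#'   `depth`, `effect` (NA until [annotate_effects()]).
#' @export
call_snps <- function(columns, p = caller_params()) {
  empty <- tibble(position = integer(), ref = character(), alt = character(),
                  freq = double(), depth = integer(), effect = character())
  if (nrow(columns) == 0) return(empty)
  cnt <- as.matrix(columns[, DNA_BASES])
  ref_idx <- match(columns$ref, DNA_BASES)
  alt_cnt <- cnt
  alt_cnt[cbind(seq_len(nrow(cnt)), ref_idx)] <- -1L
  best <- max.col(alt_cnt, ties.method = "first")
  best_n <- alt_cnt[cbind(seq_len(nrow(cnt)), best)]
  tied <- rowSums(alt_cnt == best_n) > 1L
  freq <- best_n / columns$depth
  keep <- columns$depth > p$min_depth & freq >= p$min_alt_freq & !tied &
    best_n > 0
  if (!any(keep)) return(empty)
  tibble(position = columns$pos[keep], ref = columns$ref[keep],
         alt = DNA_BASES[best[keep]], freq = freq[keep],
         depth = columns$depth[keep], effect = NA_character_)
}

# majority base of each pileup column; ties return NA
majority_base <- function(columns) {
  if (nrow(columns) == 0) return(character(0))
  cnt <- as.matrix(columns[, DNA_BASES])
  best <- max.col(cnt, ties.method = "first")
  best_n <- cnt[cbind(seq_len(nrow(cnt)), best)]
  tied <- rowSums(cnt == best_n) > 1L
  out <- DNA_BASES[best]
  out[tied | best_n == 0] <- NA_character_
  out
}

#' Cross-source conflict filter
#'
#' Compares the majority base of two alignments of the same reference (for
#' example two sequencing technologies) and returns the positions where they
#' conflict while the conflicting source is weakly covered — depth below
#' `conflict_min_depth_a` for source A or below `conflict_min_depth_b` for
#' source B (defaults 8 and 500, the published 454/Illumina convention).
#' These positions are masked from consensus and variant output.
#'
#' @param columns_a,columns_b [pileup()] tibbles on the same reference.
#' @param p [caller_params()].
#' @return A tibble: `position`, `base_a`, `depth_a`, `base_b`, `depth_b`,
#'   `weak_source` (`"a"`, `"b"` or `"both"`); `$position` is the mask.
#' @export
cross_source_filter <- function(columns_a, columns_b, p = caller_params()) {
  shared <- intersect(columns_a$pos, columns_b$pos)
  a <- columns_a[match(shared, columns_a$pos), , drop = FALSE]
  b <- columns_b[match(shared, columns_b$pos), , drop = FALSE]
  ma <- majority_base(a)
  mb <- majority_base(b)
  conflict <- !is.na(ma) & !is.na(mb) & ma != mb
  weak_a <- a$depth < p$conflict_min_depth_a
  weak_b <- b$depth < p$conflict_min_depth_b
  sel <- conflict & (weak_a | weak_b)
  tibble(position = shared[sel], base_a = ma[sel], depth_a = a$depth[sel],
         base_b = mb[sel], depth_b = b$depth[sel],
         weak_source = dplyr::case_when(weak_a[sel] & weak_b[sel] ~ "both",
                                        weak_a[sel] ~ "a", TRUE ~ "b"))
}

#' Majority-rule consensus sequence
#'
#' Per position, the base whose frequency reaches `majority_freq` of the
#' depth (default the published 51%). Positions where no base reaches the
#' threshold, with zero depth, or listed in `mask` fall back to the tie
#' policy (default: the reference base; `"first-alphabetical"` takes the
#' alphabetically first among the most frequent bases, or the reference at
#' zero depth). The output contains only `A`, `C`, `G`, `T` — never an
#' ambiguity code — and has the reference length.
#'
#' @param columns A [pileup()] tibble.
#' @param reference The reference sequence (string, [haplotype()], or
#'   [read_fasta()] tibble).
#' @param p [consensus_params()].
#' @param ref_id Reference id when `reference` holds several.
#' @param mask Optional integer vector of 0-based positions (for example
#'   from [cross_source_filter()]) forced to the tie policy.
#' @return A single consensus sequence string.
#' @export
majority_consensus <- function(columns, reference, p = consensus_params(),
                               ref_id = NULL, mask = integer(0)) {
  refs <- as_reference_set(reference)
  if (is.null(ref_id)) ref_id <- names(refs)[1]
  seqc <- refs[[ref_id]]
  n <- nchar(seqc)
  out <- strsplit(seqc, "")[[1]]
  if (nrow(columns) > 0) {
    cnt <- as.matrix(columns[, DNA_BASES])
    best <- max.col(cnt, ties.method = "first")
    best_n <- cnt[cbind(seq_len(nrow(cnt)), best)]
    called <- best_n / columns$depth >= p$majority_freq & columns$depth > 0
    idx <- columns$pos + 1L
    out[idx[called]] <- DNA_BASES[best[called]]
    if (p$tie_policy == "first-alphabetical") {
      tied <- !called & best_n > 0
      out[idx[tied]] <- DNA_BASES[best[tied]] # max.col "first" = alphabetical
    }
  }
  if (length(mask) > 0) {
    ref_chars <- strsplit(seqc, "")[[1]]
    out[mask + 1L] <- ref_chars[mask + 1L]
  }
  stopifnot(length(out) == n)
  paste(out, collapse = "")
}

# spliced CDS of a gene from a sequence: strand-aware, exons in genomic
# order; minus-strand genes return the reverse complement of the splice
spliced_cds <- function(gene, sequence) {
  if (is.data.frame(gene)) stopifnot(nrow(gene) == 1)
  es <- gene$exon_start[[1]]
  ee <- gene$exon_end[[1]]
  if (max(ee) > nchar(sequence)) abort("gene exons outside sequence")
  splice <- paste(substring(sequence, es + 1L, ee), collapse = "")
  if (gene$strand[1] == "-") revcomp(splice) else splice
}

translate_codons <- function(codons) {
  unname(Biostrings::GENETIC_CODE[codons])
}

#' Annotate coding effects of called variants
#'
#' Each variant falling in an exon is substituted alone into its codon of
#' the spliced, strand-aware CDS and classified with the standard genetic
#' code: `synonymous`, `nonsynonymous`, or `nonsense` (stop gain). Variants
#' outside every exon get `intergenic/intronic`. Genes whose spliced CDS
#' length is not a multiple of 3 trigger a warning and their variants keep
#' `NA` effects.
#'
#' @param variants A [call_snps()] tibble.
#' @param genes A gene-model tibble.
#' @param reference The reference sequence.
#' @return `variants` with the `effect` column filled.
#' @export
annotate_effects <- function(variants, genes, reference) {
  seqc <- as_sequence(reference)
  if (nrow(variants) == 0) return(variants)
  variants$effect <- "intergenic/intronic"
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    es <- g$exon_start[[1]]
    ee <- g$exon_end[[1]]
    cds <- spliced_cds(g, seqc)
    if (nchar(cds) %% 3 != 0) {
      warn(sprintf("gene %s: spliced CDS length not a multiple of 3; effects omitted",
                   g$gene_id))
      in_exon <- vapply(variants$position, function(p)
        any(p >= es & p < ee), logical(1))
      variants$effect[in_exon] <- NA_character_
      next
    }
    exon_len <- ee - es
    cum <- cumsum(c(0L, exon_len))
    for (v in seq_len(nrow(variants))) {
      pos <- variants$position[v]
      e <- which(pos >= es & pos < ee)
      if (length(e) == 0) next
      splice_pos <- cum[e] + (pos - es[e]) # 0-based position in forward splice
      L <- nchar(cds)
      if (g$strand == "+") {
        cds_pos <- splice_pos
        alt <- variants$alt[v]
      } else {
        cds_pos <- L - 1L - splice_pos
        alt <- revcomp(variants$alt[v])
      }
      ci <- cds_pos %/% 3L
      off <- cds_pos %% 3L
      codon <- substring(cds, ci * 3L + 1L, ci * 3L + 3L)
      new_codon <- codon
      substr(new_codon, off + 1L, off + 1L) <- alt
      aa_old <- translate_codons(codon)
      aa_new <- translate_codons(new_codon)
      variants$effect[v] <-
        if (aa_old == aa_new) "synonymous"
        else if (aa_new == "*") "nonsense"
        else "nonsynonymous"
    }
  }
  variants
}

#' Write variants as a TSV report (1-based positions)
#'
#' @param variants A [call_snps()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants_tsv <- function(variants, path) {
  out <- variants
  out$position <- out$position + 1L
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a mask (for example from [cross_source_filter()]) as BED
#'
#' @param positions Integer vector of 0-based positions.
#' @param path Output path.
#' @param ref Reference name for the BED chrom column.
#' @return `path`, invisibly.
#' @export
write_mask_bed <- function(positions, path, ref = "ref") {
  positions <- sort(unique(as.integer(positions)))
  writeLines(sprintf("%s\t%d\t%d", ref, positions, positions + 1L), path)
  invisible(path)
}
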