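# end-to-end presence/absence pipeline and its broom-style methods

# pileup tibble from pre-assigned hits on one member sequence
pileup_from_hits <- function(hits, member_seq) {
  n <- nchar(member_seq)
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
         ref = substring(member_seq, covered, covered),
         A = counts[1, covered], C = counts[2, covered],
         G = counts[3, covered], T = counts[4, covered],
         depth = as.integer(depth[covered]))
}

#' Infer presence/absence of every gene of a duplicated locus
#'
#' Runs the full two-evidence analysis against a reference haplotype:
#' \enumerate{
#'   \item a tiling positive control ([tile_reads()]) is mapped to the
#'     reference to measure what unique coverage the locus structure itself
#'     permits per gene;
#'   \item the sample reads are mapped and per-gene unique coverage is
#'     compared against that control;
#'   \item sample reads are mapped to the per-gene reference set
#'     (optionally including allelic variants from a second haplotype),
#'     reads exclusive to a single paralog group are kept, assigned to
#'     their best-matching group member (within-group ties dropped), and
#'     the gene-defining diagnostic SNPs are scored for consistency;
#'   \item [call_presence()] combines both branches per gene.
#' }
#'
#' @param reference A [haplotype()] with gene and group annotation.
#' @param reads A sample reads tibble (e.g. [sample_ancient_reads()] output
#'   or [read_fastq()]).
#' @param allelic Optional second [haplotype()] on shared coordinates whose
#'   alleles sharpen the diagnostics.
#' @param sim [sim_params()] for the tiling control.
#' @param map [map_params()].
#' @param thresholds [presence_thresholds()].
#' @param control_min_depth Depth a control position needs to count as
#'   covered (default 1; a single tiling pass cannot exceed twice the tile
#'   length, so the deep-control depth>1000 convention only applies to
#'   replicated control sets).
#' @return A `presence_run` object: `calls`, `coverage` (per-gene table),
#'   `control_coverage`, `sample_profile`, `control_profile`, `reports`
#'   (consistency), `mapping_summary`.
#' @export
infer_presence <- function(reference, reads, allelic = NULL,
                           sim = sim_params(), map = map_params(),
                           thresholds = presence_thresholds(),
                           control_min_depth = 1L) {
  stopifnot(inherits(reference, "haplotype"))
  reads <- as_reads(reads)
  genes <- reference$genes
  ref_index <- build_index(reference, map)

  control_map <- map_reads(tile_reads(reference, sim), ref_index)
  control_profile <- depth_profile(control_map)
  control_cov <- gene_coverage_table(control_profile, genes,
                                     min_depth = control_min_depth)

  sample_map <- map_reads(reads, ref_index)
  sample_profile <- depth_profile(sample_map)
  sample_cov <- gene_coverage_table(sample_profile, genes)
  # locus-wide adequacy: absence may only be declared when the sample
  # demonstrably covered the locus (not merely this gene's span, which a
  # whole-family deletion legitimately empties)
  adequate <- mean(sample_profile$total_depth > 0) >= 0.5

  primary <- sample_map[is.na(sample_map$ref_id) | sample_map$hit_rank == 1L, ]
  mapping_summary <- tibble(
    n_reads = nrow(primary),
    pct_mapped = 100 * mean(primary$uniqueness != "unmapped"),
    pct_multi_of_mapped = 100 * mean(
      primary$uniqueness[primary$uniqueness != "unmapped"] == "multi"))

  # SNP evidence: one mapping of the sample against all gene members
  haps <- c(list(reference), if (!is.null(allelic)) list(allelic))
  flank <- min(max(nchar(reads$bases)), 100L)
  gene_refs <- gene_reference_set(haps, flank = flank)
  member_index <- build_index(setNames(gene_refs$sequence, gene_refs$member),
                              map)
  member_map <- map_reads(reads, member_index, map)
  hit_tbl <- member_map[!is.na(member_map$ref_id), , drop = FALSE]
  hit_tbl$group <- gene_refs$group[match(hit_tbl$ref_id, gene_refs$member)]
  per_read <- hit_tbl |>
    group_by(.data$read_id) |>
    summarise(n_groups = dplyr::n_distinct(.data$group),
              group = .data$group[1], .groups = "drop")
  exclusive <- per_read[per_read$n_groups == 1L, , drop = FALSE]

  reports <- list()
  for (grp in unique(genes$group)) {
    grp_members <- gene_refs[gene_refs$group == grp, , drop = FALSE]
    pile_members <- grp_members[grp_members$hap_id == reference$hap_id, ,
                                drop = FALSE]
    span_seqs <- setNames(
      substring(grp_members$sequence, grp_members$left_flank + 1L,
                grp_members$left_flank + grp_members$span_len),
      grp_members$member)
    diags <- NULL
    if (length(span_seqs) >= 2 && length(unique(nchar(span_seqs))) == 1) {
      diags <- diagnostic_positions(span_seqs)
    }
    grp_read_ids <- exclusive$read_id[exclusive$group == grp]
    gh <- hit_tbl[hit_tbl$read_id %in% grp_read_ids &
                    hit_tbl$ref_id %in% pile_members$member, , drop = FALSE]
    if (nrow(gh) > 0) {
      gh <- gh |>
        group_by(.data$read_id) |>
        mutate(sub_best = min(.data$mismatches),
               sub_n = sum(.data$mismatches == min(.data$mismatches))) |>
        ungroup()
      gh <- gh[gh$mismatches == gh$sub_best & gh$sub_n == 1L, , drop = FALSE]
    }
    for (j in seq_len(nrow(pile_members))) {
      gene <- pile_members$gene_id[j]
      if (is.null(diags) || nrow(diags) == 0) {
        reports[[gene]] <- NULL
        next
      }
      mh <- gh[gh$ref_id == pile_members$member[j], , drop = FALSE]
      pil <- pileup_from_hits(mh, pile_members$sequence[j])
      reports[[gene]] <- consistency_counts(
        pil, diags, gene, min_depth = thresholds$min_depth,
        offset = pile_members$left_flank[j])
    }
  }

  calls <- bind_rows(lapply(seq_len(nrow(genes)), function(i) {
    g <- genes$gene_id[i]
    call_presence(g,
                  sample_unique_cov_pct = sample_cov$unique_pct[
                    match(g, sample_cov$gene_id)],
                  control_unique_cov_pct = control_cov$unique_pct[
                    match(g, control_cov$gene_id)],
                  report = reports[[g]],
                  adequate_depth = adequate,
                  thresholds = thresholds)
  }))

  structure(list(calls = calls, coverage = sample_cov,
                 control_coverage = control_cov,
                 sample_profile = sample_profile,
                 control_profile = control_profile,
                 reports = reports, mapping_summary = mapping_summary,
                 thresholds = thresholds),
            class = "presence_run")
}

#' @export
print.presence_run <- function(x, ...) {
  s <- x$mapping_summary
  cat(sprintf(
    "<presence_run> %d gene(s): %d present, %d absent, %d indeterminate\n",
    nrow(x$calls), sum(x$calls$status == "present"),
    sum(x$calls$status == "absent"),
    sum(x$calls$status == "indeterminate")))
  cat(sprintf("  reads: %d (%.1f%% mapped, %.1f%% of mapped multi-mapping)\n",
              s$n_reads, s$pct_mapped, s$pct_multi_of_mapped))
  print(x$calls[, c("gene_id", "status", "unique_cov_pct", "control_cov_pct",
                    "n_diag", "n_cons")])
  invisible(x)
}

#' Tidy a presence run into its per-gene call table
#'
#' @param x A `presence_run` from [infer_presence()].
#' @param ... Unused.
#' @return The per-gene calls tibble.
#' @method tidy presence_run
#' @export
tidy.presence_run <- function(x, ...) {
  x$calls
}

#' One-row summary of a presence run
#'
#' @param x A `presence_run` from [infer_presence()].
#' @param ... Unused.
#' @return A one-row tibble: gene counts by status, read-mapping
#'   percentages, and mean unique coverage.
#' @method glance presence_run
#' @export
glance.presence_run <- function(x, ...) {
  tibble(n_genes = nrow(x$calls),
         n_present = sum(x$calls$status == "present"),
         n_absent = sum(x$calls$status == "absent"),
         n_indeterminate = sum(x$calls$status == "indeterminate"),
         pct_mapped = x$mapping_summary$pct_mapped,
         pct_multi_of_mapped = x$mapping_summary$pct_multi_of_mapped,
         mean_unique_cov_pct = mean(x$coverage$unique_pct),
         mean_control_cov_pct = mean(x$control_coverage$unique_pct))
}

#' Write the presence calls as TSV
#'
#' @param run A `presence_run`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_presence_tsv <- function(run, path) {
  readr::write_tsv(run$calls, path, progress = FALSE)
  invisible(path)
}
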