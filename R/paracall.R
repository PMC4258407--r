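# paralog presence/absence inference: group-exclusive read filtering,
# diagnostic-SNP consistency counting, coverage comparison with the control

#' Per-gene reference set (genomic spans, optionally with allelic variants)
#'
#' Extracts each gene's genomic span (plus a flank) from one or more
#' haplotypes with identical gene organisation. When several haplotypes are
#' given, each gene contributes one member per haplotype, named
#' `<gene_id>@<hap_id>` — the allelic variants that sharpen intragroup
#' diagnostics.
#'
#' @param haps A [haplotype()] or list of haplotypes sharing coordinates.
#' @param flank Flank in bp added on each side of the span (reads
#'   overlapping the span edges then still align end-to-end); clamped at the
#'   haplotype ends, with the realised left flank recorded per member.
#' @return A tibble: `member`, `gene_id`, `group`, `hap_id`, `sequence`,
#'   `left_flank`, `span_len`.
#' @export
gene_reference_set <- function(haps, flank = 70L) {
  if (inherits(haps, "haplotype")) haps <- list(haps)
  multi <- length(haps) > 1
  rows <- list()
  for (h in haps) {
    n <- nchar(h$sequence)
    for (i in seq_len(nrow(h$genes))) {
      g <- h$genes[i, ]
      span_s <- min(g$exon_start[[1]])
      span_e <- max(g$exon_end[[1]])
      s <- max(0L, span_s - as.integer(flank))
      e <- min(n, span_e + as.integer(flank))
      member <- if (multi) paste0(g$gene_id, "@", h$hap_id) else g$gene_id
      rows[[length(rows) + 1L]] <- tibble(
        member = member, gene_id = g$gene_id, group = g$group,
        hap_id = h$hap_id, sequence = substring(h$sequence, s + 1L, e),
        left_flank = span_s - s, span_len = span_e - span_s)
    }
  }
  bind_rows(rows)
}

#' Group-exclusive read filtering
#'
#' Keeps the reads that align (within the mismatch limit) to at least one
#' member of the target paralog group and to no gene of any other group —
#' the filter that lets highly similar paralogs be interrogated one group at
#' a time.
#'
#' @param reads A reads tibble.
#' @param gene_refs A [gene_reference_set()] tibble (or any tibble with
#'   `member`, `group`, `sequence`).
#' @param target_group Group label to retain reads for.
#' @param p [map_params()].
#' @return The subset of `reads` exclusive to `target_group`.
#' @export
group_exclusive_reads <- function(reads, gene_refs, target_group,
                                  p = map_params()) {
  reads <- as_reads(reads)
  if (!target_group %in% gene_refs$group) {
    abort(sprintf("unknown group '%s'", target_group))
  }
  idx <- build_index(setNames(gene_refs$sequence, gene_refs$member), p)
  m <- map_reads(reads, idx, p)
  hit_groups <- m[!is.na(m$ref_id), c("read_id", "ref_id")]
  hit_groups$group <- gene_refs$group[match(hit_groups$ref_id, gene_refs$member)]
  per_read <- hit_groups |>
    group_by(.data$read_id) |>
    summarise(in_target = any(.data$group == target_group),
              other = any(.data$group != target_group), .groups = "drop")
  keep_ids <- per_read$read_id[per_read$in_target & !per_read$other]
  reads[reads$read_id %in% keep_ids, , drop = FALSE]
}

#' Diagnostic positions of an aligned paralog-group member set
#'
#' Scans a set of equal-length (pre-aligned, or co-linear by construction)
#' member sequences for columns carrying at least two distinct non-gap
#' bases. For each such column the per-member base is reported, and a
#' member `discriminates` at the column when its base differs from every
#' other member's base — a gene-defining SNP.
#'
#' @param member_seqs Named character vector of aligned member sequences
#'   (gaps as `-`).
#' @return A long tibble: `column` (0-based), `member`, `base`,
#'   `discriminates`.
#' @export
diagnostic_positions <- function(member_seqs) {
  if (length(member_seqs) < 2) abort("need at least two member sequences")
  if (length(unique(nchar(member_seqs))) != 1) {
    abort("member sequences have unequal alignment lengths")
  }
  mat <- do.call(rbind, strsplit(toupper(member_seqs), ""))
  rownames(mat) <- names(member_seqs)
  n_distinct_bases <- apply(mat, 2, function(col) {
    length(unique(col[col != "-"]))
  })
  cols <- which(n_distinct_bases >= 2)
  if (length(cols) == 0) {
    return(tibble(column = integer(), member = character(),
                  base = character(), discriminates = logical()))
  }
  out <- lapply(cols, function(j) {
    col <- mat[, j]
    disc <- vapply(seq_along(col), function(i) {
      col[i] != "-" && !col[i] %in% col[-i]
    }, logical(1))
    tibble(column = j - 1L, member = names(member_seqs), base = unname(col),
           discriminates = disc)
  })
  bind_rows(out)
}

#' Consistency counts of gene-defining SNPs in sample reads
#'
#' For one gene, takes the diagnostic columns that define it — columns where
#' the gene's base (the union over its alleles, when allelic members are
#' present) differs from every other group member's base — and scores each
#' against a pileup of sample reads in the member's own coordinates:
#' `consistent` when the majority sample base is one of the gene's bases,
#' `inconsistent` when it is a different base (or tied), `uncovered` when
#' depth is below `min_depth`. The three counts always partition the
#' defining columns, so missing data are never mistaken for absence.
#'
#' @param sample_pileup A [pileup()] tibble over the member sequence.
#' @param diagnostics A [diagnostic_positions()] tibble for the group.
#' @param gene_id Gene to score; members named `<gene_id>` or
#'   `<gene_id>@<hap>` count as its alleles.
#' @param min_depth Minimum depth for a column to count as covered.
#' @param offset Offset of the alignment column 0 within the pileup
#'   coordinates (the flank width when the member sequences carry flanks).
#' @return A one-row tibble: `gene_id`, `n_diagnostic`, `n_consistent`,
#'   `n_inconsistent`, `n_uncovered`.
#' @export
consistency_counts <- function(sample_pileup, diagnostics, gene_id,
                               min_depth = 3L, offset = 0L) {
  is_allele <- diagnostics$member == gene_id |
    startsWith(diagnostics$member, paste0(gene_id, "@"))
  if (!any(is_allele)) {
    abort(sprintf("gene '%s' has no member in the diagnostics", gene_id))
  }
  cols <- sort(unique(diagnostics$column))
  key <- as.character(cols)
  own_tab <- split(diagnostics$base[is_allele], diagnostics$column[is_allele])
  oth_tab <- split(diagnostics$base[!is_allele], diagnostics$column[!is_allele])
  own <- lapply(key, function(k) setdiff(unique(own_tab[[k]]), "-"))
  oth <- lapply(key, function(k) setdiff(unique(oth_tab[[k]]), "-"))
  keep <- vapply(own, length, integer(1)) > 0 &
    !mapply(function(a, b) length(intersect(a, b)) > 0, own, oth)
  cols <- cols[keep]
  own <- own[keep]
  n_diag <- length(cols)
  if (n_diag == 0) {
    return(tibble(gene_id = gene_id, n_diagnostic = 0L, n_consistent = 0L,
                  n_inconsistent = 0L, n_uncovered = 0L))
  }
  pil_pos <- cols + offset
  row <- match(pil_pos, sample_pileup$pos)
  depth <- ifelse(is.na(row), 0L, sample_pileup$depth[row])
  maj <- rep(NA_character_, n_diag)
  maj[!is.na(row)] <- majority_base(sample_pileup[row[!is.na(row)], , drop = FALSE])
  covered <- depth >= min_depth
  consistent <- covered & !is.na(maj) &
    mapply(function(m, o) !is.na(m) && m %in% o, maj, own)
  inconsistent <- covered & !consistent
  tibble(gene_id = gene_id, n_diagnostic = n_diag,
         n_consistent = sum(consistent),
         n_inconsistent = sum(inconsistent),
         n_uncovered = sum(!covered))
}

#' Presence/absence call for one gene
#'
#' Synthesises the two lines of evidence into a verdict:
#' \describe{
#'   \item{present}{enough consistent gene-defining SNPs with a tolerably
#'     small inconsistent fraction, OR sample unique coverage reaching
#'     `cov_frac` of the control unique coverage;}
#'   \item{absent}{control predicts coverage but the sample has essentially
#'     none (below `absent_cov_frac` of control), no consistent defining
#'     SNP, and `adequate_depth` is TRUE — absence is only ever declared
#'     when the sample demonstrably carried data over the locus, so missing
#'     data are not mistaken for a missing gene;}
#'   \item{indeterminate}{everything else — in particular any gene whose
#'     control unique coverage is below `control_floor` (fully duplicated
#'     sequence), which is only decidable through diagnostic SNPs.}
#' }
#' The rationale string records which branch fired.
#'
#' @param gene_id Gene label.
#' @param sample_unique_cov_pct,control_unique_cov_pct Unique-coverage
#'   percentages from [gene_coverage_pct()] for the sample and the tiling
#'   control.
#' @param report A [consistency_counts()] row (NULL when the gene has no
#'   defining SNPs).
#' @param adequate_depth Did the sample carry adequate read depth over this
#'   gene's family (e.g. its span is well covered by total/normal reads)?
#'   Absence is never called when FALSE.
#' @param thresholds [presence_thresholds()].
#' @return A one-row `presence_call` tibble.
#' @export
call_presence <- function(gene_id, sample_unique_cov_pct,
                          control_unique_cov_pct, report = NULL,
                          adequate_depth = TRUE,
                          thresholds = presence_thresholds()) {
  t <- thresholds
  if (is.null(report) || nrow(report) == 0) {
    report <- tibble(gene_id = gene_id, n_diagnostic = 0L, n_consistent = 0L,
                     n_inconsistent = 0L, n_uncovered = 0L)
  }
  snp_ok <- report$n_consistent >= t$min_consistent &&
    report$n_diagnostic > 0 &&
    report$n_inconsistent / report$n_diagnostic <= t$max_inconsistent_frac
  control_ok <- control_unique_cov_pct >= t$control_floor
  cov_ok <- control_ok &&
    sample_unique_cov_pct >= t$cov_frac * control_unique_cov_pct
  cov_absent <- control_ok &&
    sample_unique_cov_pct < t$absent_cov_frac * control_unique_cov_pct
  if (snp_ok) {
    status <- "present"
    rationale <- sprintf("SNP branch: %d/%d defining sites consistent (%d inconsistent)",
                         report$n_consistent, report$n_diagnostic,
                         report$n_inconsistent)
  } else if (cov_ok) {
    status <- "present"
    rationale <- sprintf("coverage branch: unique %.1f%% >= %.2f x control %.1f%%",
                         sample_unique_cov_pct, t$cov_frac,
                         control_unique_cov_pct)
  } else if (cov_absent && report$n_consistent == 0 && adequate_depth) {
    status <- "absent"
    rationale <- sprintf(
      "unique coverage %.1f%% despite control %.1f%%, no consistent defining SNP",
      sample_unique_cov_pct, control_unique_cov_pct)
  } else if (!control_ok) {
    status <- "indeterminate"
    rationale <- sprintf(
      "control unique coverage %.1f%% below floor %.1f%%; SNP evidence insufficient",
      control_unique_cov_pct, t$control_floor)
  } else {
    status <- "indeterminate"
    rationale <- "evidence insufficient for either branch"
  }
  out <- tibble(gene_id = gene_id, status = status,
                unique_cov_pct = sample_unique_cov_pct,
                control_cov_pct = control_unique_cov_pct,
                n_diag = report$n_diagnostic, n_cons = report$n_consistent,
                n_incons = report$n_inconsistent,
                n_uncov = report$n_uncovered, rationale = rationale)
  class(out) <- c("presence_call", class(out))
  out
}
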