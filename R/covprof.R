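# depth profiles, sliding-window coverage tracks, per-gene coverage

#' Per-position depth profile of total and uniquely mapping reads
#'
#' `total_depth` counts each read at its best placement(s): uniquely mapping
#' reads at their single best hit, multi-mapping reads (under the default
#' `"all_best"` policy) at all tied best hits — the "normal coverage" view.
#' Under `"exclude"`, multi-mapping reads are dropped entirely.
#' `unique_depth` always counts only uniquely mapping reads, the basis of
#' per-gene unique-coverage evidence.
#'
#' @param mapped A `mapped_reads` tibble from [map_reads()].
#' @param ref_id Reference to profile; defaults to the only reference in the
#'   index the reads were mapped against.
#' @param multi_policy `"all_best"` (default) or `"exclude"`.
#' @return A `depth_profile` tibble: `pos` (0-based), `total_depth`,
#'   `unique_depth`; one row per reference position.
#' @export
depth_profile <- function(mapped, ref_id = NULL,
                          multi_policy = c("all_best", "exclude")) {
  multi_policy <- match.arg(multi_policy)
  ref_lengths <- attr(mapped, "ref_lengths")
  stopifnot(!is.null(ref_lengths))
  if (is.null(ref_id)) {
    if (length(ref_lengths) != 1) {
      abort("several references mapped; supply `ref_id`")
    }
    ref_id <- names(ref_lengths)[1]
  }
  n <- unname(ref_lengths[ref_id])
  if (is.na(n)) abort(sprintf("unknown ref_id '%s'", ref_id))
  hits <- mapped[!is.na(mapped$ref_id) & mapped$ref_id == ref_id &
                   mapped$mismatches == mapped$best_mm, , drop = FALSE]
  if (nrow(hits) > 0 &&
      any(hits$start < 0 | hits$start + nchar(hits$bases) > n)) {
    abort("hit outside reference bounds")
  }
  uniq <- hits[hits$uniqueness == "unique", , drop = FALSE]
  tot <- if (multi_policy == "exclude") uniq else hits
  total_depth <- cpp_depth(n, as.integer(tot$start), nchar(tot$bases))
  unique_depth <- cpp_depth(n, as.integer(uniq$start), nchar(uniq$bases))
  out <- tibble(pos = 0:(n - 1L), total_depth = total_depth,
                unique_depth = unique_depth)
  attr(out, "ref_id") <- ref_id
  class(out) <- c("depth_profile", class(out))
  out
}

#' Sliding-window mean depth track
#'
#' Arithmetic mean of per-position depth in windows of `window` bp, step 1,
#' reported at the window start; output has `N - window + 1` rows.
#'
#' @param profile A [depth_profile()] tibble.
#' @param window Window size in bp (default the published 300).
#' @return A tibble `start` (0-based), `total_mean`, `unique_mean`.
#' @export
sliding_mean_depth <- function(profile, window = window_params()$coverage_window) {
  n <- nrow(profile)
  if (window > n) abort(sprintf("window %d exceeds profile length %d", window, n))
  wmean <- function(x) {
    cs <- cumsum(c(0, x))
    (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
  }
  tibble(start = 0:(n - window),
         total_mean = wmean(profile$total_depth),
         unique_mean = wmean(profile$unique_depth))
}

# positions (1-based index into profile) covered by a gene: genomic span or
# exon union
gene_positions <- function(gene, exonic = FALSE) {
  es <- gene$exon_start[[1]]
  ee <- gene$exon_end[[1]]
  if (exonic) {
    unlist(mapply(seq, es + 1L, ee, SIMPLIFY = FALSE))
  } else {
    (min(es) + 1L):max(ee)
  }
}

#' Percent coverage of a gene
#'
#' Fraction (in percent) of positions within the gene's genomic span (first
#' exon start to last exon end; exon-only with `exonic = TRUE`) whose
#' selected depth reaches `min_depth`. Use `min_depth = 1` for sample data;
#' deep positive-control sets conventionally use depth > 1000
#' (`window_params()$control_min_depth`).
#'
#' @param profile A [depth_profile()].
#' @param gene A one-row gene-model tibble (or list with `exon_start`,
#'   `exon_end`).
#' @param use_unique Use `unique_depth` (default) or `total_depth`.
#' @param min_depth Minimum depth for a position to count as covered.
#' @param exonic Restrict to exons rather than the genomic span.
#' @return A single percentage in `[0, 100]`.
#' @export
gene_coverage_pct <- function(profile, gene, use_unique = TRUE, min_depth = 1L,
                              exonic = FALSE) {
  if (is.data.frame(gene)) stopifnot(nrow(gene) == 1)
  pos <- gene_positions(gene, exonic)
  if (max(pos) > nrow(profile)) abort("gene extends beyond the profile")
  depth <- if (use_unique) profile$unique_depth else profile$total_depth
  100 * mean(depth[pos] >= min_depth)
}

#' Per-gene coverage report
#'
#' @param profile A [depth_profile()].
#' @param genes A gene-model tibble.
#' @param min_depth Minimum depth for a position to count as covered.
#' @param exonic Restrict to exons rather than genomic spans.
#' @return A tibble: `gene_id`, `group`, `span_bp`, `total_pct`,
#'   `unique_pct`, `mean_depth` (mean total depth over the span).
#' @export
gene_coverage_table <- function(profile, genes, min_depth = 1L, exonic = FALSE) {
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    pos <- gene_positions(g, exonic)
    tibble(gene_id = g$gene_id, group = g$group,
           span_bp = max(g$exon_end[[1]]) - min(g$exon_start[[1]]),
           total_pct = gene_coverage_pct(profile, g, use_unique = FALSE,
                                         min_depth = min_depth, exonic = exonic),
           unique_pct = gene_coverage_pct(profile, g, use_unique = TRUE,
                                          min_depth = min_depth, exonic = exonic),
           mean_depth = mean(profile$total_depth[pos]))
  })
  bind_rows(rows)
}

#' Write a depth profile as bedGraph
#'
#' @param profile A [depth_profile()].
#' @param path Output path.
#' @param track `"unique"` or `"total"`.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(profile, path, track = c("unique", "total")) {
  track <- match.arg(track)
  d <- if (track == "unique") profile$unique_depth else profile$total_depth
  ref <- attr(profile, "ref_id") %||% "ref"
  r <- rle(d)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  writeLines(sprintf("%s\t%d\t%d\t%d", ref, starts, ends, r$values), path)
  invisible(path)
}
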