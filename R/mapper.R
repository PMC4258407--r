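# exact ungapped read mapper with unique-mappability classification

#' Build a k-mer index over a reference set
#'
#' Exact positional k-mer index over both strands (reverse-strand queries
#' are answered by matching the reverse complement of the read against the
#' forward sequence); windows containing N are never seeded.
#'
#' @param references A [haplotype()], named character vector, or tibble with
#'   `id` and `sequence`.
#' @param p [map_params()].
#' @return An object of class `kmer_index`.
#' @export
build_index <- function(references, p = map_params()) {
  refs <- as_reference_set(references)
  if (length(refs) == 0) abort("empty reference set")
  if (any(nchar(refs) < p$k)) {
    abort(sprintf("reference '%s' shorter than seed length k=%d",
                  names(refs)[which(nchar(refs) < p$k)[1]], p$k))
  }
  structure(list(refs = refs, params = p), class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("<kmer_index> %d reference(s), %s bp total, k=%d\n",
              length(x$refs), format(sum(nchar(x$refs)), big.mark = ","),
              x$params$k))
  invisible(x)
}

#' Query exact occurrences of a k-mer in an index
#'
#' @param index A [build_index()] object.
#' @param kmer A k-length DNA string; k-mers containing N have no seeded
#'   occurrences by construction.
#' @return A tibble with `ref_id`, `pos` (0-based), `strand`.
#' @export
index_query <- function(index, kmer) {
  stopifnot(inherits(index, "kmer_index"))
  kmer <- toupper(kmer)
  if (grepl("N", kmer)) {
    return(tibble(ref_id = character(), pos = integer(), strand = character()))
  }
  find_all <- function(ref, pat) {
    m <- gregexpr(paste0("(?=", pat, ")"), ref, perl = TRUE)[[1]]
    if (m[1] == -1) integer(0) else as.integer(m) - 1L
  }
  out <- list()
  for (id in names(index$refs)) {
    fwd <- find_all(index$refs[[id]], kmer)
    rev <- find_all(index$refs[[id]], revcomp(kmer))
    out[[id]] <- bind_rows(
      tibble(ref_id = id, pos = fwd, strand = "+"),
      tibble(ref_id = id, pos = rev, strand = "-"))
  }
  bind_rows(out)
}

# effective seed length giving the pigeonhole full-sensitivity guarantee for
# the shortest read: with a seed at every offset, a read of length L with at
# most m mismatches always retains a clean k-window when L >= (m+1)k + m
effective_k <- function(k, max_mm, min_len) {
  k_eff <- min(k, floor((min_len - max_mm) / (max_mm + 1)))
  max(8L, as.integer(k_eff))
}

#' Map reads to an indexed reference set
#'
#' Ungapped end-to-end alignment reporting every placement with at most
#' `max_mismatches` mismatches on either strand. Seed-and-verify is used
#' where the pigeonhole guarantee holds (the effective seed length is
#' lowered automatically for short read sets); reads below the guarantee or
#' containing N are scanned exhaustively, so the hit set always equals a
#' brute-force scan. Reads shorter than the configured seed length `k` are
#' flagged unmapped with a reason.
#'
#' A read is `unique` when exactly one hit attains its minimum mismatch
#' count, `multi` when several do, `unmapped` when it has no hit. Hits are
#' sorted by mismatches, then reference id, then position, and truncated at
#' `max_hits_reported` (uniqueness is classified before truncation).
#'
#' @param reads A reads tibble (or character vector of sequences).
#' @param index A [build_index()] object.
#' @param p [map_params()]; defaults to the index's parameters.
#' @return A `mapped_reads` tibble with one row per retained hit (columns
#'   `read_id`, `bases`, `qual`, `ref_id`, `start`, `strand`, `mismatches`,
#'   `hit_rank`, `n_hits`, `best_mm`, `n_best`, `uniqueness`, `truncated`,
#'   `reason`) and one all-`NA` hit row per unmapped read.
#' @export
map_reads <- function(reads, index, p = NULL) {
  stopifnot(inherits(index, "kmer_index"))
  p <- p %||% index$params
  reads <- as_reads(reads)
  lens <- nchar(reads$bases)
  short <- lens < p$k
  mappable <- which(!short)
  hits <- NULL
  if (length(mappable) > 0) {
    k_eff <- effective_k(p$k, p$max_mismatches, min(lens[mappable]))
    ref_rank <- rank(names(index$refs), ties.method = "first") - 1L
    res <- cpp_map_reads(unname(index$refs), reads$bases[mappable], k_eff,
                         p$max_mismatches, p$max_hits_reported,
                         as.integer(ref_rank))
    idx <- mappable[res$read]
    hits <- tibble(
      read_id = reads$read_id[idx],
      bases = reads$bases[idx],
      qual = reads$qual[idx],
      ref_id = names(index$refs)[res$ref],
      start = res$pos,
      strand = c("+", "-")[res$strand + 1L],
      mismatches = res$mm)
    hits <- hits |>
      group_by(.data$read_id) |>
      mutate(hit_rank = dplyr::row_number()) |>
      ungroup()
    per_read <- tibble(read_id = reads$read_id[mappable],
                       n_hits = res$n_hits, best_mm = res$best_mm,
                       n_best = res$n_best, truncated = res$truncated)
    hits <- left_join(hits, per_read, by = "read_id")
    hits$uniqueness <- ifelse(hits$n_best == 1L, "unique", "multi")
    hits$reason <- NA_character_
    no_hit <- mappable[res$n_hits == 0L]
    if (nrow(hits) == 0) hits <- NULL
  } else {
    no_hit <- integer(0)
  }
  unmapped_idx <- c(which(short), no_hit)
  unmapped <- NULL
  if (length(unmapped_idx) > 0) {
    unmapped <- tibble(
      read_id = reads$read_id[unmapped_idx],
      bases = reads$bases[unmapped_idx],
      qual = reads$qual[unmapped_idx],
      ref_id = NA_character_, start = NA_integer_, strand = NA_character_,
      mismatches = NA_integer_, hit_rank = NA_integer_, n_hits = 0L,
      best_mm = NA_integer_, n_best = 0L, uniqueness = "unmapped",
      truncated = FALSE,
      reason = c(rep(sprintf("read shorter than seed length k=%d", p$k),
                     sum(short)),
                 rep("no placement within mismatch limit", length(no_hit))))
  }
  out <- bind_rows(hits, unmapped)
  attr(out, "params") <- p
  attr(out, "ref_lengths") <- nchar(index$refs)
  class(out) <- c("mapped_reads", class(out))
  out
}

#' Competitively filter reads against a decoy reference
#'
#' Keeps reads whose best mismatch count on the target is strictly lower
#' than on the decoy, or that map only to the target; ties (equal best
#' scores) and target-unmapped reads are discarded. This mirrors mapping a
#' sample against a genome build with the locus removed to ensure
#' locus-specificity of the retained reads.
#'
#' @param reads A reads tibble.
#' @param target_index,decoy_index [build_index()] objects built with the
#'   same parameters.
#' @param p [map_params()]; defaults to the target index's parameters.
#' @return The subset of `reads` surviving the filter.
#' @export
competitive_filter <- function(reads, target_index, decoy_index, p = NULL) {
  p <- p %||% target_index$params
  if (!identical(unclass(target_index$params), unclass(decoy_index$params))) {
    abort("target and decoy index parameters differ")
  }
  reads <- as_reads(reads)
  best_of <- function(index) {
    m <- map_reads(reads, index, p)
    s <- m[!is.na(m$ref_id) & m$hit_rank == 1L, c("read_id", "best_mm")]
    setNames(s$best_mm, s$read_id)[reads$read_id]
  }
  bt <- best_of(target_index)
  bd <- best_of(decoy_index)
  keep <- !is.na(bt) & (is.na(bd) | bt < bd)
  reads[keep, , drop = FALSE]
}
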