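# independent brute-force oracles and shared fixture builders
# (all pure R; deliberately not sharing code paths with the package mapper)

# every ungapped placement of `read` on `refs` with <= max_mm mismatches,
# found by scanning each position of each strand with raw-vector comparison
brute_hits <- function(refs, read, max_mm = 2L) {
  out <- list()
  for (id in names(refs)) {
    rc <- as.integer(charToRaw(refs[[id]]))
    for (strand in c("+", "-")) {
      rd <- if (strand == "+") read else revcomp(read)
      rdc <- as.integer(charToRaw(rd))
      L <- length(rdc)
      n <- length(rc)
      if (L > n) next
      starts <- 0:(n - L)
      win <- matrix(rc[outer(starts, seq_len(L) - 1L, `+`) + 1L],
                    nrow = length(starts))
      mm <- rowSums(win != rep(rdc, each = length(starts)))
      hit <- which(mm <= max_mm)
      if (length(hit) > 0) {
        out[[length(out) + 1L]] <- data.frame(
          ref_id = id, start = starts[hit], strand = strand,
          mismatches = mm[hit], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(ref_id = character(), start = integer(),
                      strand = character(), mismatches = integer()))
  }
  res <- do.call(rbind, out)
  res[order(res$mismatches, res$ref_id, res$start, res$strand), ,
      drop = FALSE]
}

# number of times `w` occurs as an exact substring of `ref` on either strand
occurrences_both_strands <- function(ref, w) {
  cnt <- function(s, pat) {
    m <- gregexpr(pat, s, fixed = TRUE)[[1]]
    if (m[1] == -1) 0L else length(m)
  }
  # fixed = TRUE cannot find overlapping matches; use lookahead instead
  cnt2 <- function(s, pat) {
    m <- gregexpr(paste0("(?=", pat, ")"), s, perl = TRUE)[[1]]
    if (m[1] == -1) 0L else length(m)
  }
  cnt2(ref, w) + cnt2(ref, revcomp(w))
}

# positions (0-based) of `ref` covered by at least one uniquely mappable
# window of length L — the brute-force mappability oracle
unique_mappable_positions <- function(ref, L) {
  n <- nchar(ref)
  starts <- 0:(n - L)
  wins <- substring(ref, starts + 1L, starts + L)
  uniq <- vapply(wins, function(w) occurrences_both_strands(ref, w) == 1L,
                 logical(1))
  sort(unique(unlist(lapply(starts[uniq], function(s) s:(s + L - 1L)))))
}

# standard synthetic study locus: 2 duplicated blocks, 8 genes in 4 groups,
# an allelic second haplotype, and optionally one deleted gene
make_study_locus <- function(seed, block_len = 20000, n_genes = 4,
                             divergence = 0.01, n_snps = 500,
                             delete = TRUE) {
  blk <- generate_block(block_len, n_genes, paste0("g", seq_len(n_genes)),
                        seed = seed)
  h1 <- build_haplotype(blk, 2, divergence, seed = seed + 1000L)
  h2 <- inject_allelic_snps(h1, n_snps, seed = seed + 2000L)
  del <- if (delete) {
    withr::with_seed(seed + 3000L, sample(h1$genes$gene_id, 1))
  } else NULL
  list(h1 = h1, h2 = h2, deleted = del,
       h1d = if (delete) delete_gene(h1, del) else h1,
       h2d = if (delete) delete_gene(h2, del) else h2)
}

# diploid-like ancient read sample from the two allelic haplotypes
sample_diploid_reads <- function(hap_a, hap_b, depth, seed,
                                 error_rate = 0.005) {
  n <- n_reads_for_depth(nchar(hap_a$sequence), depth)
  reads <- dplyr::bind_rows(
    sample_ancient_reads(hap_a, sim_params(n_ancient_reads = ceiling(n / 2),
                                           ancient_error_rate = error_rate,
                                           seed = seed)),
    sample_ancient_reads(hap_b, sim_params(n_ancient_reads = floor(n / 2),
                                           ancient_error_rate = error_rate,
                                           seed = seed + 1L)))
  reads$read_id <- sprintf("r%07d", seq_len(nrow(reads)))
  reads
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}
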