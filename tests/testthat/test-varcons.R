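test_that("pileup tallies match a direct per-position recount", {
  ref <- withr::with_seed(201, random_dna(300))
  idx <- build_index(c(r = ref))
  # ten identical error-free reads over one site count only the ref base
  ten <- tibble::tibble(read_id = sprintf("t%d", 1:10),
                        bases = substr(ref, 101, 140),
                        qual = strrep("?", 40))
  m <- map_reads(ten, idx)
  pil <- pileup(m, ref)
  col <- pil[pil$pos == 120, ]
  expect_equal(col$depth, 10L)
  expect_equal(col[[col$ref]], 10L)
  # empty mapping: empty pileup
  m0 <- map_reads(c(x = random_dna(40)), idx)
  expect_equal(nrow(pileup(m0, ref)), 0)
  # random reads with errors: recount every covered column independently
  reads <- sample_ancient_reads(ref, sim_params(n_ancient_reads = 40,
                                                ancient_error_rate = 0.02,
                                                seed = 7))
  mm <- map_reads(reads, idx)
  pil <- pileup(mm, ref)
  best <- mm[!is.na(mm$ref_id) & mm$uniqueness == "unique" &
               mm$mismatches == mm$best_mm, ]
  tallies <- list()
  for (i in seq_len(nrow(best))) {
    b <- if (best$strand[i] == "-") revcomp(best$bases[i]) else best$bases[i]
    ch <- strsplit(b, "")[[1]]
    for (j in seq_along(ch)) {
      key <- as.character(best$start[i] + j - 1)
      tallies[[key]] <- c(tallies[[key]], ch[j])
    }
  }
  for (k in sample(names(tallies), 30)) {
    col <- pil[pil$pos == as.integer(k), ]
    expect_equal(col$depth, length(tallies[[k]]))
    for (base in c("A", "C", "G", "T")) {
      expect_equal(col[[base]], sum(tallies[[k]] == base))
    }
  }
})

test_that("the variant caller applies the exact frequency and depth cutoffs", {
  mk_col <- function(depth, alt, ref = "A", altb = "C") {
    counts <- setNames(c(0L, 0L, 0L, 0L), c("A", "C", "G", "T"))
    counts[ref] <- depth - alt
    counts[altb] <- alt
    tibble::tibble(pos = 0L, ref = ref, A = counts["A"], C = counts["C"],
                   G = counts["G"], T = counts["T"], depth = depth)
  }
  expect_equal(nrow(call_snps(mk_col(6L, 4L))), 1) # 66.7% at depth 6
  expect_equal(nrow(call_snps(mk_col(6L, 3L))), 0) # 50.0% < 50.01%
  expect_equal(nrow(call_snps(mk_col(5L, 5L))), 0) # depth not > 5
  # a two-way tie among non-reference bases is never called
  tie <- tibble::tibble(pos = 0L, ref = "A", A = 0L, C = 5L, G = 5L, T = 0L,
                        depth = 10L)
  expect_equal(nrow(call_snps(tie)), 0)
  # exhaustive grid: called iff freq >= 0.5001 and depth > 5
  for (d in 1:30) {
    for (alt in 0:d) {
      got <- nrow(call_snps(mk_col(d, alt))) == 1
      want <- d > 5 && alt / d >= 0.5001
      expect_identical(got, want)
    }
  }
})

test_that("cross-source conflicts are masked by the depth rule", {
  mk <- function(pos, base, depth) {
    out <- tibble::tibble(pos = pos, ref = "A", A = 0L, C = 0L, G = 0L,
                          T = 0L, depth = depth)
    for (i in seq_along(pos)) out[[base[i]]][i] <- depth[i]
    out
  }
  a <- mk(c(0L, 1L, 2L), c("A", "A", "G"), c(7L, 20L, 700L))
  b <- mk(c(0L, 1L, 2L), c("G", "A", "T"), c(600L, 600L, 499L))
  masked <- cross_source_filter(a, b)
  # pos 0: conflict, source a below 8x -> masked; pos 1: agreement;
  # pos 2: conflict, source b below 500x -> masked
  expect_equal(masked$position, c(0L, 2L))
  expect_equal(masked$weak_source, c("a", "b"))
  # random property: the mask equals direct rule evaluation
  set.seed(202)
  for (case in 1:50) {
    n <- 20
    basea <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    baseb <- ifelse(runif(n) < 0.5, basea,
                    sample(c("A", "C", "G", "T"), n, replace = TRUE))
    da <- sample(c(1:20, 500:800), n, replace = TRUE)
    db <- sample(c(1:20, 400:800), n, replace = TRUE)
    a <- mk(0:(n - 1), basea, da)
    b <- mk(0:(n - 1), baseb, db)
    want <- which(basea != baseb & (da < 8 | db < 500)) - 1L
    expect_equal(cross_source_filter(a, b)$position, want)
  }
})

test_that("majority consensus honours the 51% rule and tie policy", {
  ref <- "ACGT"
  col <- tibble::tibble(pos = 1L, ref = "C", A = 51L, C = 49L, G = 0L,
                        T = 0L, depth = 100L)
  expect_equal(majority_consensus(col, ref), "AAGT")
  col5050 <- tibble::tibble(pos = 1L, ref = "C", A = 50L, C = 50L, G = 0L,
                            T = 0L, depth = 100L)
  expect_equal(majority_consensus(col5050, ref), "ACGT") # reference policy
  expect_equal(majority_consensus(col5050, ref,
                                  consensus_params(tie_policy = "first-alphabetical")),
               "AAGT")
  # masked positions revert to the reference
  expect_equal(majority_consensus(col, ref, mask = 1L), "ACGT")
  expect_false(grepl("[^ACGT]", majority_consensus(col, ref)))
})

test_that("consensus of error-free tiles reproduces any haplotype exactly", {
  blk <- generate_block(4000, 2, c("g1", "g2"), seed = 203)
  h <- build_haplotype(blk, 1, 0, seed = 203)
  idx <- build_index(h)
  m <- map_reads(tile_reads(h, sim_params()), idx)
  cons <- majority_consensus(pileup(m, h), h)
  expect_identical(cons, h$sequence)
  # idempotence: tiling the consensus and re-calling returns it unchanged
  idx2 <- build_index(c(cons = cons))
  m2 <- map_reads(tile_reads(cons, sim_params()), idx2)
  expect_identical(majority_consensus(pileup(m2, c(cons = cons)),
                                      c(cons = cons)), cons)
})

test_that("coding effects are classified through the strand-aware CDS", {
  # plus-strand gene: CDS = ATG TTT TAC TAA written at positions 10..21
  seqc <- paste0(withr::with_seed(204, random_dna(10)), "ATGTTTTACTAA",
                 withr::with_seed(205, random_dna(10)))
  genes <- tibble::tibble(gene_id = "g", group = "g", strand = "+",
                          status = "functional",
                          exon_start = list(10L), exon_end = list(22L))
  v <- tibble::tibble(position = c(15L, 13L, 18L, 2L),
                      ref = substring(seqc, c(16, 14, 19, 3),
                                      c(16, 14, 19, 3)),
                      alt = c("C", "G", "A", "A"),
                      freq = 1, depth = 10L, effect = NA_character_)
  # TTT->TTC synonymous; TTT->GTT nonsynonymous; TAC->TAA nonsense
  out <- annotate_effects(v, genes, seqc)
  expect_equal(out$effect,
               c("synonymous", "nonsynonymous", "nonsense",
                 "intergenic/intronic"))
  # the same gene on the minus strand (reverse-complement the payload)
  seqm <- paste0(withr::with_seed(206, random_dna(10)),
                 revcomp("ATGTTTTACTAA"),
                 withr::with_seed(207, random_dna(10)))
  genesm <- tibble::tibble(gene_id = "g", group = "g", strand = "-",
                           status = "functional",
                           exon_start = list(10L), exon_end = list(22L))
  # genomic position of CDS position 5 (third base of codon TTT) is
  # 10 + (12 - 1 - 5) = 16; alt G on the genome is C on the CDS -> TTC
  vm <- tibble::tibble(position = 16L, ref = substring(seqm, 17, 17),
                       alt = "G", freq = 1, depth = 10L,
                       effect = NA_character_)
  expect_equal(annotate_effects(vm, genesm, seqm)$effect, "synonymous")
  # CDS not divisible by 3: warning, effect omitted
  genes_bad <- genes
  genes_bad$exon_end <- list(21L)
  expect_warning(out <- annotate_effects(v, genes_bad, seqc), "multiple of 3")
  expect_true(is.na(out$effect[1]))
})
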