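test_that("dot-plot identity recovers self-similarity and duplications", {
  s <- withr::with_seed(401, random_dna(2000))
  m <- dotplot_identity(s, s, window = 250, step = 250)
  expect_true(all(diag(m) == 100))
  expect_equal(m, t(m), ignore_attr = TRUE)
  # unrelated random sequences sit near the 25% background expectation
  s2 <- withr::with_seed(402, random_dna(2000))
  m2 <- dotplot_identity(s, s2, window = 250, step = 250)
  expect_lt(abs(mean(m2) - 25), 1.5)
  # a duplicated-block haplotype shows a 100% off-diagonal at the offset
  blk <- generate_block(4000, 2, c("g1", "g2"), seed = 403)
  h <- build_haplotype(blk, 2, 0, seed = 403)
  mh <- dotplot_identity(h, h, window = 250, step = 250)
  off <- mh[cbind(seq_len(nrow(mh) - 16), seq_len(nrow(mh) - 16) + 16)]
  expect_true(all(off == 100)) # 4000 / 250 = 16 windows of offset
  expect_error(dotplot_identity("ACGT", s, window = 250), "window")
})

test_that("window identity tracks equal direct recomputation", {
  a <- withr::with_seed(404, random_dna(3000))
  expect_true(all(window_identity_track(a, a, window = 500)$identity == 100))
  # ten substitutions clustered inside one window: local minimum 98.0
  ch <- strsplit(a, "")[[1]]
  for (j in 1000:1009) ch[j] <- setdiff(c("A", "C", "G", "T"), ch[j])[1]
  b <- paste(ch, collapse = "")
  tr <- window_identity_track(a, b, window = 500)
  expect_equal(min(tr$identity), 98.0)
  expect_equal(nrow(tr), 3000 - 500 + 1)
  # random pair: every window equals its brute-force identity
  b2 <- withr::with_seed(405, random_dna(3000))
  tr2 <- window_identity_track(a, b2, window = 500, step = 97)
  brute <- vapply(tr2$start, function(s0) {
    100 * mean(strsplit(substring(a, s0 + 1, s0 + 500), "")[[1]] ==
                 strsplit(substring(b2, s0 + 1, s0 + 500), "")[[1]])
  }, numeric(1))
  expect_equal(tr2$identity, brute)
  expect_error(window_identity_track(a, "ACGT"), "length")
})

test_that("substitution counting respects masks and gap handling", {
  expect_equal(as.integer(count_substitutions("ACGT", "ACGA")), 1L)
  expect_equal(as.integer(count_substitutions("ACGT", "ACGT",
                                              mask = tibble::tibble(start = 0L,
                                                                    end = 4L))),
               0L)
  g <- count_substitutions("AC-TA", "ACG-A")
  expect_equal(as.integer(g), 0L)
  expect_equal(attr(g, "gap_sites"), 2L)
  expect_equal(attr(g, "sites_compared"), 3L)
  # the generator's injected SNP count is recovered exactly
  blk <- generate_block(6000, 2, c("g1", "g2"), seed = 406)
  h1 <- build_haplotype(blk, 1, 0, seed = 406)
  h2 <- inject_allelic_snps(h1, 137, seed = 407)
  expect_equal(as.integer(count_substitutions(h1$sequence, h2$sequence)),
               137L)
  # exon-restricted counts can never exceed the unrestricted count
  masked <- count_substitutions(h1$sequence, h2$sequence,
                                mask = exon_mask(h1$genes))
  expect_lte(as.integer(masked), 137L)
  expect_error(count_substitutions("ACGT", "ACG"), "length")
})

test_that("NS/S counting classifies sites and conserves totals", {
  expect_equal(ns_s_counts("TTT", "TTC")[, c("ns", "s")],
               tibble::tibble(ns = 0L, s = 1L), ignore_attr = TRUE)
  expect_equal(ns_s_counts("TTT", "GTT")[, c("ns", "s")],
               tibble::tibble(ns = 1L, s = 0L), ignore_attr = TRUE)
  # two hits in one codon are flagged, and ns + s + multi_hit = sites
  out <- ns_s_counts("TTTAAA", "TTCGCA")
  expect_equal(out$multi_hit, 2L)
  expect_equal(out$s, 1L) # the single-hit TTT -> TTC
  expect_equal(out$ns + out$s + out$multi_hit, out$sites)
  # a labelled partition conserves the whole-CDS totals
  a <- withr::with_seed(408, paste(
    sample(setdiff(paralocus:::NON_STOP_CODONS, "ATG"), 40, replace = TRUE),
    collapse = ""))
  ch <- strsplit(a, "")[[1]]
  at <- withr::with_seed(409, sample(120, 10))
  for (j in at) ch[j] <- sample(setdiff(c("A", "C", "G", "T"), ch[j]), 1)
  b <- paste(ch, collapse = "")
  whole <- ns_s_counts(a, b)
  parts <- ns_s_counts(a, b, regions = tibble::tibble(
    region = c("Ig", "tail"), start_codon = c(0L, 25L), end_codon = c(25L, 40L)))
  expect_equal(sum(parts$ns), whole$ns)
  expect_equal(sum(parts$s), whole$s)
  expect_equal(sum(parts$multi_hit), whole$multi_hit)
  expect_equal(sum(parts$sites), whole$sites)
  expect_error(ns_s_counts("TTTA", "TTCA"), "divisible")
})

test_that("p-distances match an independent implementation", {
  expect_equal(p_distance_matrix(c(a = "AAAA", b = "AAAT"))["a", "b"], 0.25)
  expect_equal(p_distance_matrix(c(a = "AAAA", b = "AAAA"))["a", "b"], 0)
  set.seed(410)
  seqs <- character(5)
  base <- random_dna(300)
  for (i in 1:5) {
    ch <- strsplit(base, "")[[1]]
    at <- sample(300, 25)
    for (j in at) ch[j] <- sample(c("A", "C", "G", "T"), 1)
    if (i > 3) ch[sample(300, 5)] <- "-" # some gap columns
    seqs[i] <- paste(ch, collapse = "")
  }
  names(seqs) <- paste0("s", 1:5)
  d <- p_distance_matrix(seqs)
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  skip_if_not_installed("ape")
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(seqs), "")))
  ref <- as.matrix(ape::dist.dna(bin, model = "raw",
                                 pairwise.deletion = TRUE))
  expect_equal(d, ref[rownames(d), colnames(d)], tolerance = 1e-12)
  expect_error(p_distance_matrix(c(a = "ACGT")), "two sequences")
})

test_that("ITIM scanning reports canonical and tyrosine-disrupted motifs", {
  hit <- scan_itims("VTYAQL")
  expect_equal(hit$motif_class, "ITIM_canonical")
  expect_equal(hit$start, 0L)
  hit2 <- scan_itims("VTFAQL")
  expect_equal(hit2$motif_class, "ITIM_disrupted_YtoF")
  expect_equal(nrow(scan_itims("VTYAQ")), 0) # too short
  expect_error(scan_itims("VTX1QL"), "non-amino-acid")
  # overlapping and mixed matches are all reported in residue order
  both <- scan_itims("AVTYAQLKKVSFESLA")
  expect_equal(both$motif_class,
               c("ITIM_canonical", "ITIM_disrupted_YtoF"))
  expect_equal(both$start, c(1L, 9L))
})

test_that("transmembrane adaptor classification follows the charge rule", {
  expect_equal(classify_tm_adaptor("LLVVAGLVILA", flank = "SSRH"),
               "Fc_gamma_type")
  expect_equal(classify_tm_adaptor("LLVKAGLVILA", flank = "SSHH"), "DAP_type")
  expect_equal(classify_tm_adaptor("LLVVAGLVILA", flank = "SSHH"), "none")
  expect_warning(both <- classify_tm_adaptor("LLVKAGL", flank = "RR"), "both")
  expect_setequal(both, c("Fc_gamma_type", "DAP_type"))
  expect_error(classify_tm_adaptor(""), "empty")
})

test_that("ORF integrity locates every class of reading-frame defect", {
  # generator genes are intact by construction
  blk <- generate_block(6000, 2, c("g1", "g2"), seed = 411)
  h <- build_haplotype(blk, 1, 0, seed = 411)
  orf <- orf_integrity_table(h)
  expect_true(all(orf$status == "functional"))
  # hand-built gene: ATG AAA TAA
  seqc <- paste0("ATGAAATAA", withr::with_seed(412, random_dna(20)))
  gene <- tibble::tibble(gene_id = "g", group = "g", strand = "+",
                         status = "functional",
                         exon_start = list(0L), exon_end = list(9L))
  expect_equal(orf_integrity(gene, seqc)$status, "functional")
  # internal stop: AAA -> TAA
  seq_stop <- paste0("ATGTAATAA", substring(seqc, 10))
  v <- orf_integrity(gene, seq_stop)
  expect_equal(v$status, "pseudogene")
  expect_equal(v$defects[[1]]$defect, "premature_stop")
  expect_equal(v$defects[[1]]$position, 1L)
  # 1-bp exon shrink: frameshift
  gene_fs <- gene
  gene_fs$exon_end <- list(8L)
  vf <- orf_integrity(gene_fs, seqc)
  expect_equal(vf$status, "pseudogene")
  expect_true("frameshift" %in% vf$defects[[1]]$defect)
  # lost start / lost stop
  gene_shift <- gene
  gene_shift$exon_start <- list(3L)
  gene_shift$exon_end <- list(12L)
  vs <- orf_integrity(gene_shift, seqc)
  expect_true("lost_start" %in% vs$defects[[1]]$defect)
})

test_that("allelic haplotype comparison recovers the generated divergence", {
  blk <- generate_block(8000, 2, c("g1", "g2"), seed = 413)
  h1 <- build_haplotype(blk, 2, 0, seed = 413)
  h2 <- inject_allelic_snps(h1, 400, seed = 414)
  cmp <- validate_haplotype_pair(h1, h2)
  expect_equal(cmp$snps_total, 400L)
  # the blocks partition the haplotype, so block counts sum to the total
  expect_equal(sum(cmp$blocks$substitutions), 400L)
  expect_true(all(cmp$blocks$exon_snps <= cmp$blocks$substitutions))
  expect_equal(cmp$functional$n_genes, c(4L, 4L))
  expect_equal(cmp$functional$hap_id[1], "H1")
  expect_true(all(cmp$functional$n_functional[1] == 4L))
})
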