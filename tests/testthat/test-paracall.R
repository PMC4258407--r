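test_that("group-exclusive filtering keeps only single-group reads", {
  set.seed(301)
  g1a <- random_dna(600)
  g1b <- random_dna(600)
  g2a <- random_dna(600)
  shared <- random_dna(120)
  gene_refs <- tibble::tibble(
    member = c("x1", "x2", "y1"),
    gene_id = c("x1", "x2", "y1"),
    group = c("g1", "g1", "g2"),
    sequence = c(g1a, paste0(g1b, shared), paste0(g2a, shared)))
  reads <- c(from_g1 = substr(g1a, 101, 140),
             from_g2 = substr(g2a, 101, 140),
             both_groups = substr(shared, 11, 50),
             nowhere = random_dna(40))
  k1 <- group_exclusive_reads(reads, gene_refs, "g1")
  expect_equal(k1$read_id, "from_g1")
  k2 <- group_exclusive_reads(reads, gene_refs, "g2")
  expect_equal(k2$read_id, "from_g2")
  expect_error(group_exclusive_reads(reads, gene_refs, "g9"), "unknown group")
  # property: kept set equals brute-force cross-group hit tabulation
  for (case in 1:20) {
    r <- if (runif(1) < 0.7) {
      src <- sample(3, 1)
      s <- sample(nchar(gene_refs$sequence[src]) - 39, 1)
      substring(gene_refs$sequence[src], s, s + 39)
    } else random_dna(40)
    hits_per_group <- vapply(c("g1", "g2"), function(gr) {
      any(vapply(which(gene_refs$group == gr), function(i) {
        nrow(brute_hits(setNames(gene_refs$sequence[i], "m"), r, 2L)) > 0
      }, logical(1)))
    }, logical(1))
    got <- nrow(group_exclusive_reads(c(x = r), gene_refs, "g1")) == 1
    expect_equal(got, hits_per_group[["g1"]] && !hits_per_group[["g2"]])
  }
})

test_that("diagnostic positions equal a brute-force column scan", {
  a <- "ACGTACGTAC"
  b <- "ACCTACGAAC" # differs at columns 2 and 7
  d <- diagnostic_positions(c(m1 = a, m2 = b))
  expect_equal(sort(unique(d$column)), c(2L, 7L))
  expect_true(all(d$discriminates)) # two members: every variable column
  expect_equal(nrow(diagnostic_positions(c(m1 = a, m2 = a))), 0)
  expect_error(diagnostic_positions(c(m1 = a, m2 = "ACG")), "unequal")
  expect_error(diagnostic_positions(c(m1 = a)), "at least two")
  # three members: a column separating only one of them
  d3 <- diagnostic_positions(c(m1 = "AAAA", m2 = "AACA", m3 = "AACA"))
  expect_equal(unique(d3$column), 2L)
  expect_equal(d3$discriminates, c(TRUE, FALSE, FALSE))
  # random property against an independent column scan
  set.seed(302)
  for (case in 1:20) {
    n <- 50
    m1 <- random_dna(n)
    ch <- strsplit(m1, "")[[1]]
    at <- sample(n, 5)
    for (j in at) ch[j] <- sample(setdiff(c("A", "C", "G", "T"), ch[j]), 1)
    m2 <- paste(ch, collapse = "")
    d <- diagnostic_positions(c(a = m1, b = m2))
    want <- which(strsplit(m1, "")[[1]] != strsplit(m2, "")[[1]]) - 1L
    expect_equal(sort(unique(d$column)), want)
  }
})

test_that("consistency counts partition defining sites correctly", {
  set.seed(303)
  x <- random_dna(800)
  ch <- strsplit(x, "")[[1]]
  at <- sort(sample(100:700, 12))
  for (j in at) ch[j] <- sample(setdiff(c("A", "C", "G", "T"), ch[j]), 1)
  y <- paste(ch, collapse = "")
  diags <- diagnostic_positions(c(X = x, Y = y))
  p <- map_params()
  # reads simulated from X only: every covered defining site is consistent
  rx <- sample_ancient_reads(x, sim_params(n_ancient_reads = 400,
                                           ancient_error_rate = 0, seed = 1))
  mx <- map_reads(rx, build_index(c(X = x), p))
  rep_x <- consistency_counts(pileup(mx, c(X = x)), diags, "X", min_depth = 3)
  expect_equal(rep_x$n_inconsistent, 0)
  expect_gt(rep_x$n_consistent, 0)
  expect_equal(rep_x$n_consistent + rep_x$n_inconsistent + rep_x$n_uncovered,
               rep_x$n_diagnostic)
  # reads simulated from paralog Y evaluated against X: the sites where
  # X != Y read as inconsistent
  ry <- sample_ancient_reads(y, sim_params(n_ancient_reads = 400,
                                           ancient_error_rate = 0, seed = 2))
  my <- map_reads(ry, build_index(c(X = x), p))
  rep_y <- consistency_counts(pileup(my, c(X = x)), diags, "X", min_depth = 3)
  expect_equal(rep_y$n_consistent, 0)
  expect_gt(rep_y$n_inconsistent, 0)
  expect_equal(rep_y$n_consistent + rep_y$n_inconsistent + rep_y$n_uncovered,
               rep_y$n_diagnostic)
})

test_that("presence calls fire the documented branches", {
  rep_good <- tibble::tibble(gene_id = "g", n_diagnostic = 10L,
                             n_consistent = 8L, n_inconsistent = 1L,
                             n_uncovered = 1L)
  rep_bad <- tibble::tibble(gene_id = "g", n_diagnostic = 10L,
                            n_consistent = 0L, n_inconsistent = 0L,
                            n_uncovered = 10L)
  # SNP branch alone suffices, even with zero control coverage
  c1 <- call_presence("g", 0, 0, rep_good)
  expect_equal(c1$status, "present")
  expect_match(c1$rationale, "SNP branch")
  # coverage branch
  c2 <- call_presence("g", 60, 80, rep_bad)
  expect_equal(c2$status, "present")
  expect_match(c2$rationale, "coverage branch")
  # absence: no unique coverage where the control predicts it, no SNPs
  c3 <- call_presence("g", 0.5, 80, rep_bad)
  expect_equal(c3$status, "absent")
  # absence is never declared on inadequate depth
  c4 <- call_presence("g", 0.5, 80, rep_bad, adequate_depth = FALSE)
  expect_equal(c4$status, "indeterminate")
  # fully duplicated gene (control below the floor) is indeterminate unless
  # the SNP branch decides
  c5 <- call_presence("g", 0, 0.5, rep_bad)
  expect_equal(c5$status, "indeterminate")
  expect_match(c5$rationale, "floor")
})

test_that("ground truth is recovered across random synthetic loci", {
  # 20 random loci: 2-3 blocks of 2-3 genes, 0-2 gene deletions, ancient
  # reads at depth 15 with error <= 1%; every gene with informative control
  # coverage (>= 5%) or >= 3 defining SNPs must be called correctly
  n_loci <- 20
  failures <- character(0)
  for (s in seq_len(n_loci)) {
    cfg <- withr::with_seed(4000 + s, list(
      n_copies = sample(2:3, 1),
      n_genes = sample(2:3, 1),
      err = runif(1, 0, 0.01),
      n_del = sample(0:2, 1)))
    blk <- generate_block(cfg$n_genes * 2500, cfg$n_genes,
                          paste0("g", seq_len(cfg$n_genes)), seed = s)
    h1 <- build_haplotype(blk, cfg$n_copies, 0.01, seed = s + 50)
    h2 <- inject_allelic_snps(h1, round(nchar(h1$sequence) * 0.012),
                              seed = s + 100)
    deleted <- withr::with_seed(s + 150,
                                sample(h1$genes$gene_id,
                                       min(cfg$n_del, nrow(h1$genes) - 1)))
    h1d <- h1
    h2d <- h2
    for (g in deleted) {
      h1d <- delete_gene(h1d, g)
      h2d <- delete_gene(h2d, g)
    }
    reads <- sample_diploid_reads(h1d, h2d, depth = 15, seed = s + 200,
                                  error_rate = cfg$err)
    run <- infer_presence(h1, reads, allelic = h2)
    calls <- tidy(run)
    informative <- calls$control_cov_pct >= 5 | calls$n_diag >= 3
    truth <- ifelse(calls$gene_id %in% deleted, "absent", "present")
    wrong <- informative & calls$status != truth
    if (any(wrong)) {
      failures <- c(failures,
                    sprintf("locus %d: %s called %s (truth %s)", s,
                            calls$gene_id[wrong], calls$status[wrong],
                            truth[wrong]))
    }
  }
  expect_equal(failures, character(0))
})

test_that("more depth never flips a correct call to an incorrect one", {
  loc <- make_study_locus(7, block_len = 10000, n_genes = 2, n_snps = 250)
  correct <- function(depth) {
    reads <- sample_diploid_reads(loc$h1d, loc$h2d, depth = depth,
                                  seed = 900 + depth)
    calls <- tidy(infer_presence(loc$h1, reads, allelic = loc$h2))
    truth <- ifelse(calls$gene_id == loc$deleted, "absent", "present")
    calls$status == truth
  }
  c10 <- correct(10)
  c20 <- correct(20)
  c30 <- correct(30)
  expect_false(any(c10 & !c20))
  expect_false(any(c20 & !c30))
})
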