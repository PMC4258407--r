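# duplication-block and diversity analytics: dot-plot and sliding-window
# identity, substitution counting, NS/S partitioning, p-distance, motif
# scanning, ORF integrity

#' Dot-plot percent identity between two sequences
#'
#' Cell `(i, j)` holds the percent of identical bases between the
#' `window`-bp segments of `seq_a` starting at row coordinate `i` and of
#' `seq_b` at column coordinate `j` (ungapped comparison). Symmetric for a
#' self-comparison; duplicated blocks show up as off-diagonal 100% runs.
#'
#' @param seq_a,seq_b Sequences (strings or [haplotype()]s), each at least
#'   `window` bp.
#' @param window Window size in bp (default the published 250).
#' @param step Step between window starts (default `window`).
#' @return A numeric matrix of class `dotplot_identity`; dimnames carry the
#'   0-based window start coordinates.
#' @export
dotplot_identity <- function(seq_a, seq_b,
                             window = window_params()$dotplot_window,
                             step = window) {
  a <- as_sequence(seq_a)
  b <- as_sequence(seq_b)
  if (nchar(a) < window || nchar(b) < window) {
    abort(sprintf("window %d exceeds a sequence length", window))
  }
  sa <- seq(0L, nchar(a) - window, by = step)
  sb <- seq(0L, nchar(b) - window, by = step)
  acode <- str_codes(a)
  bcode <- str_codes(b)
  bwin <- matrix(bcode[outer(sb, seq_len(window), `+`)], nrow = length(sb))
  m <- matrix(NA_real_, length(sa), length(sb),
              dimnames = list(as.character(sa), as.character(sb)))
  for (i in seq_along(sa)) {
    aw <- acode[(sa[i] + 1L):(sa[i] + window)]
    m[i, ] <- 100 * rowMeans(bwin == rep(aw, each = length(sb)))
  }
  attr(m, "window") <- window
  attr(m, "step") <- step
  class(m) <- c("dotplot_identity", class(m))
  m
}

#' Sliding-window identity track between two co-linear blocks
#'
#' Percent identity in windows of `window` bp (step 1) along the reference
#' block's coordinate system. The blocks must have equal (aligned) length;
#' positions where exactly one sequence has a gap score as mismatch, so
#' structural divergence appears as dips in the track.
#'
#' @param reference_block,other_block Equal-length sequences.
#' @param window Window size in bp (default the published 500).
#' @param step Step between window starts (default 1).
#' @return An `identity_track` tibble: `start` (0-based), `end`, `identity`.
#' @export
window_identity_track <- function(reference_block, other_block,
                                  window = window_params()$identity_window,
                                  step = 1L) {
  a <- as_sequence(reference_block)
  b <- as_sequence(other_block)
  if (nchar(a) != nchar(b)) {
    abort("blocks differ in length; supply a pre-aligned pair")
  }
  n <- nchar(a)
  if (window > n) abort(sprintf("window %d exceeds block length %d", window, n))
  mism <- as.integer(str_codes(a) != str_codes(b))
  cs <- cumsum(c(0L, mism))
  starts <- seq(0L, n - window, by = step)
  ident <- 100 * (window - (cs[starts + window + 1L] - cs[starts + 1L])) / window
  out <- tibble(start = starts, end = starts + window, identity = ident)
  attr(out, "window") <- window
  class(out) <- c("identity_track", class(out))
  out
}

# parse a mask given as tibble/data.frame(start, end) or 2-column matrix of
# 0-based half-open intervals into a logical position selector of length n
mask_selector <- function(mask, n) {
  if (is.null(mask)) return(rep(TRUE, n))
  if (is.matrix(mask)) mask <- tibble(start = mask[, 1], end = mask[, 2])
  stopifnot(all(c("start", "end") %in% names(mask)))
  if (any(mask$start < 0 | mask$end > n)) abort("mask interval out of bounds")
  sel <- rep(FALSE, n)
  for (i in seq_len(nrow(mask))) {
    if (mask$end[i] > mask$start[i]) sel[(mask$start[i] + 1L):mask$end[i]] <- TRUE
  }
  sel
}

#' Count substitutions between two aligned sequences
#'
#' Number of positions (optionally restricted to mask intervals) where the
#' two sequences carry different bases. Positions where either sequence has
#' a gap (`-`) are excluded from the count and tallied separately in the
#' `gap_sites` attribute; `sites_compared` records the denominator.
#'
#' @param seq_a,seq_b Equal-length (pre-aligned) sequences.
#' @param mask Optional intervals (tibble/matrix with `start`, `end`,
#'   0-based half-open) restricting the comparison, e.g. exon unions.
#' @return An integer count with attributes `gap_sites` and
#'   `sites_compared`.
#' @export
count_substitutions <- function(seq_a, seq_b, mask = NULL) {
  a <- as_sequence(seq_a)
  b <- as_sequence(seq_b)
  if (nchar(a) != nchar(b)) abort("sequences differ in length; align them first")
  n <- nchar(a)
  sel <- mask_selector(mask, n)
  ac <- strsplit(a, "")[[1]][sel]
  bc <- strsplit(b, "")[[1]][sel]
  gap <- ac == "-" | bc == "-"
  out <- sum(ac[!gap] != bc[!gap])
  attr(out, "gap_sites") <- sum(gap)
  attr(out, "sites_compared") <- sum(!gap)
  out
}

#' Exon-union mask of a gene set
#'
#' @param genes A gene-model tibble.
#' @return A tibble of `start`, `end` intervals (0-based half-open) covering
#'   every exon.
#' @export
exon_mask <- function(genes) {
  tibble(start = unlist(genes$exon_start), end = unlist(genes$exon_end))
}

#' Nonsynonymous/synonymous substitution counts between two aligned CDS
#'
#' Each differing nucleotide site is classified by substituting it alone
#' into the codon context of `cds_a` under the standard genetic code
#' (stop gains count as nonsynonymous). Sites in codons carrying more than
#' one difference are set aside in `multi_hit` rather than counted in
#' `ns`/`s`, so `ns + s + multi_hit` equals the total number of differing
#' sites. Counts are reported per labelled codon region when a partition is
#' supplied.
#'
#' @param cds_a,cds_b Aligned in-frame CDS of equal length divisible by 3.
#' @param regions Optional tibble `region`, `start_codon`, `end_codon`
#'   (0-based half-open codon intervals, e.g. Ig domains vs tail).
#' @return A tibble: `region`, `ns`, `s`, `multi_hit`, `sites`.
#' @export
ns_s_counts <- function(cds_a, cds_b, regions = NULL) {
  a <- as_sequence(cds_a)
  b <- as_sequence(cds_b)
  if (nchar(a) != nchar(b)) abort("CDS lengths differ")
  if (nchar(a) %% 3 != 0) abort("CDS length not divisible by 3")
  n_codon <- nchar(a) %/% 3
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  diff_site <- which(ac != bc)
  codon_of <- (diff_site - 1L) %/% 3L
  multi <- codon_of %in% codon_of[duplicated(codon_of)]
  cls <- character(length(diff_site))
  for (i in seq_along(diff_site)) {
    ci <- codon_of[i]
    codon <- paste(ac[(ci * 3L + 1L):(ci * 3L + 3L)], collapse = "")
    new_codon <- codon
    off <- (diff_site[i] - 1L) %% 3L
    substr(new_codon, off + 1L, off + 1L) <- bc[diff_site[i]]
    cls[i] <- if (translate_codons(codon) == translate_codons(new_codon))
      "s" else "ns"
  }
  if (is.null(regions)) {
    regions <- tibble(region = "CDS", start_codon = 0L, end_codon = n_codon)
  }
  rows <- lapply(seq_len(nrow(regions)), function(r) {
    inr <- codon_of >= regions$start_codon[r] & codon_of < regions$end_codon[r]
    tibble(region = regions$region[r],
           ns = sum(inr & !multi & cls == "ns"),
           s = sum(inr & !multi & cls == "s"),
           multi_hit = sum(inr & multi),
           sites = sum(inr))
  })
  bind_rows(rows)
}

#' Pairwise p-distance matrix of aligned sequences
#'
#' p-distance: the proportion of differing sites among compared sites, with
#' pairwise deletion of columns where either sequence of a pair has a gap
#' (`-`) or `N`. Symmetric, zero diagonal; not a metric in general.
#'
#' @param sequences Named character vector of >= 2 aligned sequences.
#' @return A symmetric numeric matrix.
#' @export
p_distance_matrix <- function(sequences) {
  if (length(sequences) < 2) abort("need at least two sequences")
  if (length(unique(nchar(sequences))) != 1) {
    abort("sequences have unequal alignment lengths")
  }
  nm <- names(sequences) %||% sprintf("seq%d", seq_along(sequences))
  mat <- do.call(rbind, strsplit(toupper(sequences), ""))
  k <- nrow(mat)
  d <- matrix(0, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ok <- !(mat[i, ] %in% c("-", "N")) & !(mat[j, ] %in% c("-", "N"))
      d[i, j] <- d[j, i] <-
        if (any(ok)) sum(mat[i, ok] != mat[j, ok]) / sum(ok) else NA_real_
    }
  }
  d
}

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Scan a protein for ITIM motifs
#'
#' Reports every match of the canonical immunoreceptor tyrosine-based
#' inhibitory motif V-x-Y-x-x-L (`ITIM_canonical`) and of its
#' tyrosine-to-phenylalanine disrupted form V-x-F-x-x-L
#' (`ITIM_disrupted_YtoF`), the substitution known to attenuate inhibitory
#' signalling. Overlapping matches are all reported.
#'
#' @param protein Amino-acid string (standard 20-letter alphabet).
#' @return A tibble: `start` (0-based residue), `motif_class`, `match`.
#' @export
scan_itims <- function(protein) {
  protein <- toupper(protein)
  if (grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"), protein)) {
    abort("non-amino-acid symbols in protein sequence")
  }
  scan_one <- function(pat, label) {
    m <- gregexpr(paste0("(?=", pat, ")"), protein, perl = TRUE)[[1]]
    if (m[1] == -1) return(NULL)
    starts <- as.integer(m) - 1L
    tibble(start = starts, motif_class = label,
           match = substring(protein, starts + 1L, starts + 6L))
  }
  out <- bind_rows(scan_one("V.Y..L", "ITIM_canonical"),
                   scan_one("V.F..L", "ITIM_disrupted_YtoF"))
  if (is.null(out) || nrow(out) == 0) {
    return(tibble(start = integer(), motif_class = character(),
                  match = character()))
  }
  arrange(out, .data$start)
}

#' Classify the activating-adaptor potential of a transmembrane region
#'
#' Activating immunoreceptors pair with their signalling adaptor through a
#' charged transmembrane residue: an arginine in the membrane-proximal
#' flank implies Fc-gamma/CD3-zeta-type pairing, a lysine within the
#' transmembrane segment implies DAP10/DAP12-type pairing. When both are
#' present, both classes are returned with a warning.
#'
#' @param tm_segment Amino-acid string of the transmembrane segment
#'   (non-empty).
#' @param flank Amino-acid string of the membrane-proximal flank (may be
#'   empty).
#' @return `"Fc_gamma_type"`, `"DAP_type"`, `"none"`, or both classes.
#' @export
classify_tm_adaptor <- function(tm_segment, flank = "") {
  if (!nzchar(tm_segment)) abort("empty transmembrane segment")
  has_r <- grepl("R", toupper(flank), fixed = TRUE)
  has_k <- grepl("K", toupper(tm_segment), fixed = TRUE)
  if (has_r && has_k) {
    warn("both a membrane-proximal arginine and a transmembrane lysine found")
    return(c("Fc_gamma_type", "DAP_type"))
  }
  if (has_r) return("Fc_gamma_type")
  if (has_k) return("DAP_type")
  "none"
}

#' Open-reading-frame integrity of a gene model
#'
#' Builds the spliced, strand-aware CDS and classifies the gene as
#' `functional` if and only if it starts with ATG, ends with a stop codon,
#' contains no internal stop, and has length divisible by 3. Otherwise the
#' gene is a `pseudogene` and every reading-frame defect is located:
#' `lost_start`, `premature_stop` (0-based codon index), `lost_stop`,
#' `frameshift` (CDS length mod 3).
#'
#' @param gene A one-row gene-model tibble.
#' @param sequence The haplotype sequence (string or [haplotype()]).
#' @return A one-row tibble: `gene_id`, `status`, `n_defects` and
#'   list-column `defects` (tibble `defect`, `position`).
#' @export
orf_integrity <- function(gene, sequence) {
  seqc <- as_sequence(sequence)
  cds <- spliced_cds(gene, seqc)
  defects <- tibble(defect = character(), position = integer())
  L <- nchar(cds)
  if (L %% 3 != 0) {
    defects <- bind_rows(defects,
                         tibble(defect = "frameshift", position = L %% 3L))
    cds <- substr(cds, 1, L - (L %% 3))
    L <- nchar(cds)
  }
  codons <- substring(cds, seq(1, L, by = 3), seq(3, L, by = 3))
  if (length(codons) == 0 || codons[1] != "ATG") {
    defects <- bind_rows(defects, tibble(defect = "lost_start", position = 0L))
  }
  if (length(codons) > 0 && !codons[length(codons)] %in% STOP_CODONS) {
    defects <- bind_rows(defects,
                         tibble(defect = "lost_stop",
                                position = length(codons) - 1L))
  }
  internal <- which(codons[-length(codons)] %in% STOP_CODONS)
  if (length(internal) > 0) {
    defects <- bind_rows(defects,
                         tibble(defect = "premature_stop",
                                position = internal - 1L))
  }
  status <- if (nrow(defects) == 0) "functional" else "pseudogene"
  tibble(gene_id = gene$gene_id[1], status = status,
         n_defects = nrow(defects), defects = list(defects))
}

#' ORF-integrity report for every gene of a haplotype
#'
#' @param h A [haplotype()].
#' @return A tibble with one [orf_integrity()] row per gene.
#' @export
orf_integrity_table <- function(h) {
  stopifnot(inherits(h, "haplotype"))
  bind_rows(lapply(seq_len(nrow(h$genes)), function(i) {
    orf_integrity(h$genes[i, ], h$sequence)
  }))
}

#' Compare two allelic haplotype assemblies
#'
#' Given two haplotypes with identical gene organisation on shared
#' coordinates (e.g. two finished assemblies of the same locus, or a
#' synthetic allele pair), recomputes the headline divergence quantities:
#' the total SNP count over the shared region, per-block substitution
#' counts, per-block exon-restricted SNP counts, and the number of
#' functional (intact-ORF) genes on each haplotype.
#'
#' @param h1,h2 [haplotype()] objects of equal length and shared
#'   coordinates.
#' @return A list: `snps_total`, `blocks` (tibble `block_id`,
#'   `substitutions`, `exon_snps`), `functional` (tibble `hap_id`,
#'   `n_functional`, `n_genes`).
#' @export
validate_haplotype_pair <- function(h1, h2) {
  stopifnot(inherits(h1, "haplotype"), inherits(h2, "haplotype"))
  if (nchar(h1$sequence) != nchar(h2$sequence)) {
    abort("haplotypes differ in length; restrict both to the shared region first")
  }
  snps_total <- as.integer(count_substitutions(h1$sequence, h2$sequence))
  blocks <- lapply(seq_len(nrow(h1$blocks)), function(i) {
    b <- h1$blocks[i, ]
    in_block <- vapply(seq_len(nrow(h1$genes)), function(j) {
      min(h1$genes$exon_start[[j]]) >= b$start &&
        max(h1$genes$exon_end[[j]]) <= b$end
    }, logical(1))
    bm <- tibble(start = b$start, end = b$end)
    em <- exon_mask(h1$genes[in_block, , drop = FALSE])
    tibble(block_id = b$block_id,
           substitutions = as.integer(
             count_substitutions(h1$sequence, h2$sequence, mask = bm)),
           exon_snps = as.integer(
             count_substitutions(h1$sequence, h2$sequence, mask = em)))
  })
  functional <- lapply(list(h1, h2), function(h) {
    orf <- orf_integrity_table(h)
    tibble(hap_id = h$hap_id, n_functional = sum(orf$status == "functional"),
           n_genes = nrow(orf))
  })
  list(snps_total = snps_total, blocks = bind_rows(blocks),
       functional = bind_rows(functional))
}
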