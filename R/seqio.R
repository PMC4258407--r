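# readers/writers for the standard formats the pipeline touches

#' Read a FASTA file
#'
#' Sequences are uppercased and U is converted to T. Duplicate record ids,
#' empty records and malformed headers are format errors that name the
#' offending record.
#'
#' @param path FASTA file path.
#' @param ids_from_first_word Take the id as the first whitespace-delimited
#'   token of the header (default TRUE).
#' @return A tibble with columns `id`, `sequence`, in file order.
#' @export
read_fasta <- function(path, ids_from_first_word = TRUE) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) abort(sprintf("malformed FASTA %s: %s",
                                                    path, conditionMessage(e))))
  ids <- names(set)
  if (ids_from_first_word) ids <- sub("\\s.*$", "", ids)
  if (any(!nzchar(ids))) {
    abort(sprintf("FASTA %s: empty header at record %d", path,
                  which(!nzchar(ids))[1]))
  }
  if (anyDuplicated(ids)) {
    abort(sprintf("FASTA %s: duplicate record id '%s'", path,
                  ids[duplicated(ids)][1]))
  }
  seqs <- chartr("u", "t", toupper(as.character(set)))
  seqs <- chartr("U", "T", seqs)
  if (any(nchar(seqs) == 0)) {
    abort(sprintf("FASTA %s: empty record '%s'", path,
                  ids[which(nchar(seqs) == 0)[1]]))
  }
  tibble(id = unname(ids), sequence = unname(seqs))
}

#' Write sequences to FASTA
#'
#' @param x A tibble with `id` and `sequence`, a named character vector, or
#'   a [haplotype()].
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  seqs <- as_reference_set(x)
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a FASTQ file (phred+33)
#'
#' Strict four-line-per-record dialect (the one the simulators write).
#' Truncated records, missing `@`/`+` markers and base/quality length
#' mismatches are format errors carrying the failing record id or number.
#'
#' @param path FASTQ path.
#' @return A tibble of reads: `read_id`, `bases`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(lines)), 0L))]
  if (length(lines) %% 4 != 0) {
    abort(sprintf("FASTQ %s: truncated record at line %d",
                  path, (length(lines) %/% 4) * 4 + 1))
  }
  n <- length(lines) %/% 4
  hdr <- lines[seq(1, length(lines), by = 4)]
  bases <- toupper(lines[seq(2, length(lines), by = 4)])
  plus <- lines[seq(3, length(lines), by = 4)]
  qual <- lines[seq(4, length(lines), by = 4)]
  if (any(!startsWith(hdr, "@"))) {
    abort(sprintf("FASTQ %s: record %d header does not start with '@'",
                  path, which(!startsWith(hdr, "@"))[1]))
  }
  if (any(!startsWith(plus, "+"))) {
    abort(sprintf("FASTQ %s: record %d separator does not start with '+'",
                  path, which(!startsWith(plus, "+"))[1]))
  }
  ids <- sub("\\s.*$", "", substring(hdr, 2))
  mismatch <- nchar(bases) != nchar(qual)
  if (any(mismatch)) {
    abort(sprintf("FASTQ %s: base/quality length mismatch in record '%s'",
                  path, ids[which(mismatch)[1]]))
  }
  if (any(grepl("[^ACGTN]", bases))) {
    abort(sprintf("FASTQ %s: invalid base characters in record '%s'",
                  path, ids[which(grepl("[^ACGTN]", bases))[1]]))
  }
  tibble(read_id = ids, bases = bases, qual = qual)
}

#' Write reads to FASTQ (phred+33)
#'
#' @param reads A reads tibble (`read_id`, `bases`, `qual`). Truth-origin
#'   columns from the simulators are not serialised.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  reads <- as_reads(reads)
  out <- character(4 * nrow(reads))
  out[seq(1, length(out), by = 4)] <- paste0("@", reads$read_id)
  out[seq(2, length(out), by = 4)] <- reads$bases
  out[seq(3, length(out), by = 4)] <- "+"
  out[seq(4, length(out), by = 4)] <- reads$qual
  writeLines(out, path)
  invisible(path)
}

#' Phred scores of a reads tibble
#'
#' @param reads A reads tibble.
#' @return A list of integer phred vectors, one per read.
#' @export
read_quals <- function(reads) {
  string_to_phred(as_reads(reads)$qual)
}

bed12_cols <- c("chrom", "start", "end", "name", "score", "strand",
                "thick_start", "thick_end", "item_rgb", "block_count",
                "block_sizes", "block_starts")

#' Read gene annotations (BED12 or the package TSV dialect)
#'
#' BED12 blocks become exons without any coordinate shift (both BED and this
#' package are 0-based, half-open). A `meta` TSV with columns `gene_id`,
#' `group`, `status` supplies the paralog-group labels; without it every
#' gene gets its own group and status `functional`. When `fasta` is
#' supplied, exon bounds are validated against the sequence lengths.
#'
#' @param path BED12 file path.
#' @param meta Optional path to the gene metadata TSV.
#' @param fasta Optional FASTA path (or tibble from [read_fasta()]) for
#'   bounds validation.
#' @return A gene-model tibble (`gene_id`, `group`, `strand`, `status`,
#'   `chrom`, list-columns `exon_start`, `exon_end`).
#' @export
read_annotations <- function(path, meta = NULL, fasta = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  bed <- suppressWarnings(readr::read_tsv(path, col_names = bed12_cols,
                                          col_types = "ciiciciicicc",
                                          progress = FALSE))
  if (any(is.na(bed$start) | is.na(bed$end))) {
    abort(sprintf("BED %s: non-numeric coordinates at line %d", path,
                  which(is.na(bed$start) | is.na(bed$end))[1]))
  }
  if (any(bed$start < 0)) {
    abort(sprintf("BED %s: negative start at line %d", path,
                  which(bed$start < 0)[1]))
  }
  parse_ints <- function(x) as.integer(strsplit(sub(",$", "", x), ",")[[1]])
  exon_start <- vector("list", nrow(bed))
  exon_end <- vector("list", nrow(bed))
  for (i in seq_len(nrow(bed))) {
    sizes <- parse_ints(bed$block_sizes[i])
    offs <- parse_ints(bed$block_starts[i])
    if (length(sizes) != bed$block_count[i] || length(offs) != bed$block_count[i]) {
      abort(sprintf("BED %s: block count mismatch at line %d", path, i))
    }
    exon_start[[i]] <- bed$start[i] + offs
    exon_end[[i]] <- bed$start[i] + offs + sizes
  }
  genes <- tibble(gene_id = bed$name, group = bed$name, strand = bed$strand,
                  status = "functional", chrom = bed$chrom,
                  exon_start = exon_start, exon_end = exon_end)
  if (!is.null(meta)) {
    m <- readr::read_tsv(meta, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
    stopifnot(all(c("gene_id", "group", "status") %in% names(m)))
    genes$group <- m$group[match(genes$gene_id, m$gene_id)]
    genes$status <- m$status[match(genes$gene_id, m$gene_id)]
    if (anyNA(genes$group)) {
      abort(sprintf("metadata %s: missing entry for gene '%s'", meta,
                    genes$gene_id[which(is.na(genes$group))[1]]))
    }
  }
  if (!is.null(fasta)) {
    fa <- if (is.character(fasta)) read_fasta(fasta) else fasta
    lens <- setNames(nchar(fa$sequence), fa$id)
    for (i in seq_len(nrow(genes))) {
      lim <- lens[genes$chrom[i]]
      if (is.na(lim)) {
        abort(sprintf("annotation chrom '%s' absent from FASTA", genes$chrom[i]))
      }
      if (max(genes$exon_end[[i]]) > lim) {
        abort(sprintf("gene %s: exon beyond end of %s", genes$gene_id[i],
                      genes$chrom[i]))
      }
    }
  }
  for (i in seq_len(nrow(genes))) {
    es <- genes$exon_start[[i]]
    ee <- genes$exon_end[[i]]
    if (any(ee <= es) || (length(es) > 1 && any(es[-1] < ee[-length(ee)]))) {
      abort(sprintf("gene %s: invalid exon intervals", genes$gene_id[i]))
    }
  }
  genes
}

#' Write gene annotations as BED12 plus a metadata TSV
#'
#' Byte-stable round trip with [read_annotations()] for coordinate-sorted
#' input.
#'
#' @param genes A gene-model tibble; a `chrom` column is used when present,
#'   otherwise `chrom` names every gene's reference.
#' @param path Output BED12 path.
#' @param meta Optional output path for the `gene_id`/`group`/`status` TSV.
#' @param chrom Reference name used when `genes` has no `chrom` column.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(genes, path, meta = NULL, chrom = "ref") {
  chroms <- if ("chrom" %in% names(genes)) genes$chrom else rep(chrom, nrow(genes))
  lines <- character(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    es <- genes$exon_start[[i]]
    ee <- genes$exon_end[[i]]
    start <- min(es)
    lines[i] <- paste(chroms[i], start, max(ee), genes$gene_id[i], 0,
                      genes$strand[i], start, max(ee), "0", length(es),
                      paste0(paste(ee - es, collapse = ","), ","),
                      paste0(paste(es - start, collapse = ","), ","),
                      sep = "\t")
  }
  writeLines(lines, path)
  if (!is.null(meta)) {
    readr::write_tsv(tibble(gene_id = genes$gene_id, group = genes$group,
                            status = genes$status), meta, progress = FALSE)
  }
  invisible(path)
}

#' Write a haplotype (FASTA + BED12 + metadata TSV) to a directory
#'
#' @param h A [haplotype()].
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix (default the haplotype id).
#' @return The directory path, invisibly.
#' @export
write_locus <- function(h, dir, prefix = h$hap_id) {
  stopifnot(inherits(h, "haplotype"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(setNames(h$sequence, h$hap_id), file.path(dir, paste0(prefix, ".fa")))
  write_annotations(h$genes, file.path(dir, paste0(prefix, ".bed")),
                    meta = file.path(dir, paste0(prefix, "_genes.tsv")),
                    chrom = h$hap_id)
  readr::write_tsv(h$blocks, file.path(dir, paste0(prefix, "_blocks.tsv")),
                   progress = FALSE)
  invisible(dir)
}

#' Write mapped reads as SAM (write-only, minimal)
#'
#' One primary record per read (its best hit) with the `NM` edit-distance
#' tag and the uniqueness tag `XT:A:U` (unique) / `XT:A:R` (repeat), so
#' alignments can be inspected in standard viewers. The in-memory
#' `mapped_reads` tibble, not this text, is the pipeline's contract.
#'
#' @param mapped A `mapped_reads` tibble from [map_reads()].
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(mapped, path) {
  ref_len <- attr(mapped, "ref_lengths")
  stopifnot(!is.null(ref_len))
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(ref_len), unname(ref_len)),
              "@PG\tID:paralocus\tPN:paralocus")
  best <- mapped[!is.na(mapped$ref_id) & mapped$hit_rank == 1L, ]
  unmapped <- mapped[is.na(mapped$ref_id), ]
  recs <- character(0)
  if (nrow(best) > 0) {
    flag <- ifelse(best$strand == "-", 16L, 0L)
    seqs <- ifelse(best$strand == "-", revcomp(best$bases), best$bases)
    quals <- ifelse(best$strand == "-",
                    vapply(best$qual, function(q)
                      paste(rev(strsplit(q, "")[[1]]), collapse = ""), character(1)),
                    best$qual)
    xt <- ifelse(best$uniqueness == "unique", "U", "R")
    recs <- paste(best$read_id, flag, best$ref_id, best$start + 1L,
                  ifelse(best$uniqueness == "unique", 60L, 0L),
                  paste0(nchar(best$bases), "M"), "*", 0L, 0L, seqs, quals,
                  paste0("NM:i:", best$mismatches), paste0("XT:A:", xt),
                  sep = "\t")
  }
  if (nrow(unmapped) > 0) {
    recs <- c(recs, paste(unmapped$read_id, 4L, "*", 0L, 0L, "*", "*", 0L, 0L,
                          unmapped$bases, unmapped$qual, sep = "\t"))
  }
  writeLines(c(header, recs), path)
  invisible(path)
}
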