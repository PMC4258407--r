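# internal helpers shared across modules

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over `{A,C,G,T,N}` (case preserved,
#' unknown characters passed through unchanged).
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp(c("ACGT", "AANT"))
revcomp <- function(x) {
  stopifnot(is.character(x))
  cpp_revcomp(x)
}

#' Generate a random DNA sequence
#'
#' Uniform i.i.d. bases; uses the current RNG state, so wrap in
#' [withr::with_seed()] (or pass `seed` to the simulator entry points)
#' for reproducibility.
#'
#' @param n Sequence length in bp.
#' @return A single character string of length `n`.
#' @export
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# single sequence as character string from the containers we accept
as_sequence <- function(x) {
  if (inherits(x, "haplotype")) return(x$sequence)
  if (is.character(x) && length(x) == 1L) return(toupper(x))
  abort("expected a haplotype or a single character sequence")
}

# integer phred scores -> phred+33 string and back
phred_to_string <- function(q) {
  vapply(q, function(v) intToUtf8(v + 33L), character(1))
}

string_to_phred <- function(s) {
  lapply(s, function(x) utf8ToInt(x) - 33L)
}

# positions (0-based) of each character of `s` equal across two strings
str_codes <- function(s) as.integer(charToRaw(s))

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, lower, upper))
  }
  x
}

# normalise a references argument to a named character vector of sequences
as_reference_set <- function(references) {
  if (inherits(references, "haplotype")) {
    return(setNames(references$sequence, references$hap_id))
  }
  if (is.data.frame(references)) {
    stopifnot(all(c("id", "sequence") %in% names(references)))
    return(setNames(toupper(references$sequence), references$id))
  }
  if (is.character(references)) {
    if (is.null(names(references)) && length(references) == 1L) {
      names(references) <- "ref"
    }
    if (is.null(names(references)) || anyNA(names(references)) ||
        any(names(references) == "")) {
      abort("character references must be named")
    }
    return(toupper(references))
  }
  abort("unsupported reference container")
}

# normalise a reads argument to a tibble with read_id / bases / qual
as_reads <- function(reads) {
  if (is.character(reads)) {
    ids <- names(reads) %||% sprintf("read%d", seq_along(reads))
    reads <- tibble(read_id = ids, bases = toupper(unname(reads)),
                    qual = strrep("?", nchar(reads)))
  }
  stopifnot(is.data.frame(reads), all(c("read_id", "bases") %in% names(reads)))
  if (!"qual" %in% names(reads)) reads$qual <- strrep("?", nchar(reads$bases))
  as_tibble(reads)
}
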