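# Shared internal helpers: sequence handling, seeded evaluation, validation.

BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()].
#'
#' @param x Character vector of DNA sequences over `A`, `C`, `G`, `T`, `N`.
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp("ACGTT")
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

assert_dna <- function(x, allow_n = FALSE, arg = "sequence") {
  pat <- if (allow_n) "^[ACGTN]+$" else "^[ACGT]+$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    abort(sprintf(
      "%s contains characters outside {%s} (first offender: element %d)",
      arg, if (allow_n) "A,C,G,T,N" else "A,C,G,T", which(bad)[1]
    ))
  }
  invisible(x)
}

assert_count <- function(x, min = 0L, arg = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %s", arg, min))
  }
  invisible(as.integer(x))
}

assert_prob <- function(x, arg = deparse(substitute(x))) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must lie in [0, 1]", arg))
  }
  invisible(x)
}

#' Read and write unigene FASTA files
#'
#' `read_unigene_fasta()` returns a tibble with one row per sequence;
#' `write_unigene_fasta()` writes such a tibble back out. Sequence handling is
#' delegated to [Biostrings::readDNAStringSet()].
#'
#' @param path File path.
#' @param unigenes Tibble with columns `id` and `sequence`.
#' @return `read_unigene_fasta()`: tibble with columns `id`, `sequence`,
#'   `length`. `write_unigene_fasta()`: `path`, invisibly.
#' @export
read_unigene_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  dna <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(dna)
  tibble::tibble(
    id = sub("\\s.*$", "", names(dna)),
    sequence = unname(seqs),
    length = nchar(seqs)
  )
}

#' @rdname read_unigene_fasta
#' @export
write_unigene_fasta <- function(unigenes, path) {
  dna <- Biostrings::DNAStringSet(setNames(unigenes$sequence, unigenes$id))
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}
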