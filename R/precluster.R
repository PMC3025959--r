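# EST cleaning and identity-threshold pre-clustering. Sequences are grouped
# into single-linkage components of the graph whose edges are local
# alignments with >= 90% identity over >= 30 aligned bases (defaults).

#' Mask low-complexity regions by windowed Shannon entropy
#'
#' Slides a window along each sequence and masks every window whose Shannon
#' entropy falls below a threshold. In the default mononucleotide mode the
#' entropy is computed over base frequencies (0-2 bits). The
#' dinucleotide-aware mode computes the entropy of overlapping dinucleotides
#' divided by two (an entropy-per-base rate, again on a 0-2 bit scale), which
#' additionally catches short-period repeats such as `ACGTACGT...` whose
#' mononucleotide entropy is maximal.
#'
#' Masked regions are recorded as 0-based half-open intervals and replaced by
#' `N` in `masked_sequence`; the original sequence is left untouched.
#'
#' @param reads Tibble with columns `id` and `sequence`.
#' @param window Window width in nt (>= 4).
#' @param entropy_threshold Threshold in bits; windows strictly below it are
#'   masked.
#' @param mode `"mono"` or `"dinucleotide"`.
#' @return `reads` with added columns `masked_sequence` and `masked_regions`
#'   (list column of tibbles with 0-based half-open `start`, `end`).
#' @export
mask_low_complexity <- function(reads, window = 16, entropy_threshold = 1.2,
                                mode = c("mono", "dinucleotide")) {
  mode <- match.arg(mode)
  if (window < 4) abort("`window` must be >= 4")
  res <- purrr::map(reads$sequence, function(s) {
    assert_dna(s, allow_n = TRUE)
    n <- nchar(s)
    mask <- logical(n)
    if (n >= window) {
      chars <- strsplit(s, "")[[1]]
      ent <- vapply(seq_len(n - window + 1), function(i) {
        win <- chars[i:(i + window - 1)]
        window_entropy(win, mode)
      }, double(1))
      low <- which(ent < entropy_threshold)
      for (i in low) mask[i:(i + window - 1)] <- TRUE
    }
    regions <- mask_to_regions(mask)
    masked_seq <- s
    if (any(mask)) {
      chars <- strsplit(s, "")[[1]]
      chars[mask] <- "N"
      masked_seq <- paste(chars, collapse = "")
    }
    list(masked_sequence = masked_seq, masked_regions = regions)
  })
  reads$masked_sequence <- purrr::map_chr(res, "masked_sequence")
  reads$masked_regions <- purrr::map(res, "masked_regions")
  reads
}

window_entropy <- function(chars, mode) {
  if (mode == "mono") {
    p <- table(chars) / length(chars)
    -sum(p * log2(p))
  } else {
    di <- paste0(chars[-length(chars)], chars[-1])
    p <- table(di) / length(di)
    -sum(p * log2(p)) / 2
  }
}

mask_to_regions <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  tibble::tibble(start = starts[keep], end = ends[keep])
}

#' Trim exact adaptor matches from read ends
#'
#' Removes exact occurrences of the supplied adaptor sequences (and their
#' reverse complements) from either end of each read. Only exact terminal
#' matches are trimmed; partial or internal matches are left alone.
#'
#' @param reads Tibble with `id`, `sequence`.
#' @param adaptors Character vector of adaptor sequences.
#' @return `reads` with trimmed `sequence` and updated `length`.
#' @export
trim_adaptors <- function(reads, adaptors) {
  pats <- unique(c(adaptors, revcomp(adaptors)))
  reads$sequence <- vapply(reads$sequence, function(s) {
    changed <- TRUE
    while (changed) {
      changed <- FALSE
      for (ad in pats) {
        if (startsWith(s, ad)) {
          s <- substr(s, nchar(ad) + 1, nchar(s)); changed <- TRUE
        }
        if (endsWith(s, ad)) {
          s <- substr(s, 1, nchar(s) - nchar(ad)); changed <- TRUE
        }
      }
    }
    s
  }, character(1), USE.NAMES = FALSE)
  reads$length <- nchar(reads$sequence)
  reads
}

#' Best local alignment identity between two sequences
#'
#' Smith-Waterman local alignment (linear gap penalty, deterministic
#' traceback) of `a` against both strands of `b`; the best-scoring
#' alignment's statistics are returned. Identity is computed over aligned
#' columns including internal gaps.
#'
#' Masked bases (`N`) never align as matches: before alignment `N`s in `a`
#' and `b` are rewritten to distinct out-of-alphabet letters so they mismatch
#' everything, including each other.
#'
#' @param a,b DNA sequences (character scalars).
#' @param match,mismatch,gap Alignment scores (gap is per gap column).
#' @param both_strands Compare `a` against `b` and its reverse complement,
#'   keeping the better score (ties prefer the forward strand).
#' @return One-row tibble: `identity_pct`, `aligned_length`, `score`,
#'   `strand`.
#' @export
#' @examples
#' pairwise_local_identity("ACGTACGTAC", "ACGTACGTAC")
pairwise_local_identity <- function(a, b, match = 1, mismatch = -2, gap = -3,
                                    both_strands = TRUE) {
  if (nchar(a) == 0 || nchar(b) == 0) abort("sequences must be non-empty")
  a2 <- gsub("N", "#", a, fixed = TRUE)
  strands <- if (both_strands) c("+", "-") else "+"
  best <- NULL
  for (st in strands) {
    bs <- if (st == "+") b else revcomp(b)
    bs <- gsub("N", "$", bs, fixed = TRUE)
    al <- .sw_local_cpp(a2, bs, match, mismatch, gap)
    if (is.null(best) || al$score > best$score) {
      best <- al
      best$strand <- st
    }
  }
  tibble::tibble(
    identity_pct = best$identity_pct,
    aligned_length = as.integer(best$aligned_length),
    score = best$score,
    strand = best$strand
  )
}

#' Pre-cluster sequences by pairwise local identity
#'
#' Computes all pairwise best local alignments and links two reads when the
#' alignment reaches at least `min_identity` percent identity over at least
#' `min_length` aligned bases. Clusters are the connected components
#' (single linkage) of this graph; each cluster is labelled by its
#' lexicographically smallest member id, so the output is invariant to input
#' order.
#'
#' If the reads carry a `masked_sequence` column (see
#' [mask_low_complexity()]) the masked form is aligned, so masked regions
#' never create links.
#'
#' @param reads Tibble with `id`, `sequence` (and optionally
#'   `masked_sequence`).
#' @param min_identity Minimum identity percent over aligned columns.
#' @param min_length Minimum aligned length in nt.
#' @inheritParams pairwise_local_identity
#' @return Tibble `cluster_id`, `member_id`, sorted by both.
#' @export
precluster <- function(reads, min_identity = 90, min_length = 30,
                       match = 1, mismatch = -2, gap = -3,
                       both_strands = TRUE) {
  if (nrow(reads) == 0) {
    return(tibble::tibble(cluster_id = character(), member_id = character()))
  }
  seqs <- if ("masked_sequence" %in% names(reads)) {
    reads$masked_sequence
  } else {
    reads$sequence
  }
  ids <- reads$id
  n <- length(ids)
  # precompute both strands once; masked bases are rewritten to distinct
  # out-of-alphabet letters on the two sides so they never align
  a_side <- gsub("N", "#", seqs, fixed = TRUE)
  b_fwd <- gsub("N", "$", seqs, fixed = TRUE)
  b_rc <- gsub("N", "$", revcomp(seqs), fixed = TRUE)
  edges <- list()
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        al <- .sw_local_cpp(a_side[i], b_fwd[j], match, mismatch, gap)
        if (both_strands) {
          al2 <- .sw_local_cpp(a_side[i], b_rc[j], match, mismatch, gap)
          if (al2$score > al$score) al <- al2
        }
        if (al$identity_pct >= min_identity &&
            al$aligned_length >= min_length) {
          edges[[length(edges) + 1]] <- c(ids[i], ids[j])
        }
      }
    }
  }
  g <- igraph::graph_from_data_frame(
    if (length(edges)) do.call(rbind, edges) else
      matrix(character(), ncol = 2),
    directed = FALSE,
    vertices = data.frame(name = sort(ids))
  )
  comp <- igraph::components(g)$membership
  out <- tibble::tibble(member_id = names(comp), comp = unname(comp)) |>
    dplyr::group_by(.data$comp) |>
    dplyr::mutate(cluster_id = min(.data$member_id)) |>
    dplyr::ungroup() |>
    dplyr::select("cluster_id", "member_id") |>
    dplyr::arrange(.data$cluster_id, .data$member_id)
  out
}
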