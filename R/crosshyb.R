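# Specificity screen for designed probes: a probe is flagged when some
# non-source unigene shows BOTH > 70% overall identity to the probe AND a
# contiguous identical stretch of > 20 nt (strict inequalities, AND rule).

#' Longest exact common substring
#'
#' Length of the longest contiguous identical stretch shared by `a` and `b`,
#' optionally considering both strands of `b`.
#'
#' @param a,b DNA sequences (character scalars).
#' @param both_strands Also compare against the reverse complement of `b`.
#' @return Integer length in nt.
#' @export
#' @examples
#' longest_common_substring("AACCGGTT", "CCGG")
longest_common_substring <- function(a, b, both_strands = TRUE) {
  if (nchar(a) == 0 || nchar(b) == 0) abort("sequences must be non-empty")
  len <- .lcs_length_cpp(a, b)
  if (both_strands) len <- max(len, .lcs_length_cpp(a, revcomp(b)))
  as.integer(len)
}

#' Overall identity of a probe against a target unigene
#'
#' Identity of the best-scoring local alignment of the probe against either
#' strand of the target. Under the default `"probe"` denominator the
#' identity is expressed over the full probe length, so probe bases left
#' unaligned count as mismatches; the `"alignment"` denominator uses aligned
#' columns only.
#'
#' @param probe,target DNA sequences (probe >= 20 nt).
#' @param denominator `"probe"` (default) or `"alignment"`.
#' @inheritParams pairwise_local_identity
#' @return Identity percent (numeric scalar).
#' @export
overall_identity <- function(probe, target,
                             denominator = c("probe", "alignment"),
                             match = 1, mismatch = -2, gap = -3,
                             both_strands = TRUE) {
  denominator <- match.arg(denominator)
  if (nchar(probe) < 20) abort("probe must be at least 20 nt")
  strands <- if (both_strands) c("+", "-") else "+"
  best <- 0
  for (st in strands) {
    tg <- if (st == "+") target else revcomp(target)
    al <- .sw_local_cpp(probe, tg, match, mismatch, gap)
    id <- if (denominator == "probe") {
      100 * al$nmatch / nchar(probe)
    } else {
      al$identity_pct
    }
    best <- max(best, id)
  }
  best
}

#' Screen designed probes for potential cross-hybridization
#'
#' Evaluates every probe against every non-source unigene and flags a probe
#' when some target satisfies BOTH thresholds strictly:
#' overall identity > `id_threshold` percent AND longest common substring >
#' `lcs_threshold` nt. Self-comparison is excluded by unigene id (probes are
#' substrings of their source).
#'
#' @param probes Tibble with columns `probe_id`, `unigene_id` (source) and
#'   `sequence`, e.g. the designed rows of a [design_probes()] report.
#' @param unigenes Tibble with columns `id`, `sequence`; must contain every
#'   probe's source unigene.
#' @param id_threshold Overall identity threshold (percent, strict).
#' @param lcs_threshold Contiguous identical length threshold (nt, strict).
#' @param denominator Identity denominator, see [overall_identity()].
#' @return An object of class `crosshyb_screen`: list with `report` (one row
#'   per probe: worst-case `target_unigene_id`, `overall_identity`,
#'   `lcs_length`, `flagged`) and `hits` (all probe/target pairs passing
#'   both thresholds). `tidy()` returns the per-probe report.
#' @export
screen_crosshyb <- function(probes, unigenes, id_threshold = 70,
                            lcs_threshold = 20, denominator = "probe") {
  missing_src <- setdiff(probes$unigene_id, unigenes$id)
  if (length(missing_src) > 0) {
    abort(sprintf("probe source unigene(s) not found: %s",
                  paste(missing_src, collapse = ", ")))
  }
  target_rc <- revcomp(unigenes$sequence)  # both strands, computed once
  pairs <- vector("list", nrow(probes))
  for (i in seq_len(nrow(probes))) {
    keep <- unigenes$id != probes$unigene_id[i]
    if (!any(keep)) {
      pairs[[i]] <- tibble::tibble(
        probe_id = character(), target_unigene_id = character(),
        overall_identity = double(), lcs_length = integer()
      )
      next
    }
    p <- probes$sequence[i]
    idx <- which(keep)
    ids <- double(length(idx)); lcs <- integer(length(idx))
    for (t in seq_along(idx)) {
      j <- idx[t]
      f <- .sw_local_cpp(p, unigenes$sequence[j], 1, -2, -3)
      r <- .sw_local_cpp(p, target_rc[j], 1, -2, -3)
      ids[t] <- if (denominator == "probe") {
        100 * max(f$nmatch, r$nmatch) / nchar(p)
      } else {
        max(f$identity_pct, r$identity_pct)
      }
      lcs[t] <- max(.lcs_length_cpp(p, unigenes$sequence[j]),
                    .lcs_length_cpp(p, target_rc[j]))
    }
    pairs[[i]] <- tibble::tibble(
      probe_id = probes$probe_id[i],
      target_unigene_id = unigenes$id[idx],
      overall_identity = ids,
      lcs_length = lcs
    )
  }
  all_pairs <- dplyr::bind_rows(pairs)
  hits <- dplyr::filter(all_pairs,
                        .data$overall_identity > id_threshold,
                        .data$lcs_length > lcs_threshold)
  report <- all_pairs |>
    dplyr::group_by(.data$probe_id) |>
    dplyr::arrange(dplyr::desc(.data$overall_identity),
                   dplyr::desc(.data$lcs_length), .data$target_unigene_id,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  report <- probes |>
    dplyr::select("probe_id", "unigene_id") |>
    dplyr::left_join(report, by = "probe_id") |>
    dplyr::mutate(flagged = .data$probe_id %in% hits$probe_id)
  structure(
    list(report = report, hits = hits,
         thresholds = c(identity = id_threshold, lcs = lcs_threshold)),
    class = "crosshyb_screen"
  )
}

#' @export
print.crosshyb_screen <- function(x, ...) {
  cat(sprintf(
    "<crosshyb_screen> %d probes screened, %d flagged (identity > %g%% AND lcs > %g nt)\n",
    nrow(x$report), sum(x$report$flagged),
    x$thresholds[["identity"]], x$thresholds[["lcs"]]
  ))
  print(x$report, ...)
  invisible(x)
}
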