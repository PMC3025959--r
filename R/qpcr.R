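# Relative qPCR quantification against a reference-gene panel, geNorm-style
# reference stability ranking, and agreement with microarray log-ratios.

#' Relative expression from threshold cycles
#'
#' Normalizes a target gene's Ct to the arithmetic mean of the reference
#' genes' Cts (equivalently, to the geometric mean of their expression
#' levels): `value = base^(s * (Ct_x - mean(Ct_refs)))`. Under the standard
#' convention `s = -1`, so expression halves when Ct increases by one cycle;
#' the `as_printed` convention (`s = +1`) reproduces a published rendering
#' of the formula in which the exponent's sign was lost in typesetting, and
#' is retained as an option rather than silently corrected.
#'
#' @param ct Target gene threshold cycle (positive).
#' @param ct_refs Numeric vector of at least 2 (by default 3) reference-gene
#'   Cts.
#' @param convention `"standard"` or `"as_printed"`.
#' @param base Amplification efficiency base (2 = perfect doubling).
#' @return Relative expression (positive numeric scalar).
#' @export
#' @examples
#' relative_expression(19, c(20, 21, 22))
relative_expression <- function(ct, ct_refs,
                                convention = c("standard", "as_printed"),
                                base = 2) {
  convention <- match.arg(convention)
  if (any(c(ct, ct_refs) <= 0)) abort("Ct values must be positive")
  if (length(ct_refs) < 2) abort("at least 2 reference Cts are required")
  s <- if (convention == "standard") -1 else 1
  base^(s * (ct - mean(ct_refs)))
}

#' Relative quantification of a Ct table
#'
#' Averages technical replicates per (gene, sample), then normalizes each
#' target gene's Ct to the mean reference-gene Ct of the same sample.
#'
#' @param ct_table Tidy Ct tibble: `gene_id`, `sample_id`, `ct`,
#'   `is_reference`, `technical_replicate` (see [simulate_ct_table()]).
#' @inheritParams relative_expression
#' @return Tibble: `gene_id`, `sample_id`, `value` (fold units relative to
#'   the reference geometric mean) and `log2_value`.
#' @export
qpcr_quantify <- function(ct_table, convention = c("standard", "as_printed"),
                          base = 2) {
  convention <- match.arg(convention)
  avg <- ct_table |>
    dplyr::group_by(.data$gene_id, .data$sample_id, .data$is_reference) |>
    dplyr::summarise(ct = mean(.data$ct), .groups = "drop")
  refs <- avg |>
    dplyr::filter(.data$is_reference) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(ref_ct = mean(.data$ct), n_refs = dplyr::n(),
                     .groups = "drop")
  if (any(refs$n_refs < 2)) {
    abort("each sample needs at least 2 reference-gene Cts")
  }
  s <- if (convention == "standard") -1 else 1
  avg |>
    dplyr::filter(!.data$is_reference) |>
    dplyr::inner_join(refs, by = "sample_id") |>
    dplyr::mutate(
      value = base^(s * (.data$ct - .data$ref_ct)),
      log2_value = log2(.data$value)
    ) |>
    dplyr::select("gene_id", "sample_id", "value", "log2_value")
}

#' geNorm-style reference-gene stability ranking
#'
#' For each candidate reference gene, the stability measure M is the mean,
#' over all other candidates, of the standard deviation across samples of
#' their pairwise Ct difference (equivalently the SD of the pairwise log2
#' expression ratio at perfect efficiency). Lower M is more stable; the top
#' `n_select` candidates form the reference panel. The optional iterative
#' mode repeatedly eliminates the least stable candidate and recomputes M,
#' as in the original procedure.
#'
#' @param ct_table Tidy tibble `gene_id`, `sample_id`, `ct` restricted to
#'   candidate reference genes (technical replicates averaged if a
#'   `technical_replicate` column is present). At least 3 candidates and 2
#'   samples are required.
#' @param n_select Size of the selected panel.
#' @param method `"single_pass"` (rank all candidates by M once) or
#'   `"iterative"` (geNorm's worst-candidate elimination).
#' @return Tibble: `gene_id`, `stability_m`, `rank`, `selected`, ordered by
#'   ascending M (for the iterative mode, by elimination order).
#' @export
reference_stability <- function(ct_table, n_select = 3,
                                method = c("single_pass", "iterative")) {
  method <- match.arg(method)
  avg <- ct_table |>
    dplyr::group_by(.data$gene_id, .data$sample_id) |>
    dplyr::summarise(ct = mean(.data$ct), .groups = "drop")
  wide <- tidyr::pivot_wider(avg, names_from = "sample_id",
                             values_from = "ct")
  x <- as.matrix(wide[-1])
  rownames(x) <- wide$gene_id
  if (nrow(x) < 3) abort("at least 3 candidate reference genes are required")
  if (ncol(x) < 2) abort("at least 2 samples are required")
  if (any(is.na(x))) abort("every candidate needs a Ct in every sample")

  m_values <- function(mat) {
    vapply(seq_len(nrow(mat)), function(j) {
      others <- setdiff(seq_len(nrow(mat)), j)
      mean(vapply(others, function(k) sd(mat[j, ] - mat[k, ]), double(1)))
    }, double(1))
  }

  if (method == "single_pass") {
    m <- m_values(x)
    out <- tibble::tibble(gene_id = rownames(x), stability_m = m) |>
      dplyr::arrange(.data$stability_m, .data$gene_id)
  } else {
    remaining <- x
    eliminated <- character()
    elim_m <- double()
    while (nrow(remaining) > 2) {
      m <- m_values(remaining)
      worst <- which.max(m)
      eliminated <- c(eliminated, rownames(remaining)[worst])
      elim_m <- c(elim_m, m[worst])
      remaining <- remaining[-worst, , drop = FALSE]
    }
    m_last <- m_values(remaining)
    out <- tibble::tibble(
      gene_id = c(rownames(remaining)[order(m_last)], rev(eliminated)),
      stability_m = c(sort(m_last), rev(elim_m))
    )
  }
  out$rank <- seq_len(nrow(out))
  out$selected <- out$rank <= n_select
  out
}

#' Agreement between microarray and qPCR log-ratios
#'
#' Pearson correlation of paired per-gene log2 ratios from the two
#' platforms, plus the fraction of genes whose direction of change agrees.
#'
#' @param array_log2,qpcr_log2 Paired numeric vectors of per-gene log2
#'   ratios (at least 3 genes, each with nonzero variance).
#' @return One-row tibble: `n`, `pearson_r`, `sign_concordance` (percent).
#' @export
platform_agreement <- function(array_log2, qpcr_log2) {
  if (length(array_log2) != length(qpcr_log2)) {
    abort("the two log2-ratio vectors must be paired (equal length)")
  }
  ok <- complete.cases(array_log2, qpcr_log2)
  a <- array_log2[ok]; q <- qpcr_log2[ok]
  if (length(a) < 3) abort("at least 3 shared genes are required")
  if (sd(a) == 0 || sd(q) == 0) {
    abort("zero variance in one platform's log2 ratios")
  }
  tibble::tibble(
    n = length(a),
    pearson_r = cor(a, q),
    sign_concordance = 100 * mean(sign(a) == sign(q))
  )
}
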