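# Differential expression on dye-corrected log2 ratios: an ordinary
# per-gene one-sample linear fit with BH adjustment, and a SAM-style
# permutation test with per-gene FDR from sign-flip permutations.

#' Per-gene linear fit of dye-corrected log2 ratios
#'
#' For each gene, fits the one-parameter linear model "mean log2 ratio" to
#' its orientation-corrected observations: the estimate is the mean, the
#' statistic an ordinary one-sample t against 0, the p-value two-sided.
#' Genes with fewer than 2 observations are reported untestable and excluded
#' from the multiplicity correction. Degenerate genes with zero SD get
#' `t = Inf` (nonzero mean; p deferred to the permutation test, excluded
#' from BH) or `t = 0, p = 1` (all-zero observations).
#'
#' @param mat Tidy expression matrix from [build_expression_matrix()] (needs
#'   columns `feature_id` and `M_corrected`).
#' @return Tibble of class `gene_fit`: `feature_id`, `n_obs`, `estimate`,
#'   `t`, `p`, `p_adj`, `testable`.
#' @export
per_gene_linear_fit <- function(mat) {
  out <- mat |>
    dplyr::filter(!is.na(.data$M_corrected)) |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::summarise(
      n_obs = dplyr::n(),
      estimate = mean(.data$M_corrected),
      s = sd(.data$M_corrected),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      testable = .data$n_obs >= 2,
      t = dplyr::case_when(
        !.data$testable ~ NA_real_,
        .data$s == 0 & .data$estimate == 0 ~ 0,
        .data$s == 0 ~ Inf * sign(.data$estimate),
        TRUE ~ .data$estimate / (.data$s / sqrt(.data$n_obs))
      ),
      p = dplyr::case_when(
        !.data$testable ~ NA_real_,
        .data$s == 0 & .data$estimate == 0 ~ 1,
        .data$s == 0 ~ NA_real_,
        TRUE ~ 2 * pt(-abs(.data$t), df = .data$n_obs - 1)
      )
    ) |>
    dplyr::select(-"s")
  adj <- rep(NA_real_, nrow(out))
  ok <- !is.na(out$p)
  adj[ok] <- bh_adjust(out$p[ok])
  out$p_adj <- adj
  class(out) <- c("gene_fit", class(out))
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment (a validated thin wrapper over
#' [stats::p.adjust()] with `method = "BH"`).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1] and be non-missing")
  }
  p.adjust(p, method = "BH")
}

#' SAM-style permutation test
#'
#' Computes the variance-stabilised statistic `d_i = mean_i / (s_i + s0)`
#' per gene, where `s_i` is the per-gene sample SD of the dye-corrected
#' log2 ratios and `s0` is a fudge constant chosen as a low quantile of the
#' `s_i` distribution. The null distribution comes from sign-flip
#' permutations of the observation columns (the natural null for a
#' one-sample dye-swap design). The per-gene FDR is the median over
#' permutations of the number of null `|d|` values at or above `|d_i|`,
#' divided by the observed count at or above `|d_i|`, capped at 1 and made
#' monotone in `|d|`.
#'
#' @param mat Tidy expression matrix from [build_expression_matrix()].
#' @param n_permutations Number of sign-flip permutations (>= 10).
#' @param seed Integer seed for the permutation draws.
#' @param s0_quantile Quantile of the `s_i` distribution used for `s0`.
#' @return Object of class `sam_fit`: list with `table` (tibble:
#'   `feature_id`, `n_obs`, `estimate`, `s`, `d`, `fdr`), `s0`,
#'   `n_permutations`, `seed`. `tidy()` returns the table.
#' @export
sam_test <- function(mat, n_permutations = 200, seed = 1,
                     s0_quantile = 0.05) {
  if (n_permutations < 10) abort("`n_permutations` must be at least 10")
  wide <- mat |>
    dplyr::select("feature_id", "slide_id", "M_corrected") |>
    tidyr::pivot_wider(names_from = "slide_id",
                       values_from = "M_corrected")
  x <- as.matrix(wide[-1])
  rownames(x) <- wide$feature_id
  n_i <- rowSums(!is.na(x))
  keep <- n_i >= 2
  x <- x[keep, , drop = FALSE]
  n_i <- n_i[keep]
  m <- rowMeans(x, na.rm = TRUE)
  s <- apply(x, 1, sd, na.rm = TRUE)
  s0 <- quantile(s, s0_quantile, names = FALSE)
  d <- m / (s + s0)
  abs_d <- abs(d)
  sorted_abs <- sort(abs_d)
  n_genes <- length(d)
  # observed count of |d| >= |d_i|
  obs_ge <- pmax(n_genes - findInterval(abs_d - 1e-12, sorted_abs), 1)

  perm_counts <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(b) {
      signs <- sample(c(-1, 1), ncol(x), replace = TRUE)
      xb <- sweep(x, 2, signs, `*`)
      mb <- rowMeans(xb, na.rm = TRUE)
      # per-gene SD must be recomputed: flipping individual observations
      # changes the spread around the permuted mean
      sqb <- rowMeans(xb^2, na.rm = TRUE)
      sb_sd <- sqrt(pmax(sqb - mb^2, 0) * n_i / (n_i - 1))
      db <- abs(mb / (sb_sd + s0))
      sb <- sort(db)
      n_genes - findInterval(abs_d - 1e-12, sb)
    }, double(n_genes))
  })
  med_false <- apply(perm_counts, 1, median)
  fdr <- pmin(med_false / obs_ge, 1)
  # FDR must be non-increasing in |d|: walking down from the largest |d|,
  # never let it drop below a value already seen above
  o <- order(abs_d, decreasing = TRUE)
  fdr[o] <- cummax(fdr[o])

  structure(list(
    table = tibble::tibble(
      feature_id = rownames(x), n_obs = as.integer(n_i),
      estimate = unname(m), s = unname(s), d = unname(d), fdr = unname(fdr)
    ),
    s0 = s0, n_permutations = n_permutations, seed = seed
  ), class = "sam_fit")
}

#' @export
print.sam_fit <- function(x, ...) {
  cat(sprintf("<sam_fit> %d genes, s0 = %.4g, %d sign-flip permutations\n",
              nrow(x$table), x$s0, x$n_permutations))
  print(x$table, ...)
  invisible(x)
}

#' Construct a differential expression gene list
#'
#' @param gene_ids Character vector of significant genes.
#' @param comparison Comparison label (e.g. `"flower_vs_leaf"`).
#' @param method `"linear_model"`, `"permutation"` or `"consensus"`.
#' @param threshold Significance threshold used.
#' @param direction Optional per-gene direction labels.
#' @return Tibble of class `de_gene_list`.
#' @export
de_gene_list <- function(gene_ids, comparison, method, threshold,
                         direction = NULL) {
  out <- tibble::tibble(
    gene_id = gene_ids, comparison = comparison, method = method,
    threshold = threshold,
    direction = direction %||% NA_character_
  )
  class(out) <- c("de_gene_list", class(out))
  out
}

#' Consensus of two differential expression lists
#'
#' Genes called by both independent methods for the same comparison; the
#' per-method provenance is retained. Mismatched comparison labels are an
#' error.
#'
#' @param linear_list,sam_list `de_gene_list` tibbles for the same
#'   comparison.
#' @return `de_gene_list` with `method = "consensus"` and logical columns
#'   `in_linear`, `in_sam`.
#' @export
consensus_lists <- function(linear_list, sam_list) {
  ca <- unique(linear_list$comparison)
  cb <- unique(sam_list$comparison)
  if (!identical(ca, cb)) {
    abort(sprintf("comparison mismatch: %s vs %s",
                  paste(ca, collapse = ","), paste(cb, collapse = ",")))
  }
  shared <- intersect(linear_list$gene_id, sam_list$gene_id)
  thresholds <- unique(c(linear_list$threshold, sam_list$threshold))
  out <- de_gene_list(
    shared, comparison = ca %||% NA_character_, method = "consensus",
    threshold = if (length(thresholds)) max(thresholds) else NA_real_
  )
  out$in_linear <- TRUE
  out$in_sam <- TRUE
  out
}
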