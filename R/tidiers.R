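# broom-style tidiers for the package's fitted objects.

#' Tidy a SAM permutation fit
#'
#' @param x A `sam_fit` from [sam_test()].
#' @param ... Unused.
#' @return The per-gene tibble: `feature_id`, `n_obs`, `estimate`, `s`,
#'   `d`, `fdr`.
#' @export
tidy.sam_fit <- function(x, ...) x$table

#' @rdname tidy.sam_fit
#' @param fdr_threshold Threshold used for the significant-gene count.
#' @return `glance()`: one-row tibble with `n_genes`, `s0`,
#'   `n_permutations`, `n_significant`.
#' @export
glance.sam_fit <- function(x, fdr_threshold = 0.05, ...) {
  tibble::tibble(
    n_genes = nrow(x$table),
    s0 = x$s0,
    n_permutations = x$n_permutations,
    n_significant = sum(x$table$fdr <= fdr_threshold)
  )
}

#' Tidy a per-gene linear fit
#'
#' @param x A `gene_fit` from [per_gene_linear_fit()].
#' @param ... Unused.
#' @return The underlying tibble.
#' @export
tidy.gene_fit <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidy.gene_fit
#' @param alpha Adjusted-p threshold for the significant-gene count.
#' @export
glance.gene_fit <- function(x, alpha = 0.05, ...) {
  tibble::tibble(
    n_genes = nrow(x),
    n_testable = sum(x$testable),
    n_significant = sum(x$p_adj <= alpha, na.rm = TRUE)
  )
}

#' Tidy a cross-hybridization screen
#'
#' @param x A `crosshyb_screen` from [screen_crosshyb()].
#' @param ... Unused.
#' @return The per-probe report tibble (worst-case hit and flag per probe).
#' @export
tidy.crosshyb_screen <- function(x, ...) x$report

#' @rdname tidy.crosshyb_screen
#' @export
glance.crosshyb_screen <- function(x, ...) {
  tibble::tibble(
    n_probes = nrow(x$report),
    n_flagged = sum(x$report$flagged),
    identity_threshold = x$thresholds[["identity"]],
    lcs_threshold = x$thresholds[["lcs"]]
  )
}

#' Tidy a hybridization dendrogram
#'
#' @param x A `hyb_dendrogram` from [hierarchical_cluster()].
#' @param ... Unused.
#' @return Tibble of merges: `merge1`, `merge2` (negative = leaf index),
#'   `height`.
#' @export
tidy.hyb_dendrogram <- function(x, ...) {
  tibble::tibble(
    merge1 = x$hclust$merge[, 1],
    merge2 = x$hclust$merge[, 2],
    height = x$hclust$height
  )
}
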