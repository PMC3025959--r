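# Downstream set analyses: tissue-specific calling from directed DE lists,
# three-set Venn partitioning, Fisher's exact functional enrichment with BH
# correction, and average-linkage hierarchical clustering of hybridizations.

#' Tissue-specifically over-expressed genes
#'
#' Given directed differential expression calls for the three pairwise
#' comparisons of three conditions, a gene is specific to condition T when
#' it is up-regulated in T in BOTH comparisons involving T.
#'
#' @param de_calls Tibble with one row per (gene, comparison):
#'   columns `gene_id`, `cond_a`, `cond_b` (the two conditions compared)
#'   and `up_in` (which of the two the gene is up-regulated in).
#' @return Tibble: `condition`, `gene_id`.
#' @export
tissue_specific <- function(de_calls) {
  conds <- sort(unique(c(de_calls$cond_a, de_calls$cond_b)))
  if (length(conds) != 3) {
    abort("expected exactly 3 conditions across the comparisons")
  }
  pairs <- unique(t(apply(de_calls[c("cond_a", "cond_b")], 1, sort)))
  if (nrow(pairs) != 3) {
    abort("expected the 3 pairwise comparisons of 3 conditions")
  }
  bad <- !(de_calls$up_in == de_calls$cond_a |
             de_calls$up_in == de_calls$cond_b)
  if (any(bad)) {
    abort("`up_in` must name one of the two compared conditions")
  }
  purrr::map(conds, function(tt) {
    involving <- de_calls[de_calls$cond_a == tt | de_calls$cond_b == tt, ]
    up <- involving[involving$up_in == tt, ]
    n_cmp <- table(up$gene_id)
    tibble::tibble(condition = tt, gene_id = sort(names(n_cmp)[n_cmp >= 2]))
  }) |>
    dplyr::bind_rows()
}

#' Three-set Venn partition
#'
#' Partitions the union of three gene sets into the seven disjoint Venn
#' regions.
#'
#' @param a,b,c Character vectors (gene sets).
#' @param names Labels for the three sets.
#' @return Tibble: `region` (e.g. `"a_only"`, `"a_and_b"`,
#'   `"a_and_b_and_c"` with the supplied labels substituted), `n`, and a
#'   `genes` list column. Regions are pairwise disjoint and their sizes sum
#'   to the size of the union.
#' @export
venn_partition <- function(a, b, c, names = c("a", "b", "c")) {
  a <- unique(a); b <- unique(b); c <- unique(c)
  u <- union(union(a, b), c)
  ina <- u %in% a; inb <- u %in% b; inc <- u %in% c
  region_of <- function(wa, wb, wc) {
    members <- u[ina == wa & inb == wb & inc == wc]
    parts <- names[base::c(wa, wb, wc)]  # `c` is masked by the third set
    label <- if (sum(wa, wb, wc) == 1) paste0(parts, "_only")
             else paste(parts, collapse = "_and_")
    tibble::tibble(region = label, n = length(members),
                   genes = list(sort(members)))
  }
  combos <- expand.grid(wa = c(TRUE, FALSE), wb = c(TRUE, FALSE),
                        wc = c(TRUE, FALSE))
  combos <- combos[rowSums(combos) > 0, ]
  purrr::pmap(combos, region_of) |> dplyr::bind_rows()
}

#' Fisher's exact functional enrichment
#'
#' For each functional term annotating the background, tests the 2x2 table
#' (term hits in the gene set, set misses, background term hits outside the
#' set, background misses) with Fisher's exact test (two-sided by default:
#' the sum of all table probabilities at or below the observed one), then
#' adjusts across terms by Benjamini-Hochberg. Direction (`over`/`under`)
#' is the side of the odds ratio. Genes present in the set but absent from
#' the annotation map still count in the set and background sizes; they just
#' hit no term.
#'
#' @param gene_set Character vector, a subset of `background`.
#' @param background Character vector of all assayed genes (the full probe
#'   set of the array is the natural reference).
#' @param term_map Tibble: `gene_id`, `term_id` and optionally `term_name`.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return Tibble: `term_id`, `term_name`, `k` (set hits), `K` (background
#'   hits), `n` (set size), `N` (background size), `odds_ratio`, `p`,
#'   `p_adj`, `direction`.
#' @export
fisher_enrichment <- function(gene_set, background, term_map,
                              alternative = "two.sided") {
  gene_set <- unique(gene_set)
  background <- unique(background)
  outside <- setdiff(gene_set, background)
  if (length(outside) > 0) {
    abort(sprintf("gene(s) not in background: %s",
                  paste(head(outside, 5), collapse = ", ")))
  }
  if (length(gene_set) == 0) {
    return(tibble::tibble(
      term_id = character(), term_name = character(), k = integer(),
      K = integer(), n = integer(), N = integer(), odds_ratio = double(),
      p = double(), p_adj = double(), direction = character()
    ))
  }
  tm <- dplyr::distinct(
    term_map[term_map$gene_id %in% background, , drop = FALSE],
    .data$gene_id, .data$term_id, .keep_all = TRUE
  )
  if (!"term_name" %in% names(tm)) tm$term_name <- NA_character_
  n <- length(gene_set)
  N <- length(background)
  out <- tm |>
    dplyr::group_by(.data$term_id, .data$term_name) |>
    dplyr::summarise(
      K = dplyr::n_distinct(.data$gene_id),
      k = sum(unique(.data$gene_id) %in% gene_set),
      .groups = "drop"
    ) |>
    dplyr::mutate(n = n, N = N)
  stats <- purrr::map2(out$k, out$K, function(k, K) {
    tab <- matrix(c(k, n - k, K - k, N - n - K + k), 2)
    ft <- fisher.test(tab, alternative = alternative)
    # exact p can exceed 1 by floating-point roundoff
    list(p = min(ft$p.value, 1), or = unname(ft$estimate))
  })
  out$odds_ratio <- purrr::map_dbl(stats, "or")
  out$p <- purrr::map_dbl(stats, "p")
  out$p_adj <- bh_adjust(out$p)
  out$direction <- ifelse(out$k / n >= out$K / N, "over", "under")
  dplyr::arrange(out, .data$p, .data$term_id) |>
    dplyr::relocate("term_id", "term_name", "k", "K", "n", "N")
}

#' Average-linkage hierarchical clustering of hybridizations
#'
#' Agglomerative clustering of expression profiles with Euclidean distance
#' and average linkage (UPGMA): the distance between two clusters is the
#' mean of all between-cluster pairwise distances. Genes (columns) with any
#' missing value are dropped first.
#'
#' @param profiles Tibble whose first column is the hybridization id and
#'   whose remaining columns are per-gene expression values, or a numeric
#'   matrix with rownames.
#' @return Object of class `hyb_dendrogram` wrapping the [stats::hclust()]
#'   result; supports `tidy()` (merge table with heights), `autoplot()` and
#'   [as_newick()].
#' @export
hierarchical_cluster <- function(profiles) {
  if (inherits(profiles, "data.frame")) {
    labels <- as.character(profiles[[1]])
    x <- as.matrix(profiles[-1])
    rownames(x) <- labels
  } else {
    x <- as.matrix(profiles)
  }
  if (nrow(x) < 2) abort("at least 2 profiles are required")
  keep <- !apply(x, 2, anyNA)
  x <- x[, keep, drop = FALSE]
  if (ncol(x) == 0) abort("no genes without missing values")
  hc <- hclust(dist(x, method = "euclidean"), method = "average")
  structure(list(hclust = hc, n_genes = ncol(x)),
            class = "hyb_dendrogram")
}

#' @export
print.hyb_dendrogram <- function(x, ...) {
  cat(sprintf("<hyb_dendrogram> %d hybridizations, %d genes, average linkage\n",
              length(x$hclust$labels), x$n_genes))
  invisible(x)
}

#' Export a dendrogram as a newick string
#'
#' Branch lengths follow the usual ultrametric convention: each leaf or
#' subtree extends from its merge height to its parent's.
#'
#' @param dendro A `hyb_dendrogram` from [hierarchical_cluster()].
#' @return Newick string (terminated by `;`).
#' @export
as_newick <- function(dendro) {
  hc <- dendro$hclust
  recurse <- function(node, parent_height) {
    if (node < 0) {
      sprintf("%s:%.6g", hc$labels[-node], parent_height)
    } else {
      h <- hc$height[node]
      left <- recurse(hc$merge[node, 1], h)
      right <- recurse(hc$merge[node, 2], h)
      sprintf("(%s,%s):%.6g", left, right, parent_height - h)
    }
  }
  n <- nrow(hc$merge)
  h <- hc$height[n]
  paste0("(", recurse(hc$merge[n, 1], h), ",",
         recurse(hc$merge[n, 2], h), ");")
}
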