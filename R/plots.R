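# ggplot2 graphics for the main result types. Each function returns a
# ggplot object so callers can restyle freely.

#' MA plot of a slide before/after normalization
#'
#' @param normalized Output of [normalize_slides()] (one or more slides).
#' @param slide Optional slide id to restrict to.
#' @return A ggplot: M (raw and normalized) against A.
#' @export
plot_ma <- function(normalized, slide = NULL) {
  df <- normalized
  if (!is.null(slide)) df <- df[df$slide_id == slide, , drop = FALSE]
  long <- tidyr::pivot_longer(df, base::c("M", "M_norm"),
                              names_to = "stage", values_to = "value")
  long$stage <- ifelse(long$stage == "M", "raw", "normalized")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$A, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "red") +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE,
                         linewidth = 0.5, colour = "blue") +
    ggplot2::facet_grid(stage ~ slide_id) +
    ggplot2::labs(x = "A (mean log2 intensity)", y = "M (log2 ratio)")
}

#' @export
autoplot.sam_fit <- function(object, fdr_threshold = 0.05, ...) {
  df <- object$table
  df$significant <- df$fdr <= fdr_threshold
  df$rank <- rank(-abs(df$d), ties.method = "first")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$d,
                                   colour = .data$significant)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "gene rank by |d|", y = "SAM d statistic",
                  colour = sprintf("FDR <= %g", fdr_threshold))
}

#' @export
autoplot.gene_fit <- function(object, alpha = 0.05, ...) {
  df <- tibble::as_tibble(object)
  df <- df[df$testable & is.finite(df$t), , drop = FALSE]
  df$significant <- !is.na(df$p_adj) & df$p_adj <= alpha
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate,
                                   y = -log10(.data$p),
                                   colour = .data$significant)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "mean log2 ratio", y = "-log10 p",
                  colour = sprintf("BH p <= %g", alpha))
}

#' @export
autoplot.cv_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rank_100, y = .data$cv)) +
    ggplot2::geom_point(size = 0.5, alpha = 0.5) +
    ggplot2::geom_vline(xintercept = 90, linetype = 2) +
    ggplot2::labs(x = "CV rank (100-based scale)", y = "CV (%)")
}

#' @export
autoplot.power_grid <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$cv, y = .data$power,
                                       colour = factor(.data$fold))) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.9, linetype = 2) +
    ggplot2::facet_wrap(~ n_per_group, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "CV (%)", y = "power", colour = "fold change")
}

#' @export
autoplot.hyb_dendrogram <- function(object, ...) {
  hc <- object$hclust
  n <- length(hc$labels)
  # x position of each leaf in plotting order
  leaf_x <- setNames(seq_len(n), hc$order)
  node_x <- double(nrow(hc$merge))
  node_y <- hc$height
  seg <- list()
  pos <- function(idx) {
    if (idx < 0) base::c(leaf_x[[as.character(-idx)]], 0)
    else base::c(node_x[idx], node_y[idx])
  }
  for (i in seq_len(nrow(hc$merge))) {
    p1 <- pos(hc$merge[i, 1]); p2 <- pos(hc$merge[i, 2])
    node_x[i] <- (p1[1] + p2[1]) / 2
    seg[[length(seg) + 1]] <- tibble::tibble(
      x = base::c(p1[1], p1[1], p2[1]),
      xend = base::c(p1[1], p2[1], p2[1]),
      y = base::c(p1[2], node_y[i], node_y[i]),
      yend = base::c(node_y[i], node_y[i], p2[2])
    )
  }
  segs <- dplyr::bind_rows(seg)
  labs <- tibble::tibble(x = seq_len(n), label = hc$labels[hc$order])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_text(data = labs,
                       ggplot2::aes(x = .data$x, y = 0, label = .data$label),
                       angle = 90, hjust = 1.1, size = 3) +
    ggplot2::scale_y_continuous("merge height (Euclidean distance)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.title.x = ggplot2::element_blank(),
                   axis.text.x = ggplot2::element_blank())
}
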