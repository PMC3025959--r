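# MA transformation and within-array loess normalization of two-color
# log-ratios. No background subtraction is performed before normalization;
# control spots are excluded from the loess fit.

#' MA transformation of two-channel intensities
#'
#' `M = log2(R/G)`, `A = (log2(R) + log2(G)) / 2`.
#'
#' @param red,green Positive foreground intensities (vectors).
#' @return Tibble with columns `M`, `A`.
#' @export
#' @examples
#' ma_transform(256, 256)
ma_transform <- function(red, green) {
  if (any(red <= 0) || any(green <= 0)) {
    abort("intensities must be strictly positive (filter spots first)")
  }
  tibble::tibble(M = log2(red / green), A = 0.5 * log2(red * green))
}

#' Loess-normalize M values against A
#'
#' Fits a locally weighted regression of M on A (tricube weights, degree 1,
#' symmetric family with 2 robustness iterations) and returns
#' `M' = M - fit(A)`. The fit removes smooth intensity-dependent dye bias;
#' A is untouched.
#'
#' @param ma Tibble with columns `M` and `A` (at least 20 rows).
#' @param span Loess span (fraction of points in each local window).
#' @return `ma` with an added `M_norm` column.
#' @export
loess_normalize <- function(ma, span = 0.4) {
  if (nrow(ma) < 20) {
    abort("at least 20 points are required for loess normalization")
  }
  fit <- loess(M ~ A, data = ma, span = span, degree = 1,
               family = "symmetric",
               control = loess.control(iterations = 2, surface = "direct"))
  ma$M_norm <- ma$M - predict(fit, ma$A)
  ma
}

#' Normalize a set of two-color slides
#'
#' Per slide: computes M and A from the foreground channels of unflagged
#' spots (no background subtraction), fits the loess trend on the
#' non-control (probe) spots only, and subtracts the fitted trend from every
#' probe spot's M.
#'
#' @param spots Spot tibble covering one or more slides (typically the
#'   output of [filter_spots()], or a raw table).
#' @param span Loess span.
#' @return Tibble: `slide_id`, `feature_id`, `M`, `A`, `M_norm` for probe
#'   spots.
#' @export
normalize_slides <- function(spots, span = 0.4) {
  spots |>
    dplyr::filter(.data$Flag == "ok", .data$F_red > 0, .data$F_green > 0,
                  .data$ControlClass == "probe") |>
    dplyr::group_by(.data$Slide) |>
    dplyr::group_modify(function(df, key) {
      ma <- ma_transform(df$F_red, df$F_green)
      ma <- loess_normalize(ma, span = span)
      tibble::tibble(feature_id = df$ID, M = ma$M, A = ma$A,
                     M_norm = ma$M_norm)
    }) |>
    dplyr::ungroup() |>
    dplyr::rename(slide_id = "Slide")
}

#' Assemble the gene expression matrix in tidy form
#'
#' Joins normalized per-slide log-ratios with the hybridization layout so
#' each observation carries its dye orientation. Swapped hybridizations
#' enter downstream contrasts with sign -1.
#'
#' @param normalized Output of [normalize_slides()].
#' @param layout Tibble with `slide_id` and `dye_orientation`
#'   (`"forward"` or `"swapped"`).
#' @return Tibble: `feature_id`, `slide_id`, `M_norm`, `dye_orientation`,
#'   `M_corrected` (orientation-corrected log2 ratio).
#' @export
build_expression_matrix <- function(normalized, layout) {
  missing <- setdiff(unique(normalized$slide_id), layout$slide_id)
  if (length(missing) > 0) {
    abort(sprintf("layout is missing slide(s): %s",
                  paste(missing, collapse = ", ")))
  }
  normalized |>
    dplyr::inner_join(layout[c("slide_id", "dye_orientation")],
                      by = "slide_id") |>
    dplyr::mutate(
      M_corrected = ifelse(.data$dye_orientation == "swapped",
                           -.data$M_norm, .data$M_norm)
    ) |>
    dplyr::select("feature_id", "slide_id", "M_norm", "dye_orientation",
                  "M_corrected")
}
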