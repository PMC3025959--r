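# Spot-level two-color QC: a GenePix-results-like TSV dialect, local
# background summaries, expression calls against the negative-control
# distribution, and the both-channel spot filter.

SPOT_COLUMNS <- c("Slide", "Block", "Row", "Column", "ID", "ControlClass",
                  "F_red", "B_red", "F_green", "B_green", "Flag")

#' Read and write spot tables
#'
#' The spot-table dialect is a strict tab-delimited subset of
#' GenePix-results conventions with mandatory columns `Slide`, `Block`,
#' `Row`, `Column`, `ID`, `ControlClass` (`probe`, `negative`, `empty` or
#' `positive`), per-channel foreground/background `F_red`, `B_red`,
#' `F_green`, `B_green`, and `Flag` (`ok` or `manual_flag`). Unknown extra
#' columns are preserved untouched. Rows with negative intensities are
#' rejected with a warning naming their line numbers; a missing mandatory
#' column is an error naming the column.
#'
#' @param path File path.
#' @param spots Spot tibble in the same dialect.
#' @return `read_spot_table()`: tibble of spot measurements.
#'   `write_spot_table()`: `path`, invisibly.
#' @export
read_spot_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("spot table not found: %s", path))
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(SPOT_COLUMNS, names(tbl))
  if (length(missing) > 0) {
    abort(sprintf("missing mandatory column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  inten <- c("F_red", "B_red", "F_green", "B_green")
  bad <- which(Reduce(`|`, lapply(tbl[inten], function(x) {
    !is.numeric(x) | is.na(x) | x < 0
  })))
  if (length(bad) > 0) {
    warn(sprintf(
      "rejected %d malformed row(s) with negative or non-numeric intensities (file line%s %s)",
      length(bad), if (length(bad) > 1) "s" else "",
      paste(bad + 1L, collapse = ", ")  # +1 for the header line
    ))
    tbl <- tbl[-bad, , drop = FALSE]
  }
  tbl
}

#' @rdname read_spot_table
#' @export
write_spot_table <- function(spots, path) {
  missing <- setdiff(SPOT_COLUMNS, names(spots))
  if (length(missing) > 0) {
    abort(sprintf("missing mandatory column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  readr::write_tsv(spots, path, progress = FALSE)
  invisible(path)
}

#' Local background from surrounding regions
#'
#' The local background of a spot is the median of the median fluorescence
#' intensities of the (up to four) square regions surrounding it; spots at
#' the array edge have fewer neighbours.
#'
#' @param neighborhood Numeric vector of 1-4 surrounding-region medians.
#' @return Numeric scalar.
#' @export
#' @examples
#' local_background(c(1, 2, 3, 4))
local_background <- function(neighborhood) {
  neighborhood <- neighborhood[!is.na(neighborhood)]
  if (length(neighborhood) == 0) {
    abort("no surrounding regions available for local background")
  }
  if (length(neighborhood) > 4) {
    abort("at most 4 surrounding regions are expected")
  }
  median(neighborhood)
}

#' Per-channel expression threshold from negative controls
#'
#' Background noise is defined from the unflagged negative-control (NC)
#' spots of each slide: the expression threshold of a channel is
#' `median(NC) + 2 * SD(NC)` (sample SD). A gene is called expressed when
#' its foreground strictly exceeds this threshold.
#'
#' @param spots Spot tibble (one or more slides).
#' @param sd_multiplier Multiplier of the NC standard deviation.
#' @return Tibble with one row per slide and channel: `Slide`, `channel`,
#'   `nc_median`, `nc_sd`, `threshold`.
#' @export
expression_threshold <- function(spots, sd_multiplier = 2) {
  nc <- dplyr::filter(spots, .data$ControlClass == "negative",
                      .data$Flag == "ok")
  counts <- dplyr::count(nc, .data$Slide)
  short <- unique(c(
    setdiff(unique(spots$Slide), counts$Slide),
    counts$Slide[counts$n < 2]
  ))
  if (length(short) > 0) {
    abort(sprintf("fewer than 2 unflagged negative-control spots on slide(s): %s",
                  paste(short, collapse = ", ")))
  }
  nc |>
    tidyr::pivot_longer(c("F_red", "F_green"), names_to = "channel",
                        values_to = "intensity") |>
    dplyr::mutate(channel = sub("^F_", "", .data$channel)) |>
    dplyr::group_by(.data$Slide, .data$channel) |>
    dplyr::summarise(
      nc_median = median(.data$intensity),
      nc_sd = sd(.data$intensity),
      .groups = "drop"
    ) |>
    dplyr::mutate(threshold = .data$nc_median + sd_multiplier * .data$nc_sd)
}

#' Call expressed genes against the background threshold
#'
#' Adds per-channel logical expression calls (`expressed_red`,
#' `expressed_green`, and `expressed` under the chosen combination rule) to
#' the spot table. The call is strict: foreground must exceed the slide's
#' threshold, not merely reach it. Flagged spots get `NA` calls.
#'
#' @param spots Spot tibble.
#' @param thresholds Output of [expression_threshold()] for the same slides.
#' @param combine How to combine the two channel calls into `expressed`:
#'   per-channel calls are always returned; `"union"` (either channel) or
#'   `"intersection"` (both).
#' @return `spots` with added call columns.
#' @export
call_expressed <- function(spots, thresholds = expression_threshold(spots),
                           combine = c("union", "intersection")) {
  combine <- match.arg(combine)
  thr <- tidyr::pivot_wider(thresholds, id_cols = "Slide",
                            names_from = "channel",
                            values_from = "threshold")
  out <- dplyr::left_join(spots, thr, by = "Slide") |>
    dplyr::mutate(
      expressed_red = ifelse(.data$Flag == "ok", .data$F_red > .data$red, NA),
      expressed_green = ifelse(.data$Flag == "ok",
                               .data$F_green > .data$green, NA),
      expressed = if (combine == "union") {
        .data$expressed_red | .data$expressed_green
      } else {
        .data$expressed_red & .data$expressed_green
      }
    ) |>
    dplyr::select(-"red", -"green")
  out
}

#' Presence call across replicate hybridizations
#'
#' A gene is considered present in an experiment when it is called expressed
#' in at least `k` of the `n` hybridizations (the study fixes `k = 5` of
#' `n = 6`).
#'
#' @param calls Logical vector of per-hybridization expression calls; exactly
#'   `n` values must be supplied.
#' @param k Minimum number of positive calls.
#' @param n Number of hybridizations.
#' @return Logical scalar.
#' @export
#' @examples
#' present_across(c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
present_across <- function(calls, k = 5, n = 6) {
  if (length(calls) != n) {
    abort(sprintf("expected %d calls, got %d", n, length(calls)))
  }
  sum(calls, na.rm = TRUE) >= k
}

#' Filter spots against the empty/negative control distribution
#'
#' Retains probe spots whose foreground exceeds, in BOTH channels, a filter
#' threshold computed per slide and channel from the unflagged empty and
#' negative-control spots: the `percentile` quantile of the control
#' intensities plus `sd_multiplier` times their sample SD. Flagged spots are
#' never retained.
#'
#' The percentile-plus-SD form (defaults: 90th percentile + 2 SD) is this
#' package's reading of the filter rule; both knobs are exposed.
#'
#' @param spots Spot tibble.
#' @param percentile Control-intensity quantile (0-1).
#' @param sd_multiplier Multiplier of the control SD.
#' @return The retained probe spots, with a `filter_thresholds` attribute
#'   (tibble: `Slide`, `channel`, `threshold`).
#' @export
filter_spots <- function(spots, percentile = 0.90, sd_multiplier = 2) {
  assert_prob(percentile)
  ctl <- dplyr::filter(spots, .data$ControlClass %in% c("empty", "negative"),
                       .data$Flag == "ok")
  if (nrow(ctl) == 0) abort("no unflagged empty/negative control spots")
  thr <- ctl |>
    tidyr::pivot_longer(c("F_red", "F_green"), names_to = "channel",
                        values_to = "intensity") |>
    dplyr::mutate(channel = sub("^F_", "", .data$channel)) |>
    dplyr::group_by(.data$Slide, .data$channel) |>
    dplyr::summarise(
      threshold = quantile(.data$intensity, percentile, names = FALSE) +
        sd_multiplier * sd(.data$intensity),
      .groups = "drop"
    )
  thr_wide <- tidyr::pivot_wider(thr, id_cols = "Slide",
                                 names_from = "channel",
                                 values_from = "threshold")
  kept <- dplyr::left_join(spots, thr_wide, by = "Slide") |>
    dplyr::filter(.data$ControlClass == "probe", .data$Flag == "ok",
                  .data$F_red > .data$red, .data$F_green > .data$green) |>
    dplyr::select(-"red", -"green")
  attr(kept, "filter_thresholds") <- thr
  kept
}
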