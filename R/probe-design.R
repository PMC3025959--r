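# One long oligonucleotide per unigene, or a "missing gene". Hard
# constraints: Tm 67 +/- 3 degC, length 65 +/- 5 nt, GC 43 +/- 5%, probe
# 3'-most base within 1000 nt of the unigene 3' end, and caps on hairpin
# stem / self-dimer lengths. Among feasible windows the one minimising a
# weighted distance from the targets is selected.

# Unified nearest-neighbor parameter table: dH in kcal/mol, dS in cal/(mol K)
NN_DH <- c(
  AA = -7.9, AT = -7.2, AC = -8.4, AG = -7.8,
  TA = -7.2, TT = -7.9, TC = -8.2, TG = -8.5,
  CA = -8.5, CT = -7.8, CC = -8.0, CG = -10.6,
  GA = -8.2, GT = -8.4, GC = -9.8, GG = -8.0
)
NN_DS <- c(
  AA = -22.2, AT = -20.4, AC = -22.4, AG = -21.0,
  TA = -21.3, TT = -22.2, TC = -22.2, TG = -22.7,
  CA = -22.7, CT = -21.0, CC = -19.9, CG = -27.2,
  GA = -22.2, GT = -22.4, GC = -24.4, GG = -19.9
)
# duplex initiation terms per terminal base
INIT_DH <- c(A = 2.3, T = 2.3, C = 0.1, G = 0.1)
INIT_DS <- c(A = 4.1, T = 4.1, C = -2.8, G = -2.8)
GAS_R <- 1.9872  # cal/(mol K)

#' GC content of DNA sequences
#'
#' @param seq Character vector of unambiguous DNA sequences.
#' @return Numeric vector: percent G+C.
#' @export
#' @examples
#' gc_content("ACGTACGTGG")
gc_content <- function(seq) {
  assert_dna(seq)
  vapply(seq, function(s) {
    b <- strsplit(s, "")[[1]]
    100 * sum(b %in% c("G", "C")) / length(b)
  }, double(1), USE.NAMES = FALSE)
}

#' Nearest-neighbor melting temperature
#'
#' Melting temperature of the perfect DNA duplex under unified
#' nearest-neighbor thermodynamics with a monovalent-salt entropy correction
#' (`0.368 * (L - 1) * ln[Na+]`) and the duplex-fraction term
#' `R * ln(CT / 4)` for non-self-complementary strands:
#'
#' `Tm = 1000 * dH / (dS_salt + R * ln(CT / 4)) - 273.15`
#'
#' The default 50 mM monovalent salt reflects typical hybridization-buffer
#' ionic strength and is the regime in which the design windows
#' (Tm 67 +/- 3 degC at GC 43 +/- 5% for 65-mers) are mutually consistent;
#' both parameters are exposed because vendor Tm models vary.
#'
#' @param seq Character vector of unambiguous DNA sequences, each >= 8 nt
#'   (the nearest-neighbor model is unreliable below that).
#' @param na_mM Monovalent cation concentration in mM.
#' @param oligo_nM Total oligonucleotide concentration in nM.
#' @return Numeric vector of Tm in degrees Celsius.
#' @export
#' @examples
#' melting_temperature("AGCGTAAGCTAGCGTAAGCT")
melting_temperature <- function(seq, na_mM = 50, oligo_nM = 50) {
  assert_dna(seq)
  if (any(nchar(seq) < 8)) {
    abort("sequences must be at least 8 nt for the nearest-neighbor model")
  }
  vapply(seq, function(s) {
    b <- strsplit(s, "")[[1]]
    steps <- paste0(b[-length(b)], b[-1])
    dh <- sum(NN_DH[steps]) + INIT_DH[b[1]] + INIT_DH[b[length(b)]]
    ds <- sum(NN_DS[steps]) + INIT_DS[b[1]] + INIT_DS[b[length(b)]]
    ds_salt <- ds + 0.368 * (length(b) - 1) * log(na_mM / 1000)
    1000 * dh / (ds_salt + GAS_R * log(oligo_nM * 1e-9 / 4)) - 273.15
  }, double(1), USE.NAMES = FALSE)
}

#' Secondary-structure scores of an oligonucleotide
#'
#' Two exact-pairing scores used to limit probe secondary structure:
#' `stem_score`, the longest run of intramolecular Watson-Crick pairs whose
#' innermost pair encloses at least `min_loop` unpaired bases (a hairpin
#' stem), and `selfdimer_score`, the longest contiguous reverse-complementary
#' pairing between two copies of the sequence (no loop constraint; computed
#' as the longest common substring of the sequence and its reverse
#' complement).
#'
#' @param seq Character vector of DNA sequences.
#' @param min_loop Minimum hairpin loop length in nt.
#' @return Tibble with columns `stem_score`, `selfdimer_score` (nt).
#' @export
secondary_structure_scores <- function(seq, min_loop = 3) {
  assert_dna(seq)
  rc <- revcomp(seq)
  tibble::tibble(
    stem_score = vapply(seq, .stem_score_cpp, integer(1),
                        min_loop = as.integer(min_loop), USE.NAMES = FALSE),
    selfdimer_score = mapply(.lcs_length_cpp, seq, rc, USE.NAMES = FALSE)
  )
}

#' Probe design constraints
#'
#' Container for the physicochemical and positional constraints of probe
#' selection, with the array's published design windows as defaults.
#'
#' @param tm_target,tm_tol Melting temperature target and tolerance (degC).
#' @param length_target,length_tol Probe length target and tolerance (nt).
#' @param gc_target,gc_tol GC content target and tolerance (percent).
#' @param max_dist_3prime Maximum distance (nt) from the probe's 3'-most base
#'   to the unigene 3' end.
#' @param max_stem,max_selfdimer Caps on the secondary-structure scores (nt).
#' @param min_loop Minimum hairpin loop (nt) for the stem score.
#' @param na_mM,oligo_nM Tm model parameters, see [melting_temperature()].
#' @param weights Named numeric rank weights `tm`, `gc`, `stem`, `selfdimer`,
#'   `dist3`: the rank score is
#'   `w_tm*|tm - tm_target| + w_gc*|gc - gc_target| + w_stem*stem +
#'   w_selfdimer*selfdimer + w_dist3*dist_3prime`. Constraint closeness
#'   dominates; the small 3'-distance weight breaks near-ties in favour of
#'   3'-proximal windows.
#' @return A list of class `probe_constraints`.
#' @export
probe_constraints <- function(tm_target = 67, tm_tol = 3,
                              length_target = 65, length_tol = 5,
                              gc_target = 43, gc_tol = 5,
                              max_dist_3prime = 1000,
                              max_stem = 8, max_selfdimer = 12,
                              min_loop = 3, na_mM = 50, oligo_nM = 50,
                              weights = c(tm = 1, gc = 1, stem = 1,
                                          selfdimer = 1, dist3 = 0.001)) {
  if (tm_tol < 0 || length_tol < 0 || gc_tol < 0) {
    abort("tolerances must be >= 0")
  }
  if (length_target - length_tol < 20) {
    abort("`length_target - length_tol` must be >= 20")
  }
  structure(list(
    tm_target = tm_target, tm_tol = tm_tol,
    length_target = length_target, length_tol = length_tol,
    gc_target = gc_target, gc_tol = gc_tol,
    max_dist_3prime = max_dist_3prime,
    max_stem = max_stem, max_selfdimer = max_selfdimer,
    min_loop = min_loop, na_mM = na_mM, oligo_nM = oligo_nM,
    weights = weights
  ), class = "probe_constraints")
}

# Vectorised per-window Tm and GC via cumulative sums over the sequence
window_thermo <- function(chars, starts, lens, na_mM, oligo_nM) {
  n <- length(chars)
  gc_cum <- c(0, cumsum(chars %in% c("G", "C")))
  steps <- paste0(chars[-n], chars[-1])
  dh_cum <- c(0, cumsum(NN_DH[steps]))
  ds_cum <- c(0, cumsum(NN_DS[steps]))
  ends <- starts + lens - 1L
  gc <- 100 * (gc_cum[ends + 1L] - gc_cum[starts]) / lens
  dh <- dh_cum[ends] - dh_cum[starts] +
    INIT_DH[chars[starts]] + INIT_DH[chars[ends]]
  ds <- ds_cum[ends] - ds_cum[starts] +
    INIT_DS[chars[starts]] + INIT_DS[chars[ends]]
  ds_salt <- ds + 0.368 * (lens - 1) * log(na_mM / 1000)
  tm <- 1000 * dh / (ds_salt + GAS_R * log(oligo_nM * 1e-9 / 4)) - 273.15
  list(tm = unname(tm), gc = unname(gc))
}

#' Enumerate annotated probe candidate windows
#'
#' All windows of a unigene whose length lies within the constraint window
#' and whose 3'-most base is within `max_dist_3prime` nt of the unigene
#' 3' end, annotated with Tm, GC and secondary-structure scores. Ordered by
#' start, then length. A unigene shorter than the minimum probe length
#' yields an empty tibble.
#'
#' @param sequence Unigene sequence (character scalar).
#' @param constraints A [probe_constraints()] object.
#' @param structure Compute secondary-structure scores (set `FALSE` to defer
#'   them; [select_probe()] computes them only for Tm/GC-feasible windows).
#' @return Tibble: `start` (0-based), `length`, `sequence`, `tm`, `gc`,
#'   `dist_3prime`, and if `structure` is `TRUE` also `stem_score`,
#'   `selfdimer_score`.
#' @export
enumerate_candidates <- function(sequence, constraints = probe_constraints(),
                                 structure = TRUE) {
  c_ <- constraints
  assert_dna(sequence)
  n <- nchar(sequence)
  lens <- seq(c_$length_target - c_$length_tol,
              c_$length_target + c_$length_tol)
  lens <- lens[lens <= n]
  if (length(lens) == 0) {
    return(tibble::tibble(
      start = integer(), length = integer(), sequence = character(),
      tm = double(), gc = double(), dist_3prime = integer()
    ))
  }
  chars <- strsplit(sequence, "")[[1]]
  grids <- lapply(lens, function(L) {
    # 1-based starts; dist_3prime = n - (start0 + L) <= max_dist_3prime
    min_start1 <- max(1L, n - c_$max_dist_3prime - L + 1L)
    tibble::tibble(start1 = seq(min_start1, n - L + 1L), length = L)
  })
  grid <- dplyr::bind_rows(grids)
  th <- window_thermo(chars, grid$start1, grid$length, c_$na_mM, c_$oligo_nM)
  out <- tibble::tibble(
    start = grid$start1 - 1L,
    length = as.integer(grid$length),
    sequence = substring(sequence, grid$start1, grid$start1 + grid$length - 1L),
    tm = th$tm,
    gc = th$gc,
    dist_3prime = as.integer(n - (grid$start1 - 1L + grid$length))
  ) |>
    dplyr::arrange(.data$start, .data$length)
  if (structure) {
    out <- dplyr::bind_cols(
      out, secondary_structure_scores(out$sequence, c_$min_loop)
    )
  }
  out
}

#' Select the probe for one unigene
#'
#' Among candidate windows satisfying all hard constraints (Tm and GC within
#' tolerance, structure scores at or below their caps; length and
#' 3'-distance are enforced by the enumeration), returns the window with the
#' smallest rank score (see [probe_constraints()]), breaking ties by smaller
#' `dist_3prime` then smaller `start`. If no window exists at all the
#' unigene is reported missing with reason `"too_short"`; if windows exist
#' but none is feasible, with reason `"no_window_meets_constraints"`.
#'
#' @inheritParams enumerate_candidates
#' @param unigene_id Identifier carried into the outcome row.
#' @return One-row tibble: `unigene_id`, `outcome` (`"designed"` or
#'   `"missing"`), `missing_reason`, and for designed probes `start`,
#'   `length`, `sequence`, `tm`, `gc`, `stem_score`, `selfdimer_score`,
#'   `dist_3prime`, `rank_score`.
#' @export
select_probe <- function(sequence, constraints = probe_constraints(),
                         unigene_id = NA_character_) {
  c_ <- constraints
  cand <- enumerate_candidates(sequence, c_, structure = FALSE)
  missing_row <- function(reason) {
    tibble::tibble(
      unigene_id = unigene_id, outcome = "missing", missing_reason = reason,
      start = NA_integer_, length = NA_integer_, sequence = NA_character_,
      tm = NA_real_, gc = NA_real_, stem_score = NA_integer_,
      selfdimer_score = NA_integer_, dist_3prime = NA_integer_,
      rank_score = NA_real_
    )
  }
  if (nrow(cand) == 0) return(missing_row("too_short"))
  ok <- abs(cand$tm - c_$tm_target) <= c_$tm_tol &
    abs(cand$gc - c_$gc_target) <= c_$gc_tol
  cand <- cand[ok, , drop = FALSE]
  if (nrow(cand) == 0) return(missing_row("no_window_meets_constraints"))
  cand <- dplyr::bind_cols(
    cand, secondary_structure_scores(cand$sequence, c_$min_loop)
  )
  feas <- cand$stem_score <= c_$max_stem &
    cand$selfdimer_score <= c_$max_selfdimer
  cand <- cand[feas, , drop = FALSE]
  if (nrow(cand) == 0) return(missing_row("no_window_meets_constraints"))
  w <- c_$weights
  cand$rank_score <- w[["tm"]] * abs(cand$tm - c_$tm_target) +
    w[["gc"]] * abs(cand$gc - c_$gc_target) +
    w[["stem"]] * cand$stem_score +
    w[["selfdimer"]] * cand$selfdimer_score +
    w[["dist3"]] * cand$dist_3prime
  cand <- dplyr::arrange(cand, .data$rank_score, .data$dist_3prime,
                         .data$start)
  best <- cand[1, ]
  tibble::tibble(
    unigene_id = unigene_id, outcome = "designed", missing_reason = "none",
    start = best$start, length = best$length, sequence = best$sequence,
    tm = best$tm, gc = best$gc, stem_score = best$stem_score,
    selfdimer_score = best$selfdimer_score, dist_3prime = best$dist_3prime,
    rank_score = best$rank_score
  )
}

#' Design one probe per unigene
#'
#' Applies [select_probe()] to every unigene. The output partitions the
#' input: every unigene appears exactly once, either designed or missing
#' with a reason (the array's "missing genes" bookkeeping).
#'
#' @param unigenes Tibble with columns `id`, `sequence`.
#' @param constraints A [probe_constraints()] object.
#' @return Design report tibble, one row per unigene (see [select_probe()]),
#'   with a `probe_id` column (`<unigene id>_probe`) for designed rows.
#' @export
design_probes <- function(unigenes, constraints = probe_constraints()) {
  if (nrow(unigenes) == 0) {
    empty <- select_probe("A", probe_constraints(), "x")[0, ]
    empty$probe_id <- character()
    return(dplyr::relocate(empty, "probe_id", .after = "unigene_id"))
  }
  out <- purrr::map2(unigenes$sequence, unigenes$id,
                     function(s, id) select_probe(s, constraints, id)) |>
    dplyr::bind_rows()
  out$probe_id <- ifelse(out$outcome == "designed",
                         paste0(out$unigene_id, "_probe"), NA_character_)
  dplyr::relocate(out, "probe_id", .after = "unigene_id")
}
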