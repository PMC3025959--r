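# Seeded simulators for every input the toolkit consumes. Each generator
# returns the simulated data together with a ground-truth table, so recovery
# tests score results against construction rather than re-deriving truth.

#' Simulate a unigene set with planted homologous blocks
#'
#' Generates random unigene sequences and, optionally, plants homologous
#' blocks between pairs of them with an exactly realised identity percentage
#' and block length (constructed by copying a block and mutating a fixed
#' number of evenly spaced positions, not by sampling mismatches).
#'
#' The default base composition is AT-rich (40% GC), typical of plant
#' EST-derived 3' sequence.
#'
#' @param n_unigenes Number of sequences.
#' @param seed Integer seed; the same seed yields byte-identical output.
#' @param length_range Length range in nt, sampled uniformly.
#' @param gc Expected GC fraction of the random background.
#' @param homology Optional tibble with columns `id_a`, `id_b`,
#'   `identity` (percent) and `length` (nt) describing blocks to plant.
#'   Ids refer to `UG0001`-style identifiers assigned in order.
#' @return A list with elements `unigenes` (tibble: `id`, `sequence`,
#'   `length`) and `homology` (tibble of planted blocks with realised
#'   identity and 0-based block coordinates in both members).
#' @export
#' @examples
#' fx <- simulate_unigenes(5, seed = 1)
#' fx$unigenes
simulate_unigenes <- function(n_unigenes = 30, seed = 1,
                              length_range = c(400, 1500), gc = 0.40,
                              homology = NULL) {
  assert_count(n_unigenes, min = 1)
  if (length(length_range) != 2 || length_range[1] > length_range[2]) {
    abort("`length_range` must be c(min, max) with min <= max")
  }
  with_seed(seed, {
    lens <- sample(seq(length_range[1], length_range[2]), n_unigenes,
                   replace = TRUE)
    ids <- sprintf("UG%04d", seq_len(n_unigenes))
    probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    seqs <- vapply(lens, function(L) {
      paste(sample(BASES, L, replace = TRUE, prob = probs), collapse = "")
    }, character(1))
    names(seqs) <- ids

    truth <- tibble::tibble(
      id_a = character(), id_b = character(), identity = double(),
      length = integer(), start_a = integer(), start_b = integer()
    )
    if (!is.null(homology) && nrow(homology) > 0) {
      for (r in seq_len(nrow(homology))) {
        ia <- homology$id_a[r]; ib <- homology$id_b[r]
        L <- as.integer(homology$length[r])
        if (!ia %in% ids || !ib %in% ids) {
          abort(sprintf("homology row %d names an unknown unigene id", r))
        }
        if (L > nchar(seqs[ia]) || L > nchar(seqs[ib])) {
          abort(sprintf(
            "homology row %d: block length %d exceeds a member sequence", r, L
          ))
        }
        start_a <- sample.int(nchar(seqs[ia]) - L + 1, 1)
        block <- strsplit(substr(seqs[ia], start_a, start_a + L - 1), "")[[1]]
        n_mut <- round((1 - homology$identity[r] / 100) * L)
        if (n_mut > 0) {
          # evenly spaced mutation sites; deterministic base rotation
          at <- unique(round(seq(1, L, length.out = n_mut)))
          while (length(at) < n_mut) {
            at <- unique(c(at, setdiff(seq_len(L), at)[1]))
          }
          idx <- match(block[at], BASES)
          block[at] <- BASES[idx %% 4 + 1]
        }
        start_b <- sample.int(nchar(seqs[ib]) - L + 1, 1)
        substr(seqs[ib], start_b, start_b + L - 1) <-
          paste(block, collapse = "")
        truth <- dplyr::bind_rows(truth, tibble::tibble(
          id_a = ia, id_b = ib,
          identity = 100 * (L - n_mut) / L,
          length = L, start_a = start_a - 1L, start_b = start_b - 1L
        ))
      }
    }
    list(
      unigenes = tibble::tibble(id = ids, sequence = unname(seqs),
                                length = nchar(seqs)),
      homology = truth
    )
  })
}

#' Simulate dye-swapped two-color slides with known truth
#'
#' Builds spot tables for a one-contrast dye-swap experiment: `n_slides`
#' hybridizations of the same two samples with alternating dye orientation
#' (the study layout is 3 biological replicates x 2 dyes = 6 slides per
#' contrast). Negative-control and empty spots are drawn from a Gaussian
#' truncated at zero; probe spots carry planted log2 fold changes, Gaussian
#' log-ratio noise and a smooth intensity-dependent dye bias added to M.
#'
#' @param n_genes Number of probe features.
#' @param n_slides Number of hybridizations (dye orientation alternates).
#' @param seed Integer seed.
#' @param n_negative_controls,n_empty Numbers of negative-control and empty
#'   spots per slide (at least 2 negative controls are required, otherwise
#'   their SD is undefined).
#' @param nc_mean,nc_sd Mean and SD of the control fluorescence distribution.
#' @param dye_bias_amplitude Amplitude (log2 units) of the smooth dye bias
#'   added to M as a quadratic function of A.
#' @param n_de_genes Number of genes given a planted fold change.
#' @param de_log2_fold Planted log2 fold change(s), recycled over DE genes.
#' @param noise_sd SD (log2 units) of the per-spot log-ratio noise.
#' @param a_range Range of per-gene mean log2 intensity A.
#' @return A list: `spots` (tidy spot table, one row per spot per slide, in
#'   the column dialect of [read_spot_table()]), `layout` (slide id,
#'   replicate, dye orientation), `truth` (feature id, planted log2 fold) and
#'   `params`.
#' @export
simulate_two_color_slides <- function(n_genes = 500, n_slides = 6, seed = 1,
                                      n_negative_controls = 50, n_empty = 10,
                                      nc_mean = 100, nc_sd = 20,
                                      dye_bias_amplitude = 0.5,
                                      n_de_genes = 0, de_log2_fold = 1,
                                      noise_sd = 0.3, a_range = c(8, 14)) {
  assert_count(n_genes, min = 1)
  assert_count(n_slides, min = 1)
  if (n_negative_controls < 2) {
    abort("at least 2 negative-control spots are required (SD undefined)")
  }
  with_seed(seed, {
    gene_ids <- sprintf("G%04d", seq_len(n_genes))
    theta <- rep(0, n_genes)
    if (n_de_genes > 0) {
      theta[seq_len(n_de_genes)] <- rep_len(de_log2_fold, n_de_genes)
    }
    a_base <- runif(n_genes, a_range[1], a_range[2])
    orientation <- rep_len(c(1, -1), n_slides)
    layout <- tibble::tibble(
      slide_id = sprintf("S%02d", seq_len(n_slides)),
      replicate = (seq_len(n_slides) + 1L) %/% 2L,
      dye_orientation = ifelse(orientation == 1, "forward", "swapped")
    )

    n_ctl <- n_negative_controls + n_empty
    ctl_class <- c(rep("negative", n_negative_controls), rep("empty", n_empty))
    ctl_ids <- c(sprintf("NC%03d", seq_len(n_negative_controls)),
                 sprintf("EMPTY%03d", seq_len(n_empty)))
    n_spots <- n_genes + n_ctl

    per_slide <- lapply(seq_len(n_slides), function(s) {
      A <- a_base + rnorm(n_genes, 0, 0.05)
      z <- (A - mean(a_range)) / (diff(a_range) / 2)
      bias <- dye_bias_amplitude * (z^2 - z) / 2
      M <- orientation[s] * theta + bias + rnorm(n_genes, 0, noise_sd)
      f_red <- 2^(A + M / 2)
      f_green <- 2^(A - M / 2)
      nc_red <- pmax(rnorm(n_ctl, nc_mean, nc_sd), 0)
      nc_green <- pmax(rnorm(n_ctl, nc_mean, nc_sd), 0)
      idx <- seq_len(n_spots)
      tibble::tibble(
        Slide = layout$slide_id[s],
        Block = 1L,
        Row = (idx - 1L) %/% 40L + 1L,
        Column = (idx - 1L) %% 40L + 1L,
        ID = c(gene_ids, ctl_ids),
        ControlClass = c(rep("probe", n_genes), ctl_class),
        F_red = c(f_red, nc_red),
        B_red = pmax(rnorm(n_spots, nc_mean / 2, nc_sd / 2), 0),
        F_green = c(f_green, nc_green),
        B_green = pmax(rnorm(n_spots, nc_mean / 2, nc_sd / 2), 0),
        Flag = "ok"
      )
    })

    list(
      spots = dplyr::bind_rows(per_slide),
      layout = layout,
      truth = tibble::tibble(feature_id = gene_ids, log2_fold = theta),
      params = list(
        n_genes = n_genes, n_slides = n_slides, seed = seed,
        n_negative_controls = n_negative_controls, n_empty = n_empty,
        nc_mean = nc_mean, nc_sd = nc_sd,
        dye_bias_amplitude = dye_bias_amplitude, noise_sd = noise_sd
      )
    )
  })
}

#' Simulate a qPCR Ct table with stable reference genes
#'
#' Reference genes have a constant expected Ct across samples; each target
#' gene's Ct is offset from the reference mean by minus its planted log2
#' expression (one cycle per 2-fold change at 100% amplification efficiency).
#'
#' @param n_targets,n_samples,n_reference Table dimensions. At least 3
#'   reference genes are required.
#' @param n_technical Technical replicates per (gene, sample).
#' @param seed Integer seed.
#' @param ct_noise_sd Ct noise SD in cycles (0 gives exact planted folds).
#' @param ref_ct Mean reference-gene Ct.
#' @param log2_expression Optional matrix (`n_targets` x `n_samples`) of
#'   planted log2 expression values; defaults to uniform draws in [-2, 2].
#' @return List with `ct` (tibble: `gene_id`, `sample_id`, `ct`,
#'   `is_reference`, `technical_replicate`) and `truth` (planted log2
#'   expression per gene and sample).
#' @export
simulate_ct_table <- function(n_targets = 12, n_samples = 3, n_reference = 3,
                              n_technical = 2, seed = 1, ct_noise_sd = 0.2,
                              ref_ct = 21, log2_expression = NULL) {
  assert_count(n_targets, min = 1)
  assert_count(n_samples, min = 1)
  if (n_reference < 3) abort("at least 3 reference genes are required")
  with_seed(seed, {
    samples <- sprintf("sample%d", seq_len(n_samples))
    refs <- sprintf("REF%d", seq_len(n_reference))
    targets <- sprintf("T%03d", seq_len(n_targets))
    if (is.null(log2_expression)) {
      log2_expression <- matrix(runif(n_targets * n_samples, -2, 2),
                                n_targets, n_samples)
    }
    # small constant per-reference offsets that cancel in the geometric mean
    ref_off <- seq(-0.5, 0.5, length.out = n_reference)
    ref_off <- ref_off - mean(ref_off)

    grid <- tidyr::expand_grid(
      gene_id = c(refs, targets),
      sample_id = samples,
      technical_replicate = seq_len(n_technical)
    )
    is_ref <- grid$gene_id %in% refs
    gi <- match(grid$gene_id, targets)
    si <- match(grid$sample_id, samples)
    expected <- ifelse(
      is_ref,
      ref_ct + ref_off[match(grid$gene_id, refs)],
      ref_ct - log2_expression[cbind(gi, si)]
    )
    ct <- expected + rnorm(nrow(grid), 0, ct_noise_sd)
    truth <- tibble::tibble(
      gene_id = rep(targets, times = n_samples),
      sample_id = rep(samples, each = n_targets),
      log2_expression = as.vector(log2_expression)
    )
    list(
      ct = tibble::tibble(
        gene_id = grid$gene_id, sample_id = grid$sample_id, ct = ct,
        is_reference = is_ref,
        technical_replicate = grid$technical_replicate
      ),
      truth = truth
    )
  })
}
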