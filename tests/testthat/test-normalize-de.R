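# MA transformation, loess dye-bias removal, per-gene linear fits, the SAM
# permutation test and BH adjustment, against hand computations, an
# independent binned-trend check and the simulators' truth tables.

test_that("MA transformation matches hand log2 computation", {
  expect_equal(ma_transform(256, 256), tibble::tibble(M = 0, A = 8))
  expect_equal(ma_transform(64, 16), tibble::tibble(M = 2, A = 5))
  fwd <- ma_transform(300, 70)
  swp <- ma_transform(70, 300)
  expect_equal(swp$M, -fwd$M)
  expect_equal(swp$A, fwd$A)
  expect_error(ma_transform(0, 10), "positive")
})

test_that("loess normalization removes a constant offset exactly", {
  withr::with_seed(1, {
    ma <- tibble::tibble(A = runif(200, 6, 14), M = 0.7)
  })
  out <- loess_normalize(ma)
  interior <- out$A > 7 & out$A < 13
  expect_lt(max(abs(out$M_norm[interior])), 1e-6)
  expect_error(loess_normalize(ma[1:10, ]), "at least 20")
})

test_that("planted smooth dye bias is removed, planted DE is preserved", {
  sl <- simulate_two_color_slides(n_genes = 600, n_slides = 1, seed = 41,
                                  dye_bias_amplitude = 0.8, n_de_genes = 1,
                                  de_log2_fold = 1, noise_sd = 0.15)
  norm <- normalize_slides(sl$spots)
  # independent check: median normalized M within each A-decile stays near 0
  null_genes <- norm[!norm$feature_id %in% "G0001", ]
  dec <- cut(null_genes$A, quantile(null_genes$A, 0:10 / 10),
             include.lowest = TRUE)
  med_by_dec <- tapply(null_genes$M_norm, dec, median)
  expect_lt(max(abs(med_by_dec)), 0.05)
  # before normalization the bias is visible
  med_raw <- tapply(null_genes$M, dec, median)
  expect_gt(max(abs(med_raw)), 0.1)
  # the single planted DE gene keeps its fold
  de_m <- norm$M_norm[norm$feature_id == "G0001"]
  expect_lt(abs(de_m - 1), 0.2)
  # A is never changed by normalization
  expect_equal(norm$A, ma_transform(
    sl$spots$F_red[sl$spots$ControlClass == "probe"],
    sl$spots$F_green[sl$spots$ControlClass == "probe"]
  )$A)
})

test_that("dye orientation correction flips swapped hybridizations", {
  norm <- tibble::tibble(
    slide_id = c("S1", "S2"), feature_id = "G1",
    M = c(1, -1), A = 10, M_norm = c(1, -1)
  )
  layout <- tibble::tibble(slide_id = c("S1", "S2"),
                           dye_orientation = c("forward", "swapped"))
  mat <- build_expression_matrix(norm, layout)
  expect_equal(mat$M_corrected, c(1, 1))
  expect_error(build_expression_matrix(norm, layout[1, ]), "missing slide")
})

test_that("per-gene linear fit matches hand t computation", {
  mat <- tibble::tibble(
    feature_id = rep(c("g1", "g2", "g3"), each = 3),
    slide_id = rep(c("S1", "S2", "S3"), 3),
    M_corrected = c(1.0, 1.2, 0.8, 0, 0, 0, 0.5, 0.5, 0.5)
  )
  fit <- per_gene_linear_fit(mat)
  g1 <- fit[fit$feature_id == "g1", ]
  expect_equal(g1$estimate, 1.0)
  expect_equal(g1$t, 1.0 / (0.2 / sqrt(3)), tolerance = 1e-12)
  expect_equal(g1$p, 2 * pt(-abs(g1$t), df = 2))
  # all-zero observations: degenerate but defined
  g2 <- fit[fit$feature_id == "g2", ]
  expect_equal(g2$t, 0)
  expect_equal(g2$p, 1)
  # zero SD with nonzero mean: untestable by t, excluded from BH
  g3 <- fit[fit$feature_id == "g3", ]
  expect_equal(g3$t, Inf)
  expect_true(is.na(g3$p_adj))
  # fewer than 2 observations -> untestable
  fit1 <- per_gene_linear_fit(mat[c(1, 4, 5), ])
  expect_false(fit1$testable[fit1$feature_id == "g1"])
})

test_that("BH adjustment equals the hand step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  withr::with_seed(14, {
    for (trial in 1:10) {
      p <- runif(sample(3:50, 1))
      expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
    }
  })
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  expect_error(bh_adjust(c(0.5, NA)), "0, 1")
})

test_that("SAM d with s0 = 0 is the t statistic scaled by sqrt(n)", {
  withr::with_seed(3, {
    mat <- tibble::tibble(
      feature_id = rep(sprintf("g%02d", 1:20), each = 6),
      slide_id = rep(sprintf("S%d", 1:6), 20),
      M_corrected = rnorm(120)
    )
  })
  sam <- sam_test(mat, n_permutations = 50, seed = 2, s0_quantile = 0)
  fit <- per_gene_linear_fit(mat)
  joined <- dplyr::inner_join(tidy(sam), tibble::as_tibble(fit),
                              by = "feature_id")
  # s0 = min(s) > 0 at quantile 0; rebuild d with s0 = 0 from components
  d0 <- joined$estimate.x / joined$s
  expect_equal(d0 * sqrt(6), joined$t, tolerance = 1e-12)
  # reproducibility for a fixed seed
  sam2 <- sam_test(mat, n_permutations = 50, seed = 2, s0_quantile = 0)
  expect_identical(tidy(sam), tidy(sam2))
  expect_error(sam_test(mat, n_permutations = 5), "at least 10")
})

test_that("SAM recovers planted DE genes and FDR is monotone in |d|", {
  sl <- simulate_two_color_slides(n_genes = 500, n_slides = 6, seed = 7,
                                  n_de_genes = 50, de_log2_fold = 2,
                                  noise_sd = 0.3)
  mat <- build_expression_matrix(normalize_slides(filter_spots(sl$spots)),
                                 sl$layout)
  sam <- sam_test(mat, n_permutations = 200, seed = 3)
  tt <- dplyr::inner_join(tidy(sam), sl$truth, by = "feature_id")
  planted <- tt[tt$log2_fold == 2, ]
  expect_gte(sum(planted$fdr <= 0.01), 45)
  # FDR non-increasing in |d|
  o <- order(abs(tt$d), decreasing = TRUE)
  expect_true(all(diff(tt$fdr[o]) >= -1e-12))
})

test_that("planted log2 folds are recovered with small bias and RMSE", {
  # mostly-null fixture with balanced up/down folds; a large
  # one-directional DE fraction would let the loess trend absorb part of
  # the fold, which is a property of the normalization, not an error
  sl <- simulate_two_color_slides(n_genes = 600, n_slides = 6, seed = 29,
                                  n_de_genes = 30,
                                  de_log2_fold = c(1, -1),
                                  noise_sd = 0.3)
  mat <- build_expression_matrix(normalize_slides(filter_spots(sl$spots)),
                                 sl$layout)
  fit <- per_gene_linear_fit(mat)
  est <- dplyr::inner_join(tibble::as_tibble(fit), sl$truth,
                           by = "feature_id")
  de <- est[est$log2_fold != 0, ]
  expect_equal(nrow(de), 30)
  expect_lt(abs(mean(de$estimate - de$log2_fold)), 0.05)
  expect_lt(sqrt(mean((de$estimate - de$log2_fold)^2)), 0.15)
})

test_that("consensus is the intersection with matching comparisons", {
  la <- de_gene_list(c("g1", "g2", "g3"), "flower_vs_leaf",
                     "linear_model", 0.01)
  sa <- de_gene_list(c("g2", "g3", "g4"), "flower_vs_leaf",
                     "permutation", 0.01)
  cons <- consensus_lists(la, sa)
  expect_setequal(cons$gene_id, c("g2", "g3"))
  expect_equal(unique(cons$method), "consensus")
  # subset relation and disjoint lists
  expect_setequal(
    consensus_lists(de_gene_list("g1", "x", "linear_model", 0.01),
                    de_gene_list(c("g1", "g9"), "x", "permutation", 0.01))$gene_id,
    "g1"
  )
  empty <- consensus_lists(de_gene_list("g1", "x", "linear_model", 0.01),
                           de_gene_list("g7", "x", "permutation", 0.01))
  expect_equal(nrow(empty), 0)
  expect_error(
    consensus_lists(la, de_gene_list("g1", "other", "permutation", 0.01)),
    "mismatch"
  )
  withr::with_seed(9, {
    aa <- sample(letters, 12); bb <- sample(letters, 12)
  })
  expect_setequal(
    consensus_lists(de_gene_list(aa, "x", "linear_model", 0.05),
                    de_gene_list(bb, "x", "permutation", 0.05))$gene_id,
    intersect(aa, bb)
  )
})
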