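# GC, nearest-neighbor Tm, structure scores, candidate enumeration and
# probe selection, each against direct hand computation or brute force.

test_that("gc_content counts bases and rejects ambiguity", {
  expect_equal(gc_content("ATATAT"), 0)
  expect_equal(gc_content("GCGC"), 100)
  expect_equal(gc_content("ACGTACGTGG"), 60)
  expect_equal(gc_content(c("AA", "GG")), c(0, 100))
  expect_error(gc_content("ACGN"), "A,C,G,T")
})

test_that("melting temperature matches a hand table-sum of unified NN terms", {
  # independent hand sum with its own copy of the published unified table
  dh <- c(AG = -7.8, GC = -9.8, CG = -10.6, GT = -8.4, TA = -7.2,
          AA = -7.9, AG2 = -7.8, GC2 = -9.8, CT = -7.8)
  ds <- c(AG = -21.0, GC = -24.4, CG = -27.2, GT = -22.4, TA = -21.3,
          AA = -22.2, AG2 = -21.0, GC2 = -24.4, CT = -21.0)
  # AGCGTAAGCT: steps AG GC CG GT TA AA AG GC CT; ends A (2.3, 4.1), T (2.3, 4.1)
  dH <- sum(dh) + 2.3 + 2.3
  dS <- sum(ds) + 4.1 + 4.1
  dS_salt <- dS + 0.368 * 9 * log(0.05)
  tm_hand <- 1000 * dH / (dS_salt + 1.9872 * log(50e-9 / 4)) - 273.15
  expect_equal(melting_temperature("AGCGTAAGCT", na_mM = 50, oligo_nM = 50),
               tm_hand, tolerance = 1e-10)
})

test_that("Tm is symmetric under reverse complement and increases with GC", {
  withr::with_seed(5, {
    for (i in 1:5) {
      s <- random_dna(30)
      expect_equal(melting_temperature(s), melting_temperature(revcomp(s)),
                   tolerance = 1e-9)
    }
  })
  # progressively replace AT pairs with GC pairs at fixed length
  base <- strsplit("ATATATATTATATATATATA", "")[[1]]
  tms <- vapply(0:8, function(k) {
    s <- base
    if (k > 0) s[seq_len(k) * 2] <- "G"
    melting_temperature(paste(s, collapse = ""))
  }, double(1))
  expect_true(all(diff(tms) > 0))
  expect_error(melting_temperature("ACGTACG"), "at least 8")
})

test_that("structure scores find planted hairpins and are RC-invariant", {
  expect_equal(secondary_structure_scores("AAAAAAAAAA"),
               tibble::tibble(stem_score = 0L, selfdimer_score = 0L))
  stem <- "ACGGATCC"
  hairpin <- paste0("TT", stem, "AAAA", revcomp(stem), "TT")
  sc <- secondary_structure_scores(hairpin, min_loop = 3)
  expect_equal(sc$stem_score, 8L)
  # brute force over all substring pairs with >= min_loop separation
  brute_stem <- function(s, min_loop) {
    ch <- strsplit(s, "")[[1]]
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    best <- 0
    n <- length(ch)
    for (i in seq_len(n)) for (j in seq(i, n)) {
      k <- 0
      while (i + k < j - k &&
             (j - k) - (i + k) - 1 >= min_loop &&
             !is.na(comp[ch[i + k]]) && comp[ch[i + k]] == ch[j - k]) {
        k <- k + 1
      }
      best <- max(best, k)
    }
    best
  }
  withr::with_seed(8, {
    for (trial in 1:10) {
      s <- random_dna(40)
      expect_equal(
        secondary_structure_scores(s, min_loop = 3)$stem_score,
        brute_stem(s, 3),
        info = s
      )
      rc <- revcomp(s)
      expect_equal(secondary_structure_scores(s)$stem_score,
                   secondary_structure_scores(rc)$stem_score)
      expect_equal(secondary_structure_scores(s)$selfdimer_score,
                   secondary_structure_scores(rc)$selfdimer_score)
      # selfdimer equals the two-string LCS oracle against the RC
      expect_equal(secondary_structure_scores(s)$selfdimer_score,
                   oracle_lcs(s, rc))
    }
  })
})

test_that("candidate enumeration matches the direct counting oracle", {
  cons <- probe_constraints()
  expect_equal(nrow(enumerate_candidates(strrep("ACGT", 10), cons)), 0)
  withr::with_seed(3, {
    s200 <- random_dna(200, gc = 0.42)
  })
  cand <- enumerate_candidates(s200, cons)
  want_n <- sum(vapply(60:70, function(L) 200 - L + 1, double(1)))
  expect_equal(nrow(cand), want_n)
  # annotations recomputable from the sequence
  idx <- c(1, 50, nrow(cand))
  expect_equal(cand$gc[idx], gc_content(cand$sequence[idx]))
  expect_equal(cand$tm[idx], melting_temperature(cand$sequence[idx]),
               tolerance = 1e-9)
  expect_equal(cand$dist_3prime, 200L - (cand$start + cand$length))
  expect_equal(cand$sequence[1],
               substr(s200, cand$start[1] + 1, cand$start[1] + cand$length[1]))
  # 3'-distance restriction honoured
  short_reach <- probe_constraints(max_dist_3prime = 50)
  cand2 <- enumerate_candidates(s200, short_reach)
  expect_true(all(cand2$dist_3prime <= 50))
})

test_that("selection outcomes partition unigenes and match brute force", {
  cons <- probe_constraints()
  # GC unattainable
  allat <- select_probe(strrep("AT", 150), cons, "at")
  expect_equal(allat$outcome, "missing")
  expect_equal(allat$missing_reason, "no_window_meets_constraints")
  # too short for any window
  expect_equal(select_probe(strrep("ACGT", 10), cons, "short")$missing_reason,
               "too_short")
  # brute-force argmin oracle on a random unigene
  withr::with_seed(17, {
    s <- random_dna(1500, gc = 0.40)
  })
  got <- select_probe(s, cons, "u1")
  expect_equal(got$outcome, "designed")
  cand <- enumerate_candidates(s, cons, structure = TRUE)
  feas <- cand[abs(cand$tm - 67) <= 3 & abs(cand$gc - 43) <= 5 &
                 cand$stem_score <= 8 & cand$selfdimer_score <= 12, ]
  expect_gt(nrow(feas), 0)
  rank <- abs(feas$tm - 67) + abs(feas$gc - 43) + feas$stem_score +
    feas$selfdimer_score + 0.001 * feas$dist_3prime
  best <- feas[order(rank, feas$dist_3prime, feas$start)[1], ]
  expect_equal(got$start, best$start)
  expect_equal(got$length, best$length)
  expect_equal(got$rank_score, min(rank))
})

test_that("every designed probe satisfies the published constraint windows", {
  fx <- simulate_unigenes(12, seed = 23)
  report <- design_probes(fx$unigenes)
  expect_equal(nrow(report), 12)
  expect_setequal(report$outcome, c("designed"))
  d <- report[report$outcome == "designed", ]
  expect_true(all(abs(d$tm - 67) <= 3))
  expect_true(all(abs(d$gc - 43) <= 5))
  expect_true(all(d$length >= 60 & d$length <= 70))
  expect_true(all(d$dist_3prime <= 1000))
  expect_true(all(d$stem_score <= 8 & d$selfdimer_score <= 12))
  # probe sequence is the claimed unigene substring
  i <- match(d$unigene_id, fx$unigenes$id)
  expect_equal(d$sequence,
               substr(fx$unigenes$sequence[i], d$start + 1,
                      d$start + d$length))
  # selection is a pure per-unigene function: permuting inputs changes nothing
  perm <- fx$unigenes[withr::with_seed(2, sample(12)), ]
  report2 <- design_probes(perm)
  expect_equal(dplyr::arrange(report, .data$unigene_id),
               dplyr::arrange(report2, .data$unigene_id))
})
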