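# Cross-hybridization screen: LCS and overall identity against DP oracles,
# the strict AND flagging rule, monotonicity and strand symmetry.

test_that("longest common substring matches the R DP oracle", {
  probe <- withr::with_seed(1, random_dna(65))
  expect_equal(longest_common_substring(probe, probe), 65L)
  expect_equal(longest_common_substring(strrep("A", 30), strrep("C", 30)), 0L)
  withr::with_seed(2, {
    for (trial in 1:10) {
      a <- random_dna(65); b <- random_dna(200)
      expect_equal(longest_common_substring(a, b), oracle_lcs_2s(a, b))
    }
    # planted 25-mer inside random flanks
    block <- random_dna(25)
    a <- paste0(random_dna(20), block, random_dna(20))
    b <- paste0(random_dna(80), block, random_dna(100))
    expect_gte(longest_common_substring(a, b), 25L)
    expect_equal(oracle_lcs_2s(a, b), longest_common_substring(a, b))
    # found on the reverse strand too
    b_rc <- revcomp(b)
    expect_equal(longest_common_substring(a, b_rc),
                 longest_common_substring(a, b))
  })
})

test_that("overall identity uses the probe-length denominator", {
  withr::with_seed(6, {
    target <- random_dna(300)
  })
  probe <- substr(target, 101, 165)
  expect_equal(overall_identity(probe, target), 100)
  # 19 of 65 positions mutated -> 46/65 ~ 70.8%; keep runs of >= 3 matches
  # at both ends so the best local alignment cannot trim matches
  ch <- strsplit(probe, "")[[1]]
  at <- round(seq(4, 62, length.out = 19))
  for (pos in at) ch[pos] <- setdiff(c("A", "C", "G", "T"), ch[pos])[1]
  mut <- paste(ch, collapse = "")
  expect_equal(overall_identity(mut, target), 100 * 46 / 65,
               tolerance = 1e-9)
  # random probe vs unrelated target: low identity, equal to the DP oracle
  withr::with_seed(7, {
    for (trial in 1:5) {
      p <- random_dna(65); tg <- random_dna(400)
      got <- overall_identity(p, tg)
      ora <- oracle_local_align_2s(p, tg)
      # co-optimal local alignments can differ in match count between two
      # DP implementations; the optimal score is the exact invariant
      sw <- pairwise_local_identity(p, tg)
      expect_equal(sw$score, ora$score)
      expect_lt(abs(got - 100 * ora$nmatch / 65), 5)
      expect_lt(got, 60)
    }
  })
})

# deterministic screen fixture: 5 unigenes, probe of UG1; UG2 carries a
# planted high-identity copy, UG3 a short exact block only
make_screen_fixture <- function(seed = 33) {
  withr::with_seed(seed, {
    u1 <- random_dna(400, gc = 0.4)
    probe <- substr(u1, 300, 364)
    ch <- strsplit(probe, "")[[1]]
    # 6 mutations in the first half -> 59/65 ~ 90.8% overall identity
    # (sparse enough that the local alignment spans the whole probe),
    # leaving an intact > 30 nt exact stretch for the LCS rule
    at <- round(seq(3, 30, length.out = 6))
    for (pos in at) ch[pos] <- setdiff(c("A", "C", "G", "T"), ch[pos])[1]
    u2 <- paste0(random_dna(100), paste(ch, collapse = ""), random_dna(100))
    # exact 25-mer but nothing else
    u3 <- paste0(random_dna(150), substr(probe, 20, 44), random_dna(150))
    u4 <- random_dna(350)
    u5 <- random_dna(350)
  })
  list(
    unigenes = tibble::tibble(
      id = paste0("U", 1:5), sequence = c(u1, u2, u3, u4, u5)
    ),
    probes = tibble::tibble(probe_id = "U1_probe", unigene_id = "U1",
                            sequence = probe)
  )
}

test_that("the AND rule flags only targets passing both strict thresholds", {
  fx <- make_screen_fixture()
  scr <- screen_crosshyb(fx$probes, fx$unigenes)
  rep <- tidy(scr)
  expect_true(rep$flagged[rep$probe_id == "U1_probe"])
  # U2 passes both; U3 passes LCS only (overall identity ~ 25/65)
  expect_true("U2" %in% scr$hits$target_unigene_id)
  expect_false("U3" %in% scr$hits$target_unigene_id)
  # raising the identity threshold above U2's identity unflags everything
  hi <- screen_crosshyb(fx$probes, fx$unigenes, id_threshold = 95)
  expect_false(any(tidy(hi)$flagged))
  # single-unigene input: no non-source targets, no flags
  solo <- screen_crosshyb(fx$probes, fx$unigenes[1, ])
  expect_false(any(tidy(solo)$flagged))
  expect_error(screen_crosshyb(fx$probes, fx$unigenes[-1, ]), "not found")
})

test_that("flags are monotone in both thresholds and strand-symmetric", {
  fx <- make_screen_fixture(seed = 44)
  base <- screen_crosshyb(fx$probes, fx$unigenes, 70, 20)
  looser_id <- screen_crosshyb(fx$probes, fx$unigenes, 50, 20)
  looser_lcs <- screen_crosshyb(fx$probes, fx$unigenes, 70, 10)
  flagged <- function(s) tidy(s)$probe_id[tidy(s)$flagged]
  expect_true(all(flagged(base) %in% flagged(looser_id)))
  expect_true(all(flagged(base) %in% flagged(looser_lcs)))
  # reverse-complementing a target does not change the flag set
  rc <- fx$unigenes
  rc$sequence[2] <- revcomp(rc$sequence[2])
  expect_equal(flagged(screen_crosshyb(fx$probes, rc, 70, 20)),
               flagged(base))
})

test_that("screen equals the brute-force double oracle on small sets", {
  withr::with_seed(55, {
    for (trial in 1:3) {
      hom <- tibble::tibble(
        id_a = sprintf("UG%04d", 1:2), id_b = sprintf("UG%04d", 3:4),
        identity = c(92.5, 87.5), length = c(80, 60)
      )
      fx <- simulate_unigenes(8, seed = sample.int(1e6, 1),
                              length_range = c(150, 400), homology = hom)
      probes <- design_probes(fx$unigenes)
      probes <- probes[probes$outcome == "designed",
                       c("probe_id", "unigene_id", "sequence")]
      scr <- screen_crosshyb(probes, fx$unigenes)
      got_flags <- sort(tidy(scr)$probe_id[tidy(scr)$flagged])
      want_flags <- character()
      for (i in seq_len(nrow(probes))) {
        for (j in seq_len(nrow(fx$unigenes))) {
          if (fx$unigenes$id[j] == probes$unigene_id[i]) next
          ora <- oracle_local_align_2s(probes$sequence[i],
                                       fx$unigenes$sequence[j])
          oid <- 100 * ora$nmatch / nchar(probes$sequence[i])
          olcs <- oracle_lcs_2s(probes$sequence[i], fx$unigenes$sequence[j])
          if (oid > 70 && olcs > 20) {
            want_flags <- c(want_flags, probes$probe_id[i])
            break
          }
        }
      }
      expect_equal(got_flags, sort(unique(want_flags)))
    }
  })
})
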