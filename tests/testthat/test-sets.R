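# Tissue-specific calling, Venn partitioning, Fisher enrichment vs a
# hypergeometric summation oracle, and average-linkage clustering vs an
# O(n^3) oracle.

test_that("tissue specificity requires up-regulation in both comparisons", {
  calls <- tibble::tibble(
    gene_id = c("g1", "g1", "g2", "g2", "g3"),
    cond_a  = c("bean", "bean", "bean", "bean", "leaf"),
    cond_b  = c("leaf", "flower", "leaf", "flower", "flower"),
    up_in   = c("bean", "bean", "bean", "flower", "leaf")
  )
  spec <- tissue_specific(calls)
  expect_equal(spec$gene_id[spec$condition == "bean"], "g1")
  expect_false("g2" %in% spec$gene_id)  # up in bean once, flower once
  bad <- calls; bad$up_in[1] <- "stem"
  expect_error(tissue_specific(bad), "up_in")
  two_cond <- calls[calls$cond_a == "bean" & calls$cond_b == "leaf", ]
  expect_error(tissue_specific(two_cond), "3 conditions")
})

test_that("tissue specificity equals a brute-force set-logic oracle", {
  conds <- c("bean", "flower", "leaf")
  pairs <- t(combn(conds, 2))
  withr::with_seed(12, {
    for (trial in 1:5) {
      genes <- sprintf("g%02d", 1:30)
      calls <- purrr::map(seq_len(3), function(i) {
        picked <- sample(genes, 15)
        tibble::tibble(gene_id = picked, cond_a = pairs[i, 1],
                       cond_b = pairs[i, 2],
                       up_in = sample(pairs[i, ], 15, replace = TRUE))
      }) |> dplyr::bind_rows()
      got <- tissue_specific(calls)
      for (tt in conds) {
        inv <- calls[calls$cond_a == tt | calls$cond_b == tt, ]
        oracle <- names(which(table(inv$gene_id[inv$up_in == tt]) == 2))
        expect_setequal(got$gene_id[got$condition == tt], oracle)
      }
    }
  })
})

test_that("venn partition is disjoint, conservative and oracle-exact", {
  v <- venn_partition(c("a", "b"), c("c"), c("d"),
                      names = c("bean", "flower", "leaf"))
  expect_equal(sum(v$n), 4)
  expect_equal(v$n[v$region == "bean_and_flower_and_leaf"], 0)
  same <- venn_partition(letters[1:3], letters[1:3], letters[1:3])
  expect_equal(same$n[same$region == "a_and_b_and_c"], 3)
  expect_equal(sum(same$n), 3)
  withr::with_seed(8, {
    for (trial in 1:5) {
      A <- sample(letters, 12); B <- sample(letters, 9); C <- sample(letters, 15)
      v <- venn_partition(A, B, C)
      u <- union(union(A, B), C)
      expect_equal(sum(v$n), length(u))
      all_members <- unlist(v$genes)
      expect_equal(sort(all_members), sort(u))  # disjoint cover
      # element-wise membership oracle for one region
      abc <- v$genes[[which(v$region == "a_and_b_and_c")]]
      expect_setequal(abc, intersect(intersect(A, B), C))
      a_only <- v$genes[[which(v$region == "a_only")]]
      expect_setequal(a_only, setdiff(setdiff(A, B), C))
    }
  })
})

test_that("Fisher enrichment equals hypergeometric summation to 1e-12", {
  bg <- sprintf("g%03d", 1:100)
  tm <- tibble::tibble(
    gene_id = c(bg[1:5], bg[1:40], bg),
    term_id = c(rep("T1", 5), rep("T2", 40), rep("TALL", 100))
  )
  gset <- bg[1:10]
  res <- fisher_enrichment(gset, bg, tm)
  t1 <- res[res$term_id == "T1", ]
  expect_equal(t1$k, 5L); expect_equal(t1$K, 5L)
  expect_equal(t1$n, 10); expect_equal(t1$N, 100)
  expect_equal(t1$p, oracle_fisher_two_sided(5, 5, 10, 100),
               tolerance = 1e-12)
  expect_equal(t1$direction, "over")
  # a term annotating every background gene is uninformative
  expect_equal(res$p[res$term_id == "TALL"], 1)
  # random small tables, all N <= 60
  withr::with_seed(25, {
    for (trial in 1:20) {
      N <- sample(10:60, 1)
      K <- sample(1:N, 1)
      n <- sample(1:N, 1)
      bgx <- sprintf("x%02d", 1:N)
      tmx <- tibble::tibble(gene_id = bgx[seq_len(K)], term_id = "T")
      gsx <- sample(bgx, n)
      rx <- fisher_enrichment(gsx, bgx, tmx)
      k <- sum(gsx %in% bgx[seq_len(K)])
      expect_equal(rx$p[rx$term_id == "T"],
                   oracle_fisher_two_sided(k, K, n, N), tolerance = 1e-12)
    }
  })
  expect_equal(nrow(fisher_enrichment(character(), bg, tm)), 0)
  expect_error(fisher_enrichment("nope", bg, tm), "not in background")
  # BH across terms via the package's own validated adjuster
  expect_equal(res$p_adj, bh_adjust(res$p))
})

test_that("average-linkage merges match hand computation and the oracle", {
  # two identical profiles merge at height 0
  prof <- tibble::tibble(id = c("h1", "h2"), g1 = c(1, 1), g2 = c(2, 2))
  expect_equal(tidy(hierarchical_cluster(prof))$height, 0)
  # three 1-D points 0, 1, 10: merge (0,1) at 1, then at mean(10, 9) = 9.5
  prof3 <- tibble::tibble(id = c("a", "b", "c"), x = c(0, 1, 10))
  hc <- hierarchical_cluster(prof3)
  expect_equal(tidy(hc)$height, c(1, 9.5))
  expect_true(all(diff(tidy(hc)$height) >= 0))
  withr::with_seed(31, {
    for (trial in 1:5) {
      n <- sample(5:10, 1)
      x <- matrix(rnorm(n * 6), n)
      rownames(x) <- sprintf("h%d", seq_len(n))
      got <- hierarchical_cluster(x)
      ora <- oracle_average_linkage(as.matrix(dist(x)))
      expect_equal(got$hclust$height, ora$heights, tolerance = 1e-12)
      expect_equal(hclust_members(got$hclust), ora$members)
    }
  })
  expect_error(hierarchical_cluster(prof3[1, ]), "at least 2")
})

test_that("replicates co-cluster before any cross-condition merge", {
  # three condition signatures, two replicates each, modest noise
  withr::with_seed(77, {
    sig <- matrix(rnorm(3 * 40, sd = 2), 3)
    prof <- do.call(rbind, lapply(1:3, function(k) {
      rbind(sig[k, ] + rnorm(40, sd = 0.3), sig[k, ] + rnorm(40, sd = 0.3))
    }))
  })
  rownames(prof) <- c("A_r1", "A_r2", "B_r1", "B_r2", "C_r1", "C_r2")
  hc <- hierarchical_cluster(prof)
  members <- hclust_members(hc$hclust)
  # the first three merges are exactly the three replicate pairs
  first3 <- members[1:3]
  expect_setequal(lapply(first3, identity),
                  list(c(1L, 2L), c(3L, 4L), c(5L, 6L)))
})

test_that("newick export preserves topology and ultrametric depths", {
  prof3 <- tibble::tibble(id = c("a", "b", "c"), x = c(0, 1, 10))
  hc <- hierarchical_cluster(prof3)
  nwk <- as_newick(hc)
  expect_match(nwk, "^\\(.*\\);$")
  tree <- ape::read.tree(text = nwk)
  expect_setequal(tree$tip.label, c("a", "b", "c"))
  # a and b are sisters; depths reproduce the merge heights
  mrca_ab <- ape::getMRCA(tree, c("a", "b"))
  depths <- ape::node.depth.edgelength(tree)
  expect_equal(max(depths), 9.5)
  expect_equal(max(depths) - depths[mrca_ab], 1)
})
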