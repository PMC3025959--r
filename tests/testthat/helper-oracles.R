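# Independent oracles used to validate the package's implementations.
# Each oracle is deliberately written over a different code path than the
# function it checks (Biostrings dynamic programming, plain-R DP, direct
# enumeration or summation).

# Best local alignment via Biostrings (full DP, linear gap penalty to match
# the package's scoring scheme). Returns score, nmatch, aligned width and
# identity over aligned columns.
oracle_local_align <- function(a, b, match = 1, mismatch = -2, gap = -3) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match, mismatch,
                                                  baseOnly = TRUE)
  al <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                      substitutionMatrix = mat,
                                      gapOpening = 0, gapExtension = -gap)
  list(
    score = Biostrings::score(al),
    nmatch = Biostrings::nmatch(al),
    width = Biostrings::nchar(al),
    identity_pct = Biostrings::pid(al, type = "PID1")
  )
}

# Best over both strands of b, mirroring pairwise_local_identity()
oracle_local_align_2s <- function(a, b, ...) {
  f <- oracle_local_align(a, b, ...)
  r <- oracle_local_align(a, oligoarray::revcomp(b), ...)
  if (r$score > f$score) r else f
}

# Plain-R longest common substring DP (row-vectorised)
oracle_lcs <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  prev <- integer(length(y))
  best <- 0L
  for (i in seq_along(x)) {
    cur <- ifelse(y == x[i], c(0L, prev[-length(prev)]) + 1L, 0L)
    best <- max(best, cur)
    prev <- cur
  }
  best
}

oracle_lcs_2s <- function(a, b) {
  max(oracle_lcs(a, b), oracle_lcs(a, oligoarray::revcomp(b)))
}

# Union-find single-linkage components; returns a canonical partition
# (list of sorted member vectors, ordered by smallest member)
oracle_components <- function(ids, edges) {
  parent <- setNames(ids, ids)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  if (length(edges) > 0) {
    for (e in edges) {
      ra <- find(e[1]); rb <- find(e[2])
      if (ra != rb) parent[[rb]] <- ra
    }
  }
  roots <- vapply(ids, find, character(1))
  unname(lapply(split(ids, roots), sort))[order(
    vapply(split(ids, roots), min, character(1))
  )]
}

canonical_partition <- function(cluster_tbl) {
  unname(lapply(
    split(cluster_tbl$member_id, cluster_tbl$cluster_id), sort
  ))
}

# Hand step-up BH adjustment
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(n / (n:1) * p[o]))
  adj[ro]
}

# Two-sided Fisher p by direct hypergeometric summation: sum of the
# probabilities of all tables (given margins) no more likely than observed
oracle_fisher_two_sided <- function(k, K, n, N) {
  support <- max(0, n + K - N):min(n, K)
  probs <- dhyper(support, K, N - K, n)
  p_obs <- dhyper(k, K, N - K, n)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# O(n^3) average-linkage agglomeration on a distance matrix; returns merge
# heights and the leaf partition after each merge
oracle_average_linkage <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  active <- rep(TRUE, n + (n - 1))
  clusters <- c(clusters, vector("list", n - 1))
  active[(n + 1):length(active)] <- FALSE
  heights <- double(n - 1)
  members <- list()
  avg_dist <- function(ci, cj) {
    mean(d[ci, cj])
  }
  for (step in seq_len(n - 1)) {
    idx <- which(active)
    best <- c(NA, NA); bh <- Inf
    for (i in idx) for (j in idx) {
      if (i < j) {
        h <- avg_dist(clusters[[i]], clusters[[j]])
        if (h < bh - 1e-12) { bh <- h; best <- c(i, j) }
      }
    }
    new_id <- n + step
    clusters[[new_id]] <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    active[best] <- FALSE
    active[new_id] <- TRUE
    heights[step] <- bh
    members[[step]] <- clusters[[new_id]]
  }
  list(heights = heights, members = members)
}

# partition of leaves after each hclust merge, for structural comparison
hclust_members <- function(hc) {
  n <- length(hc$order)
  out <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    grab <- function(x) if (x < 0) -x else out[[x]]
    out[[i]] <- sort(c(grab(hc$merge[i, 1]), grab(hc$merge[i, 2])))
  }
  out
}

# direct windowed Shannon entropy (bits) of a character window
oracle_entropy <- function(chars) {
  p <- table(chars) / length(chars)
  -sum(p * log2(p))
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
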