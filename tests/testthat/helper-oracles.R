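# Independent oracles used to check the package's implementations.
# Everything here is deliberately written by a different route than the
# functions under test (explicit loops, exhaustive enumeration, closed
# forms), so an agreement is informative.

# Two-sided Fisher p-value for a 2x2 table by exhaustive enumeration of the
# hypergeometric sample space (point-probability method: sum of all table
# probabilities not exceeding the observed one, with the customary relative
# tolerance for float comparison).
oracle_fisher_2x2 <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  lo <- max(0L, c1 - (n - r1)); hi <- min(r1, c1)
  xs <- lo:hi
  probs <- vapply(xs, function(x) {
    exp(lchoose(r1, x) + lchoose(n - r1, c1 - x) - lchoose(n, c1))
  }, 0)
  p_obs <- probs[match(a, xs)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Hand step-up Benjamini-Hochberg: adjusted_(i) = min_{j >= i} p_(j) * m / j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(j) ps[j] * m / j, 0)
    adj[i] <- min(1, min(cand))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Probability that two uniform starts on [0, L] fall within w of each other,
# by brute-force numeric integration of P(|u - v| <= w) on the unit square.
oracle_pair_prob <- function(L, w, n_grid = 2000L) {
  u <- (seq_len(n_grid) - 0.5) / n_grid * L
  mean(vapply(u, function(x) {
    (min(x + w, L) - max(x - w, 0)) / L
  }, 0))
}

# Brute-force duplication classifier: evaluates the rule cascade by
# explicit pair enumeration, one gene at a time, with no shared code with
# classify_duplications().
oracle_classify <- function(genome, hits, blocks, outgroup_anchored = NULL,
                            proximal_max = 20L) {
  genes <- genome$gene_id
  chrom <- setNames(genome$chromosome, genes)
  rank <- setNames(genome$rank, genes)
  block_genes <- character()
  anchor_pairs <- character()
  for (b in blocks) {
    block_genes <- union(block_genes, as.vector(b$anchor_pairs))
    for (i in seq_len(nrow(b$anchor_pairs))) {
      anchor_pairs <- c(anchor_pairs,
                        paste(sort(b$anchor_pairs[i, ]), collapse = "|"))
    }
  }
  partner_of <- function(g) {
    p1 <- hits$subject[hits$query == g]
    p2 <- hits$query[hits$subject == g]
    unique(c(p1, p2))
  }
  out <- setNames(rep(NA_character_, length(genes)), genes)
  for (g in genes) {
    partners <- partner_of(g)
    if (length(partners) == 0 && !(g %in% block_genes)) {
      out[g] <- "singleton"
      next
    }
    if (g %in% block_genes) {
      out[g] <- "wgd_segmental"
      next
    }
    pair_modes <- character()
    for (p in partners) {
      key <- paste(sort(c(g, p)), collapse = "|")
      if (key %in% anchor_pairs) {
        pair_modes <- c(pair_modes, "wgd_segmental")
      } else if (chrom[g] == chrom[p] && abs(rank[g] - rank[p]) == 1) {
        pair_modes <- c(pair_modes, "tandem")
      } else if (chrom[g] == chrom[p] &&
                 abs(rank[g] - rank[p]) >= 2 &&
                 abs(rank[g] - rank[p]) <= proximal_max) {
        pair_modes <- c(pair_modes, "proximal")
      } else if (!is.null(outgroup_anchored) &&
                 xor(g %in% outgroup_anchored,
                     p %in% outgroup_anchored)) {
        # only the non-anchored member is transposed
        if (g %in% outgroup_anchored) pair_modes <- c(pair_modes, "dispersed")
        else pair_modes <- c(pair_modes, "transposed")
      } else {
        pair_modes <- c(pair_modes, "dispersed")
      }
    }
    for (m in c("wgd_segmental", "tandem", "proximal", "transposed",
                "dispersed")) {
      if (m %in% pair_modes) { out[g] <- m; break }
    }
  }
  out
}
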