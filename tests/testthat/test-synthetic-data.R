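test_that("a single tandem event yields an adjacent labeled pair", {
  cfg <- synthetic_config(n_chromosomes = 1L, n_ancestral_genes = 10L,
                          event_counts = c(tandem = 1L), seed = 7)
  sim <- generate_genome(cfg)
  expect_equal(nrow(sim$genome), 11L)
  tp <- sim$truth$true_pairs
  expect_equal(nrow(tp), 1L)
  expect_equal(tp$mode, "tandem")
  r <- setNames(sim$genome$rank, sim$genome$gene_id)
  expect_equal(abs(r[tp$gene1] - r[tp$gene2]), 1L, ignore_attr = TRUE)
  expect_equal(unname(sim$truth$true_mode[c(tp$gene1, tp$gene2)]),
               c("tandem", "tandem"))
})

test_that("generation is a pure function of config and seed", {
  cfg <- small_config(seed = 42)
  a <- generate_genome(cfg)
  b <- generate_genome(cfg)
  expect_identical(a, b)
  expect_identical(generate_hits(a$truth, noise = 0.1),
                   generate_hits(b$truth, noise = 0.1))
  expect_identical(generate_expression(a$truth, cfg),
                   generate_expression(b$truth, cfg))
})

test_that("zero planted events give an all-singleton genome", {
  cfg <- synthetic_config(n_ancestral_genes = 30L,
                          event_counts = c(tandem = 0L), seed = 2)
  sim <- generate_genome(cfg)
  expect_true(all(sim$truth$true_mode == "singleton"))
  expect_equal(nrow(sim$truth$true_pairs), 0L)
})

test_that("planted pair counts equal the configured event counts", {
  cfg <- small_config(seed = 11)
  sim <- generate_genome(cfg)
  tp <- sim$truth$true_pairs
  counts <- table(tp$mode)
  expect_equal(counts[["tandem"]], 3L)
  expect_equal(counts[["proximal"]], 3L)
  expect_equal(counts[["transposed"]], 2L)
  expect_equal(counts[["dispersed"]], 2L)
  # one anchor pair per copied gene in each segmental block
  expect_equal(counts[["wgd_segmental"]], 2L * 3L)
  expect_length(sim$truth$planted_blocks, 2L)
})

test_that("planted events respect their distance rules", {
  cfg <- small_config(seed = 13)
  sim <- generate_genome(cfg)
  r <- setNames(sim$genome$rank, sim$genome$gene_id)
  ch <- setNames(sim$genome$chromosome, sim$genome$gene_id)
  tp <- sim$truth$true_pairs
  for (i in seq_len(nrow(tp))) {
    g1 <- tp$gene1[i]; g2 <- tp$gene2[i]
    d <- abs(r[g1] - r[g2])
    same <- ch[g1] == ch[g2]
    switch(tp$mode[i],
      tandem = expect_true(same && d == 1),
      proximal = expect_true(same && d >= 2 && d <= 20),
      transposed = expect_false(same),
      dispersed = expect_true(!same || d >= 21))
  }
})

test_that("event capacity is validated", {
  expect_error(generate_genome(
    synthetic_config(n_ancestral_genes = 10L,
                     event_counts = c(tandem = 20L), seed = 1)),
    "capacity")
})

test_that("noise-free hits cover every true pair and survive filtering", {
  cfg <- small_config(seed = 21)
  sim <- generate_genome(cfg)
  hits <- generate_hits(sim$truth, noise = 0)
  expect_equal(nrow(hits), 2L * nrow(sim$truth$true_pairs))
  kept <- filter_hits(hits, max_e = 1e-5, top_k = 5)
  key <- paste(pmin(kept$query, kept$subject),
               pmax(kept$query, kept$subject))
  tp <- sim$truth$true_pairs
  want <- paste(pmin(tp$gene1, tp$gene2), pmax(tp$gene1, tp$gene2))
  expect_true(all(want %in% key))
})

test_that("expression correlation tracks the configured rho", {
  # degenerate rho = 1 gives exactly correlated profiles
  cfg1 <- small_config(seed = 3, rho_by_mode = c(
    wgd_segmental = 1, tandem = 1, proximal = 1, transposed = 1,
    dispersed = 1), expression_samples = 20L)
  sim1 <- generate_genome(cfg1)
  e1 <- generate_expression(sim1$truth, cfg1)
  tp <- sim1$truth$true_pairs
  for (i in seq_len(nrow(tp)))
    expect_equal(cor(e1[tp$gene1[i], ], e1[tp$gene2[i], ]), 1)

  # rho = 0 with many samples: |r| < 0.1 for at least 95% of pairs
  # (Fisher z standard error 1/sqrt(n - 3) ~ 0.032 at n = 1000)
  cfg0 <- synthetic_config(
    n_ancestral_genes = 500L, event_counts = c(dispersed = 150L),
    rho_by_mode = c(wgd_segmental = 0, tandem = 0, proximal = 0,
                    transposed = 0, dispersed = 0),
    expression_samples = 1000L, seed = 5)
  sim0 <- generate_genome(cfg0)
  e0 <- generate_expression(sim0$truth, cfg0)
  tp0 <- sim0$truth$true_pairs
  rs <- vapply(seq_len(nrow(tp0)), function(i)
    cor(e0[tp0$gene1[i], ], e0[tp0$gene2[i], ]), 0)
  expect_gte(mean(abs(rs) < 0.1), 0.95)

  # rho = 0.7, 500 samples, 200 pairs: mean r within 0.05 of 0.7
  cfg7 <- synthetic_config(
    n_ancestral_genes = 600L, event_counts = c(tandem = 200L),
    rho_by_mode = c(wgd_segmental = 0.7, tandem = 0.7, proximal = 0.7,
                    transposed = 0.7, dispersed = 0.7),
    expression_samples = 500L, seed = 8)
  sim7 <- generate_genome(cfg7)
  e7 <- generate_expression(sim7$truth, cfg7)
  tp7 <- sim7$truth$true_pairs
  rs7 <- vapply(seq_len(nrow(tp7)), function(i)
    cor(e7[tp7$gene1[i], ], e7[tp7$gene2[i], ]), 0)
  expect_lt(abs(mean(rs7) - 0.7), 0.05)
})

test_that("family trees are cherries at planted events", {
  cfg <- synthetic_config(n_chromosomes = 2L, n_ancestral_genes = 40L,
                          event_counts = c(tandem = 1L), family_size = 2L,
                          seed = 17)
  sim <- generate_genome(cfg)
  tp <- sim$truth$true_pairs
  fam <- sim$truth$family_of[[tp$gene1]]
  tr <- generate_family_tree(sim$truth, fam)
  expect_true(all(c(tp$gene1, tp$gene2) %in% tr$tip.label))
  mrca <- ape::getMRCA(tr, c(tp$gene1, tp$gene2))
  below <- ape::extract.clade(tr, mrca)$tip.label
  expect_setequal(below, c(tp$gene1, tp$gene2))
})

test_that("phenotype generator plants configurable enrichments", {
  cfg <- small_config(seed = 23)
  sim <- generate_genome(cfg)
  focal <- names(sim$truth$true_mode)[1:30]
  ph <- generate_phenotypes(sim$truth, cfg, focal = focal,
                            boost_class = "essential", boost_odds = Inf)
  expect_true(all(ph[focal] == "essential"))
  # without a boost, classes follow the configured probabilities
  ph0 <- generate_phenotypes(sim$truth, cfg)
  expect_setequal(unique(names(table(ph0))),
                  intersect(names(cfg$phenotype_class_probs),
                            unique(ph0)))
})

test_that("interaction generator plants exact-degree hubs", {
  cfg <- small_config(seed = 29)
  sim <- generate_genome(cfg)
  hub <- names(sim$truth$true_mode)[5]
  edges <- generate_interactions(sim$truth, cfg, hub_genes = hub,
                                 hub_degree = 25L)
  ds <- degree_stats(edges, focal = names(sim$truth$true_mode),
                     hub_threshold = 20L)
  expect_equal(ds$hubs, hub)
  expect_equal(unname(ds$degree_of[hub]), 25L)
})
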