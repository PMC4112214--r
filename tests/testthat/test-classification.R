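toy_genome <- function(n = 30, chrom = "chr1") {
  as_genome_table(data.frame(
    gene_id = sprintf("%s_g%02d", chrom, seq_len(n)),
    chromosome = chrom,
    start = seq_len(n) * 1000L, end = seq_len(n) * 1000L + 500L,
    strand = "+"))
}

hit <- function(q, s) data.frame(query = q, subject = s, e_value = 1e-20)

test_that("adjacent homologs are tandem, near ones proximal", {
  g <- toy_genome(30)
  lab <- classify_duplications(g, hit("chr1_g05", "chr1_g06"))
  expect_equal(unname(lab$mode_of[c("chr1_g05", "chr1_g06")]),
               c("tandem", "tandem"))
  # ranks 4 and 10: five intervening genes, inside the 20-gene window
  lab2 <- classify_duplications(g, hit("chr1_g05", "chr1_g11"))
  expect_equal(unname(lab2$mode_of[c("chr1_g05", "chr1_g11")]),
               c("proximal", "proximal"))
  # beyond the window: dispersed
  lab3 <- classify_duplications(g, hit("chr1_g01", "chr1_g30"))
  expect_equal(unname(lab3$mode_of[["chr1_g01"]]), "dispersed")
  # no hits at all: everything is singleton
  lab0 <- classify_duplications(g, data.frame(query = character(),
                                              subject = character(),
                                              e_value = numeric()))
  expect_true(all(lab0$mode_of == "singleton"))
})

test_that("block anchorship outranks adjacency", {
  g <- toy_genome(10)
  b <- list(list(block_id = "0",
                 anchor_pairs = rbind(c("chr1_g02", "chr1_g03"),
                                      c("chr1_g04", "chr1_g05")),
                 chrom_pair = c("chr1", "chr1"),
                 score = NA_real_, e_value = NA_real_))
  lab <- classify_duplications(g, hit("chr1_g02", "chr1_g03"), blocks = b)
  expect_equal(unname(lab$mode_of[["chr1_g02"]]), "wgd_segmental")
  expect_equal(unname(lab$mode_of[["chr1_g03"]]), "wgd_segmental")
})

test_that("tandem arrays link transitively", {
  g <- toy_genome(10)
  hits <- rbind(hit("chr1_g03", "chr1_g04"), hit("chr1_g04", "chr1_g05"),
                hit("chr1_g05", "chr1_g06"))
  lab <- classify_duplications(g, hits)
  arr <- sprintf("chr1_g%02d", 3:6)
  expect_true(all(lab$mode_of[arr] == "tandem"))
})

test_that("transposed detection requires the outgroup-anchored set", {
  g <- as_genome_table(data.frame(
    gene_id = c("a1", "a2", "b1"),
    chromosome = c("chr1", "chr1", "chr2"),
    start = c(1000L, 99000L, 1000L), end = c(1500L, 99500L, 1500L),
    strand = "+"))
  h <- hit("a1", "b1")
  no_og <- classify_duplications(g, h)
  expect_equal(unname(no_og$mode_of[c("a1", "b1")]),
               c("dispersed", "dispersed"))
  with_og <- classify_duplications(g, h, outgroup_anchored = "a1")
  expect_equal(unname(with_og$mode_of[["b1"]]), "transposed")
  expect_equal(unname(with_og$mode_of[["a1"]]), "dispersed")
  expect_equal(with_og$ancestral_of, c(b1 = "a1"))
})

test_that("unknown gene ids in evidence are rejected", {
  g <- toy_genome(5)
  expect_error(classify_duplications(g, hit("chr1_g01", "nope")),
               "absent from genome")
})

test_that("labeling is exhaustive and exclusive", {
  for (s in 1:3) {
    cfg <- small_config(seed = s)
    sim <- generate_genome(cfg)
    hits <- filter_hits(generate_hits(sim$truth, noise = 0.1))
    lab <- classify_duplications(sim$genome, hits,
                                 sim$truth$planted_blocks,
                                 sim$truth$outgroup_anchored)
    expect_setequal(names(lab$mode_of), sim$genome$gene_id)
    expect_equal(sum(table(lab$mode_of)), nrow(sim$genome))
  }
})

test_that("classification equals the brute-force oracle on small genomes", {
  for (s in 1:5) {
    cfg <- synthetic_config(
      n_chromosomes = 3L, n_ancestral_genes = 150L,
      event_counts = c(wgd_segmental = 2L, tandem = 3L, proximal = 3L,
                       transposed = 2L, dispersed = 2L),
      block_length = 3L, family_size = 10L, seed = s)
    sim <- generate_genome(cfg)
    hits <- filter_hits(generate_hits(sim$truth, noise = 0.15))
    lab <- classify_duplications(sim$genome, hits,
                                 sim$truth$planted_blocks,
                                 sim$truth$outgroup_anchored)
    oracle <- oracle_classify(sim$genome, hits, sim$truth$planted_blocks,
                              sim$truth$outgroup_anchored)
    expect_equal(lab$mode_of, oracle)
  }
})

test_that("noise-free classification recovers the planted truth", {
  cfg <- small_config(seed = 31)
  sim <- generate_genome(cfg)
  hits <- filter_hits(generate_hits(sim$truth, noise = 0))
  lab <- classify_duplications(sim$genome, hits, sim$truth$planted_blocks,
                               sim$truth$outgroup_anchored)
  expect_equal(lab$mode_of, sim$truth$true_mode[names(lab$mode_of)])
})

test_that("adding a block never demotes a gene", {
  cfg <- small_config(seed = 37)
  sim <- generate_genome(cfg)
  hits <- filter_hits(generate_hits(sim$truth))
  lab0 <- classify_duplications(sim$genome, hits, list())
  prec <- c(wgd_segmental = 1, tandem = 2, proximal = 3, transposed = 4,
            dispersed = 5, singleton = 6)
  # put an arbitrary tandem pair into a new block: its genes must move up
  tp <- sim$truth$true_pairs[sim$truth$true_pairs$mode == "tandem", ][1, ]
  b <- list(list(block_id = "x",
                 anchor_pairs = rbind(c(tp$gene1, tp$gene2),
                                      c(sim$genome$gene_id[1],
                                        sim$genome$gene_id[2])),
                 chrom_pair = c(NA, NA), score = NA_real_,
                 e_value = NA_real_))
  lab1 <- classify_duplications(sim$genome, hits, b)
  expect_true(all(prec[lab1$mode_of] <= prec[lab0$mode_of]))
})

test_that("duplication depth counts distinct blocks per anchor", {
  g <- toy_genome(10)
  b1 <- list(block_id = "0",
             anchor_pairs = rbind(c("chr1_g01", "chr1_g05")),
             chrom_pair = c("chr1", "chr1"), score = NA, e_value = NA)
  b2 <- list(block_id = "1",
             anchor_pairs = rbind(c("chr1_g01", "chr1_g08")),
             chrom_pair = c("chr1", "chr1"), score = NA, e_value = NA)
  d <- compute_duplication_depth(g, list(b1, b2))
  expect_equal(unname(d$depth_of[["chr1_g01"]]), 2L)
  expect_equal(d$max_depth, 2L)
  expect_equal(d$median_depth, 1)

  d1 <- compute_duplication_depth(g, list(b1))
  expect_equal(d1$median_depth, 1)
  expect_equal(d1$max_depth, 1L)

  d0 <- compute_duplication_depth(g, list())
  expect_true(is.na(d0$median_depth))
})

test_that("summary percentages follow half-away rounding of count tables", {
  all_genes <- c(wgd_segmental = 7496, dispersed_transposed = 11779,
                 proximal = 1323, tandem = 2875, singleton = 5233)
  s <- tabulate_summary(all_genes)
  expect_equal(s$genome_wide$percent,
               c(26.1, 41.0, 4.6, 10.0, 18.2))
  expect_equal(s$fraction_duplicated, 82)

  focal <- c(wgd_segmental = 335, dispersed_transposed = 444,
             proximal = 67, tandem = 89, singleton = 2)
  sf <- tabulate_summary(focal)
  # 335/937 = 35.752% rounds up; the remaining cells land on .x exactly
  expect_equal(sf$genome_wide$percent, c(35.8, 47.4, 7.2, 9.5, 0.2))

  even <- tabulate_summary(c(a = 1, b = 1, c = 1, d = 1, e = 1))
  expect_true(all(even$genome_wide$percent == 20.0))
  expect_error(tabulate_summary(c(a = 0, b = 0)), "empty labeling")
})

test_that("family counts carry sizes, observed modes and expectations", {
  cfg <- small_config(seed = 41)
  sim <- generate_genome(cfg)
  hits <- filter_hits(generate_hits(sim$truth))
  lab <- classify_duplications(sim$genome, hits, sim$truth$planted_blocks,
                               sim$truth$outgroup_anchored)
  s <- tabulate_summary(lab, family_of = sim$truth$family_of,
                        focal_families = c("fam001", "fam002"))
  fc <- s$family_counts
  expect_equal(sum(fc$N), nrow(sim$genome))
  mode_cols <- c("wgd_segmental", "dispersed", "transposed", "proximal",
                 "tandem", "singleton")
  expect_equal(unname(rowSums(fc[, mode_cols])), fc$N)
  expect_equal(fc$expected_segmental, 0.75 * fc$N)
  expect_true(all(fc$expected_tandem >= 0))
  expect_equal(sum(s$focal$count),
               sum(sim$truth$family_of %in% c("fam001", "fam002")))
})
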