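test_that("gene table reader sorts by coordinate and assigns ranks", {
  p <- write_tsv_lines(c("gB\tchr1\t5000\t5900\t+",
                         "gA\tchr1\t100\t900\t+",
                         "gC\tchr1\t200\t1100\t-"))
  gt <- read_gene_table(p, format = "tsv")
  expect_s3_class(gt, "genome_table")
  expect_equal(gt$gene_id, c("gA", "gC", "gB"))
  expect_equal(gt$rank, c(0L, 1L, 2L))
})

test_that("gene table reader rejects empty and malformed input", {
  expect_error(read_gene_table(write_tsv_lines(character()), "tsv"),
               "no gene records")
  expect_error(read_gene_table(write_tsv_lines("g1\tchr1\t10"), "tsv"),
               "line 1")
  p <- write_tsv_lines(c("g1\tchr1\t10\t90\t+", "g1\tchr1\t200\t300\t+"))
  expect_error(read_gene_table(p, "tsv"), "duplicate gene_id")
})

test_that("GFF3 gene rows are parsed with coordinates intact", {
  p <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\t.\tgene\t10\t90\t.\t+\t.\tID=g1",
               "chr1\t.\tmRNA\t10\t90\t.\t+\t.\tID=t1;Parent=g1",
               "chr1\t.\tgene\t500\t900\t.\t-\t.\tID=g2"), p)
  gt <- read_gene_table(p, format = "gff3")
  expect_equal(nrow(gt), 2L)
  expect_equal(gt$start, c(10L, 500L))
  expect_equal(gt$end[1], 90L)
  expect_equal(gt$strand, c("+", "-"))
})

test_that("gene table round trip preserves content", {
  cfg <- small_config(seed = 3)
  genome <- generate_genome(cfg)$genome
  p <- tempfile()
  write_gene_table(genome, p)
  back <- read_gene_table(p, "tsv")
  expect_equal(back, genome)
})

test_that("collinearity reader handles the block-header dialect", {
  p <- write_tsv_lines(c(
    "############### Parameters ###############",
    "# MATCH_SCORE: 50",
    "## Alignment 0: score=500 e_value=1e-20 N=2 at1&at3 plus",
    "0-0:\tAT1G01010\tAT3G01010\t1e-30",
    "0-1:\tAT1G01020\tAT3G01020\t1e-25",
    "## Alignment 1: score=300 e_value=1e-10 N=2 at2&at2 plus",
    "1-0:\tAT2G01010\tAT2G05010\t1e-12",
    "1-1:\tAT2G01020\tAT2G05020\t1e-11"))
  blocks <- read_collinearity(p)
  expect_length(blocks, 2L)
  expect_equal(blocks[[1]]$block_id, "0")
  expect_equal(nrow(blocks[[1]]$anchor_pairs), 2L)
  expect_equal(blocks[[1]]$anchor_pairs[1, ], c("AT1G01010", "AT3G01010"))
  expect_equal(blocks[[1]]$chrom_pair, c("at1", "at3"))
  expect_equal(blocks[[2]]$block_id, "1")
})

test_that("collinearity reader flags structural problems", {
  expect_error(read_collinearity(write_tsv_lines(
    c("0-0:\tg1\tg2\t1e-10"))), "before any block header")
  expect_error(read_collinearity(write_tsv_lines(
    c("## Alignment 0: score=1 e_value=1 N=1 a&b plus", "0-0:\tg1"))),
    "line 2")
  expect_warning(read_collinearity(write_tsv_lines(
    c("## Alignment 0: score=1 e_value=1 N=3 a&b plus",
      "0-0:\tg1\tg2\t1e-10"))), "N=3 but 1")
})

test_that("collinearity round trip preserves blocks", {
  cfg <- small_config(seed = 5)
  blocks <- generate_genome(cfg)$truth$planted_blocks
  p <- tempfile()
  write_collinearity(blocks, p)
  back <- read_collinearity(p)
  expect_length(back, length(blocks))
  for (i in seq_along(blocks)) {
    expect_equal(unname(back[[i]]$anchor_pairs),
                 unname(blocks[[i]]$anchor_pairs))
    expect_equal(back[[i]]$chrom_pair, blocks[[i]]$chrom_pair)
  }
})

test_that("hit filter applies cutoff, per-query cap and tie rule", {
  hits <- data.frame(
    query = "g1",
    subject = sprintf("s%d", 1:7),
    e_value = c(1e-10, 1e-9, 1e-8, 1e-7, 1e-6, 1e-5, 1e-4))
  out <- filter_hits(hits, max_e = 1e-5, top_k = 5)
  expect_equal(nrow(out), 5L)
  expect_equal(out$subject, sprintf("s%d", 1:5))

  expect_equal(nrow(filter_hits(data.frame(query = "a", subject = "b",
                                           e_value = 1e-4))), 0L)
  # self-hits removed
  expect_equal(nrow(filter_hits(data.frame(query = "a", subject = "a",
                                           e_value = 1e-30))), 0L)
  # ties at the top_k boundary resolved by subject id, deterministically
  tied <- data.frame(query = "g1", subject = c("sZ", "sA", "sB"),
                     e_value = c(1e-8, 1e-8, 1e-8))
  out2 <- filter_hits(tied, top_k = 2)
  expect_equal(out2$subject, c("sA", "sB"))
})

test_that("hit filter is idempotent", {
  set.seed(9)
  hits <- data.frame(query = sample(sprintf("g%d", 1:10), 60, TRUE),
                     subject = sample(sprintf("g%d", 1:10), 60, TRUE),
                     e_value = 10^-runif(60, 2, 12))
  once <- filter_hits(hits)
  twice <- filter_hits(once)
  expect_equal(twice, once)
})

test_that("coverage filter keeps the boundary and removes below it", {
  # 10 match columns; coverage = non-gaps among them
  mk <- function(n_nongap) paste0(strrep("A", n_nongap),
                                  strrep("-", 10 - n_nongap))
  aln <- list(sequences = c(full = mk(10), s7 = mk(7), s6 = mk(6)),
              match_mask = rep(TRUE, 10))
  res <- filter_alignment_coverage(aln, threshold = 0.70)
  expect_equal(unname(res$report), c(1.0, 0.7, 0.6))
  expect_setequal(names(res$retained$sequences), c("full", "s7"))
})

test_that("coverage filter extremes behave as documented", {
  aln <- list(sequences = c(a = "AA--", b = "AAAA", c = "A---"),
              match_mask = c(TRUE, TRUE, TRUE, FALSE))
  all_kept <- filter_alignment_coverage(aln, threshold = 1e-9)
  expect_length(all_kept$retained$sequences, 3L)
  strict <- filter_alignment_coverage(aln, threshold = 1)
  expect_equal(names(strict$retained$sequences), "b")
  expect_error(filter_alignment_coverage(
    list(sequences = c(a = "AA"), match_mask = c(FALSE, FALSE)), 0.7),
    "zero match columns")
})

test_that("profile alignment reader pairs FASTA with its match mask", {
  fa <- tempfile(); mk <- tempfile()
  writeLines(c(">s1", "AC-G", ">s2", "A--G"), fa)
  writeLines("1101", mk)
  aln <- read_profile_alignment(fa, mk)
  expect_equal(names(aln$sequences), c("s1", "s2"))
  expect_equal(sum(aln$match_mask), 3L)
  writeLines("11", mk)
  expect_error(read_profile_alignment(fa, mk), "mask length")
})

test_that("newick, expression and label readers validate their inputs", {
  p <- write_tsv_lines("((a,b),c);")
  tr <- read_newick(p)
  expect_equal(sort(tr$tip.label), c("a", "b", "c"))
  expect_equal(tr$Nnode, 2L)

  ep <- tempfile()
  m <- matrix(rnorm(6), 2, 3,
              dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  write_expression(m, ep)
  back <- read_expression(ep)
  expect_equal(back, m)

  lp <- write_tsv_lines(c("g1\tfamA", "g1\tfamB"))
  expect_error(read_label_table(lp), "conflicting labels")
  lp2 <- write_tsv_lines(c("g1\tfamA", "g2\tfamB", "g1\tfamA"))
  expect_equal(read_label_table(lp2), c(g1 = "famA", g2 = "famB"))
})
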