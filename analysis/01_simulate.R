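#!/usr/bin/env Rscript
# Stage 1: build the synthetic study genome.
#
# Generates a 3000-gene, 5-chromosome genome whose duplication-mode
# composition matches the genome-wide summary the analysis models
# (~26% WGD/segmental, ~41% dispersed+transposed, ~4.6% proximal, ~10%
# tandem, ~18% singleton), together with homology hits, collinear blocks,
# expression profiles and full ground truth, and writes all of it in the
# package's interchange formats under results/data/.

library(kinomedup)

seed <- 20260930L %% 100000L
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

cfg <- synthetic_config(seed = seed)
sim <- generate_genome(cfg)
hits <- generate_hits(sim$truth, noise = 0.05)
expr <- generate_expression(sim$truth, cfg)

write_gene_table(sim$genome, "results/data/genes.tsv")
write_collinearity(sim$truth$planted_blocks, "results/data/blocks.collinearity")
write.table(hits, "results/data/hits.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE, col.names = FALSE)
write_expression(expr, "results/data/expression.tsv")
writeLines(sim$truth$outgroup_anchored, "results/data/outgroup_anchored.txt")
write.table(data.frame(gene = names(sim$truth$family_of),
                       family = unname(sim$truth$family_of)),
            "results/data/families.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE, col.names = FALSE)
write.table(data.frame(gene = names(sim$truth$true_mode),
                       mode = unname(sim$truth$true_mode)),
            "results/data/true_modes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE, col.names = FALSE)
# later stages rebuild the ground truth deterministically from this seed

comp <- round(100 * prop.table(table(sim$truth$true_mode)), 1)
message("simulated ", nrow(sim$genome), " genes on ",
        cfg$n_chromosomes, " chromosomes; mode composition (%):")
message(paste(names(comp), comp, sep = "=", collapse = "  "))
message("planted ", nrow(sim$truth$true_pairs), " duplicate pairs and ",
        length(sim$truth$planted_blocks), " collinear blocks")
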