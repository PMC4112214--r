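#!/usr/bin/env Rscript
# Stage 4: family-by-mode enrichment and phenotype-class enrichment.
#
# Tests every family x mode cell with a two-sided Fisher's exact test
# against the other families, BH-adjusts jointly, and reports Pearson
# residuals; then tests a planted phenotype enrichment in a focal set.

library(kinomedup)

seed <- 20260930L %% 100000L
fc <- read.delim("results/family_counts.tsv", check.names = FALSE)
modes <- c("wgd_segmental", "tandem", "proximal", "transposed",
           "dispersed", "singleton")
obs <- as.matrix(fc[, modes])
rownames(obs) <- fc$family

enr <- fisher_enrichment(obs)
write.table(enr, "results/enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
sig <- enr[enr$p_adjusted < 0.05, ]
message(nrow(sig), " of ", nrow(enr),
        " family-mode combinations significant after BH (alpha 0.05)")

# phenotype classes with a planted enrichment for essential phenotypes in
# a focal ("kinase-like") set of 400 genes; the ground truth is rebuilt
# deterministically from the stage-1 seed
cfg <- synthetic_config(seed = seed)
truth <- generate_genome(cfg)$truth
genes <- names(truth$true_mode)
focal <- genes[seq_len(400)]
ph <- generate_phenotypes(truth, cfg, focal = focal,
                          boost_class = "essential", boost_odds = 6,
                          seed = seed + 3L)
pe <- phenotype_enrichment(ph, focal)
write.table(pe, "results/phenotype_enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
ess <- pe[pe$class == "essential", ]
message(sprintf(
  "planted essential-phenotype enrichment: odds ratio %.2f, adjusted p %.3g",
  ess$odds_ratio, ess$p_adjusted))
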