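#!/usr/bin/env Rscript
# Stage 6: phylogeny annotation, MRCA duplication mapping, and
# interaction-network degree statistics by duplication mode.

library(kinomedup)

seed <- 20260930L %% 100000L
cfg <- synthetic_config(seed = seed)
truth <- generate_genome(cfg)$truth
pairs <- read.delim("results/pairs.tsv")
labels <- read.delim("results/labels.tsv")
lab <- structure(list(mode_of = setNames(labels$mode, labels$gene),
                      pairs = pairs),
                 class = "duplication_labeling")

tree <- generate_kinome_tree(truth)
fam_pairs <- pairs[pairs$gene1 %in% tree$tip.label &
                     pairs$gene2 %in% tree$tip.label, ]
mk <- map_duplications_to_tree(tree, fam_pairs)
write.table(mk, "results/mrca_marking.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("mapped ", nrow(mk), " duplicate pairs to ",
        length(unique(mk$node)), " ancestral nodes")

known <- truth$family_of[tree$tip.label]
hidden <- seq(1, length(known), by = 10)
ann <- annotate_by_clade(tree, known[-hidden])
acc <- mean(ann$proposals$proposed_family ==
              truth$family_of[ann$proposals$gene_id])
write.table(ann$proposals, "results/annotation_proposals.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf(
  "proposed families for %d unlabeled tips; %.1f%% match the truth",
  nrow(ann$proposals), 100 * acc))

# one planted hub (degree 25) on top of the Poisson background
hub <- names(truth$true_mode)[42]
edges <- generate_interactions(truth, cfg, hub_genes = hub,
                               hub_degree = 25L)
ds <- degree_stats(edges, focal = names(truth$true_mode), labeling = lab)
write.table(data.frame(gene = names(ds$degree_of),
                       degree = unname(ds$degree_of)),
            "results/degrees.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("mean interaction degree %.2f; %d hub gene(s) at >= 20",
                ds$mean_degree, length(ds$hubs)))
message("mean degree by mode: ",
        paste(sprintf("%s=%.2f", names(ds$mean_degree_by_mode),
                      ds$mean_degree_by_mode), collapse = "  "))
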