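# kinomedup

Duplication-mode analysis of gene families: classify every gene of a
genome as a WGD/segmental, tandem, proximal, transposed, dispersed or
singleton locus; test which families are enriched or depleted for each
mode; and quantify how expression of duplicate pairs diverges by mode.

The package is written for the kind of analysis applied to the
*Arabidopsis thaliana* kinome — a gene family of interest is carved out
of a genome-scale duplication scan, family-level statistics are computed
against explicit null models, and the duplication history is mapped onto
the family phylogeny — but every stage is generic over any annotated
genome and family labeling.

## What it computes

**Classification.** From gene order, filtered homology hits
(E ≤ 10⁻⁵, best 5 per gene), within-genome collinear blocks and an
optional set of outgroup-anchored loci, `classify_duplications()`
assigns one mode per gene by precedence:
block anchor → WGD/segmental; same-chromosome hit pair at rank
distance 1 → tandem (arrays link transitively); rank distance 2–20 →
proximal; pair with exactly one outgroup-anchored member → the other
member transposed; any remaining pair → dispersed; no evidence →
singleton.

**Null models.** The expected number of tandem pairs in a family of
size *N* follows from dropping *N* 1-kb genes uniformly on a 100,000-kb
genome and counting pairs within a 50-kb window (Monte Carlo over a
10–300 grid, 1000 replicates, with the closed form
C(N,2)·(2w/L′ − (w/L′)²) as an independent check). The expected number
of segmental duplicates is segexp = 0.75·N, from the genome fraction
covered by duplicated blocks. Observed/expected ratios per family are
banded around the cross-family median at ±1 and ±2 sample SDs.

**Enrichment.** Every family × mode cell is tested with a two-sided
Fisher's exact test against the other families, jointly
Benjamini–Hochberg corrected, with Pearson residuals (O−E)/√E giving
direction and strength. The same machinery tests phenotype-class
enrichment of a focal gene set.

**Phylogeny.** Duplicate pairs map to the most recent common ancestor
of their tips; unlabeled tips receive family proposals from sister-clade
unanimity or clade majority, never overwriting an existing label.

**Coexpression and networks.** Pearson correlations of expression
profiles are summarized per duplication mode against a random-pair
baseline, with dual gene orderings (coexpression clustering vs phylogeny
tip order); interaction-network degrees are summarized per mode with
hub calling at degree ≥ 20.

**Synthetic genomes.** Because the upstream tools (BLAST, collinearity
scans, expression compendia) are out of scope, `generate_genome()` and
its companions plant duplication events of every mode with full ground
truth — known modes, pairs, blocks, family trees whose nodes are the
planted events, expression with mode-specific correlation, phenotypes
and interaction degrees with plantable enrichments. The whole pipeline
is validated against this truth.

## Worked example

```r
library(kinomedup)

cfg <- synthetic_config(seed = 60930)   # 3000 genes, 5 chromosomes
sim <- generate_genome(cfg)
hits <- filter_hits(generate_hits(sim$truth, noise = 0.05))
lab <- classify_duplications(sim$genome, hits, sim$truth$planted_blocks,
                             outgroup_anchored = sim$truth$outgroup_anchored)
mean(lab$mode_of == sim$truth$true_mode[names(lab$mode_of)])
#> [1] 0.991
tabulate_summary(lab)$genome_wide
#>            mode count percent
#> 1 wgd_segmental   780    26.0
#> 2     dispersed  1045    34.8
#> 3    transposed   210     7.0
#> 4      proximal   138     4.6
#> 5        tandem   300    10.0
#> 6     singleton   527    17.6
```

At a 5% spurious-hit rate, 99.1% of genes are restored to their planted
mode (with noise-free hits, recovery is exact), and the mode composition
reproduces the genome-wide summary the generator is calibrated to:
about 26% WGD/segmental, 41% dispersed+transposed combined, 4.6%
proximal, 10% tandem and 18% singleton, i.e. roughly 82% of genes
derive from some duplication event. Expression divergence then follows
the configured mode ladder:

```r
expr <- generate_expression(sim$truth, cfg)
r <- pairwise_correlation(expr, genes = unique(c(lab$pairs$gene1,
                                                 lab$pairs$gene2)))
correlation_by_mode(r$correlations, lab$pairs, n_random = 1000,
                    seed = 1)$summary[, c("mode", "n", "mean")]
#>            mode    n         mean
#> 1 wgd_segmental  390  0.700305316
#> 2        tandem  150  0.402345850
#> 3      proximal   70  0.095267674
#> 4    transposed  214 -0.004413070
#> 5     dispersed  462  0.045932783
#> 6        random 1000 -0.001454083
```

Segmental pairs stay strongly coexpressed (mean r ≈ 0.70), tandem pairs
moderately (≈ 0.40), while transposed pairs are indistinguishable from
random pairs — the generator's encoding of the conservation-by-mode
ordering, recovered from the expression matrix by the analysis.

The `analysis/` directory holds the same workflow as six numbered
driver scripts (simulate → classify → expectations → enrichment →
coexpression → phylogeny/network), each writing its tables under
`results/` and printing a one-paragraph narrative of what it found.

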