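Package: kinomedup
Title: Duplication-Mode Analysis of Gene Families
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies gene duplications into tandem, proximal,
    whole-genome/segmental, transposed and dispersed modes from gene order,
    homology hits and collinear blocks; computes Monte Carlo and analytic
    null expectations for tandem and segmental duplicate counts; performs
    family-by-mode enrichment with Fisher's exact test, Benjamini-Hochberg
    correction and Pearson residuals; maps duplicate pairs to ancestral
    nodes of a phylogeny and proposes clade-based family annotations;
    quantifies coexpression divergence of duplicate pairs; and summarises
    interaction-network degrees by duplication mode. Includes a synthetic
    genome generator that plants duplication events of every mode with
    full ground truth, used as the test substrate for the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    GenomicRanges,
    phangorn,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
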