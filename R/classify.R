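#' Classification parameters
#'
#' @param proximal_max_rank_distance largest same-chromosome rank distance
#'   treated as proximal (default 20, the 20-gene window; tandem is rank
#'   distance exactly 1).
#' @param precedence mode precedence, highest first; a gene's mode is the
#'   highest-precedence mode among its duplicate pairs (block anchorship
#'   counts as a segmental pair).
#' @return a \code{classification_params} list.
#' @export
classification_params <- function(
    proximal_max_rank_distance = 20L,
    precedence = c("wgd_segmental", "tandem", "proximal", "transposed",
                   "dispersed")) {
  stopifnot(proximal_max_rank_distance > 1L)
  if (!setequal(precedence, c("wgd_segmental", "tandem", "proximal",
                              "transposed", "dispersed")))
    stop_validation("precedence must be a permutation of the five modes")
  structure(list(proximal_max_rank_distance =
                   as.integer(proximal_max_rank_distance),
                 precedence = precedence),
            class = "classification_params")
}

#' Classify every gene into a duplication mode
#'
#' Assigns one of \code{wgd_segmental, tandem, proximal, transposed,
#' dispersed, singleton} to each gene, following the rule cascade used by
#' collinearity-based duplication classifiers: (1) genes with no retained
#' hit and no block anchorship are singletons; (2) genes anchored in at
#' least one within-genome collinear block are WGD/segmental; (3) hit pairs
#' on one chromosome at rank distance 1 (transitively linked into arrays)
#' are tandem; (4) same-chromosome pairs within the proximal window are
#' proximal; (5) pairs in which exactly one member carries outgroup
#' collinearity support (the ancestral locus) mark the other member as
#' transposed; (6) every remaining duplicated gene is dispersed. A gene
#' with several pairs takes the highest-precedence mode.
#'
#' @param genome a \code{genome_table}.
#' @param hits homology hits that already passed [filter_hits()].
#' @param blocks list of collinear blocks (within-genome).
#' @param outgroup_anchored optional character vector of genes whose locus
#'   is supported by outgroup collinearity; when absent, step (5) is
#'   skipped and such pairs remain dispersed.
#' @param params a [classification_params()].
#' @return a \code{duplication_labeling}: list with \code{mode_of} (named
#'   character vector over all genes), \code{pairs} (data.frame gene1,
#'   gene2, mode; transposed pairs are directional with gene1 the moved
#'   copy) and \code{ancestral_of} (named vector for transposed genes).
#' @export
classify_duplications <- function(genome, hits, blocks = list(),
                                  outgroup_anchored = NULL,
                                  params = classification_params()) {
  stopifnot(inherits(genome, "genome_table"))
  gid <- genome$gene_id
  block_genes <- unique(unlist(lapply(blocks, function(b)
    as.vector(b$anchor_pairs))))
  unknown <- setdiff(c(hits$query, hits$subject, block_genes), gid)
  if (length(unknown))
    stop_validation("gene ids absent from genome: ",
                    paste(utils::head(unknown, 5), collapse = ", "))

  chrom <- stats::setNames(genome$chromosome, gid)
  rank <- stats::setNames(genome$rank, gid)

  # undirected unique hit pairs
  if (nrow(hits)) {
    a <- pmin(hits$query, hits$subject)
    b <- pmax(hits$query, hits$subject)
    pk <- !duplicated(paste(a, b))
    pair_df <- data.frame(a = a[pk], b = b[pk], stringsAsFactors = FALSE)
  } else {
    pair_df <- data.frame(a = character(), b = character())
  }

  # anchor-pair lookup for rule 2 pair typing
  anchor_key <- unlist(lapply(blocks, function(bl) {
    ap <- bl$anchor_pairs
    c(paste(ap[, 1], ap[, 2]), paste(ap[, 2], ap[, 1]))
  }))

  same_chrom <- chrom[pair_df$a] == chrom[pair_df$b]
  rd <- abs(rank[pair_df$a] - rank[pair_df$b])
  in_block <- paste(pair_df$a, pair_df$b) %in% anchor_key
  og <- !is.null(outgroup_anchored)
  a_anc <- pair_df$a %in% outgroup_anchored
  b_anc <- pair_df$b %in% outgroup_anchored

  pair_mode <- ifelse(in_block, "wgd_segmental",
               ifelse(same_chrom & rd == 1, "tandem",
               ifelse(same_chrom & rd >= 2 &
                        rd <= params$proximal_max_rank_distance, "proximal",
               ifelse(og & xor(a_anc, b_anc), "transposed", "dispersed"))))

  # directional orientation for transposed pairs: gene1 = moved copy
  g1 <- pair_df$a; g2 <- pair_df$b
  flip <- pair_mode == "transposed" & a_anc
  tmp <- g1[flip]; g1[flip] <- g2[flip]; g2[flip] <- tmp

  pairs <- data.frame(gene1 = g1, gene2 = g2, mode = pair_mode,
                      stringsAsFactors = FALSE)

  prec <- c(stats::setNames(seq_along(params$precedence), params$precedence),
            singleton = length(params$precedence) + 1L)
  mode_of <- stats::setNames(rep("singleton", length(gid)), gid)
  # block anchorship alone makes a gene segmental
  mode_of[block_genes] <- "wgd_segmental"
  if (nrow(pairs)) {
    long <- data.frame(gene = c(pairs$gene1, pairs$gene2),
                       mode = rep(pairs$mode, 2),
                       stringsAsFactors = FALSE)
    # the ancestral partner of a transposed pair is not itself transposed;
    # it falls through to dispersed unless other evidence applies
    long$mode[seq(nrow(pairs) + 1L, 2L * nrow(pairs))][
      pairs$mode == "transposed"] <- "dispersed"
    best <- tapply(prec[long$mode], long$gene, min)
    upd <- names(best)
    better <- prec[mode_of[upd]] > best
    mode_of[upd[better]] <- params$precedence[best[better]]
  }

  tr <- pairs[pairs$mode == "transposed", , drop = FALSE]
  ancestral_of <- stats::setNames(tr$gene2, tr$gene1)

  structure(list(mode_of = mode_of, pairs = pairs,
                 ancestral_of = ancestral_of),
            class = "duplication_labeling")
}

#' Duplication depth from collinear blocks
#'
#' Depth of a gene is the number of distinct blocks in which it appears as
#' an anchor. The median is taken over genes with depth >= 1.
#'
#' @param genome a \code{genome_table}.
#' @param blocks list of collinear blocks.
#' @return list with \code{depth_of} (named integer vector over all genes),
#'   \code{median_depth} and \code{max_depth} (NA when no gene is anchored).
#' @export
compute_duplication_depth <- function(genome, blocks) {
  depth <- stats::setNames(rep(0L, nrow(genome)), genome$gene_id)
  for (b in blocks) {
    g <- unique(as.vector(b$anchor_pairs))
    depth[g] <- depth[g] + 1L
  }
  pos <- depth[depth >= 1L]
  list(depth_of = depth,
       median_depth = if (length(pos)) stats::median(pos) else NA_real_,
       max_depth = if (length(pos)) max(pos) else NA_integer_)
}

#' Tabulate a genome-wide and focal-set duplication summary
#'
#' Produces mode counts with percentages for the whole labeling, per-family
#' counts with null expectations, and a focal-set (e.g. kinase) column, in
#' the layout of a duplication-summary table. Percentages use the column's
#' own count sum as denominator and are rounded half away from zero to one
#' decimal; the headline "fraction duplicated" is rounded to the nearest
#' integer.
#'
#' @param labeling a \code{duplication_labeling}, or a named integer vector
#'   of mode counts (modes as names) for table-only arithmetic.
#' @param family_of optional named vector gene -> family.
#' @param focal_families optional character vector of focal family names.
#' @param tandem_expectation optional function N -> expected tandem count
#'   used to fill per-family expectations (see
#'   [make_tandem_expectation()]); defaults to [analytic_expected_tandem()].
#' @return list with \code{genome_wide} (data.frame mode, count, percent),
#'   \code{fraction_duplicated}, and when family information is given,
#'   \code{family_counts} and \code{focal} summaries.
#' @export
tabulate_summary <- function(labeling, family_of = NULL,
                             focal_families = NULL,
                             tandem_expectation = NULL) {
  mode_levels <- c("wgd_segmental", "dispersed", "transposed", "proximal",
                   "tandem", "singleton")
  if (is.numeric(labeling)) {
    counts <- labeling
    mode_of <- NULL
  } else {
    mode_of <- labeling$mode_of
    if (length(mode_of) == 0L) stop_validation("empty labeling")
    counts <- table(factor(mode_of, levels = mode_levels))
    counts <- stats::setNames(as.integer(counts), names(counts))
  }
  if (sum(counts) == 0L) stop_validation("empty labeling")
  pct <- round_half_away(100 * counts / sum(counts), 1)
  genome_wide <- data.frame(mode = names(counts),
                            count = as.integer(counts),
                            percent = as.numeric(pct),
                            stringsAsFactors = FALSE)
  singleton <- if ("singleton" %in% names(counts))
    counts[["singleton"]] else 0L
  fraction_duplicated <-
    round_half_away(100 * (1 - singleton / sum(counts)), 0)

  out <- list(genome_wide = genome_wide,
              fraction_duplicated = as.numeric(fraction_duplicated))

  if (!is.null(mode_of) && !is.null(family_of)) {
    if (is.null(tandem_expectation))
      tandem_expectation <- function(N)
        analytic_expected_tandem(N)
    fams <- sort(unique(family_of))
    fc <- lapply(fams, function(f) {
      g <- names(family_of)[family_of == f]
      m <- factor(mode_of[g], levels = mode_levels)
      obs <- stats::setNames(as.integer(table(m)), mode_levels)
      N <- length(g)
      data.frame(family = f, N = N, t(obs),
                 expected_tandem = tandem_expectation(N),
                 expected_segmental = expected_segmental(N),
                 check.names = FALSE, stringsAsFactors = FALSE)
    })
    out$family_counts <- do.call(rbind, fc)
    if (!is.null(focal_families)) {
      fg <- names(family_of)[family_of %in% focal_families]
      fm <- table(factor(mode_of[fg], levels = mode_levels))
      fm <- stats::setNames(as.integer(fm), mode_levels)
      fpct <- round_half_away(100 * fm / sum(fm), 1)
      out$focal <- data.frame(mode = names(fm), count = as.integer(fm),
                              percent = as.numeric(fpct),
                              stringsAsFactors = FALSE)
    }
  }
  out
}
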