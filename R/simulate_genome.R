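#' Configuration for the synthetic genome generator
#'
#' The generator plants duplication events of every mode into a multi-
#' chromosome genome of 1-kb genes and records full ground truth, providing
#' the test substrate for the classifier, the enrichment machinery, the
#' coexpression analysis and the phylogeny mapping.
#'
#' Defaults describe the study conditions used throughout the package's own
#' analyses: 5 chromosomes and a 3000-gene genome whose event mix is
#' calibrated so the resulting mode composition matches the genome-wide
#' duplication summary of the Arabidopsis analysis this package models
#' (about 26% WGD/segmental, 41% dispersed+transposed, 4.6% proximal, 10%
#' tandem, 18% singleton), 500 expression samples, and per-mode expression
#' correlations ordered segmental > tandem > proximal > dispersed >
#' transposed.
#'
#' @param n_chromosomes number of chromosomes.
#' @param n_ancestral_genes ancestral (pre-duplication) gene count.
#' @param event_counts named integer vector of planted event counts for
#'   modes \code{wgd_segmental, tandem, proximal, transposed, dispersed}.
#' @param block_length genes per planted segmental block.
#' @param family_size ancestral genes per family (families partition the
#'   ancestral gene set; copies inherit their source's family).
#' @param family_bias optional named list \code{mode -> named weights}
#'   multiplying a family's chance of sourcing events of that mode; used to
#'   plant family-level enrichments in expectation.
#' @param family_event_quota optional named list \code{mode -> named
#'   integer vector family -> event count}: exactly that many events of the
#'   mode are sourced from the family, planting an enrichment of fixed
#'   magnitude (the remaining events are drawn from the other families).
#' @param proximal_max_rank_distance largest rank separation planted for
#'   proximal copies (window of 20 genes, non-adjacent).
#' @param dispersed_min_rank_distance smallest same-chromosome rank
#'   separation for dispersed copies (21, i.e. more than the proximal
#'   window).
#' @param gene_size_bp,gene_spacing_bp gene length and start-to-start
#'   spacing used when coordinates are laid out after all insertions.
#' @param expression_samples number of expression samples.
#' @param rho_by_mode named numeric vector of target expression correlations
#'   between a duplicate and its source, per mode.
#' @param phenotype_class_probs named probability vector over phenotype
#'   classes (must sum to 1).
#' @param degree_lambda mean interaction degree for the interaction
#'   generator.
#' @param seed integer seed; every generator derives its own substream.
#' @return a \code{synthetic_config} list.
#' @export
synthetic_config <- function(n_chromosomes = 5L,
                             n_ancestral_genes = 1776L,
                             event_counts = c(wgd_segmental = 78L,
                                              tandem = 150L,
                                              proximal = 69L,
                                              transposed = 205L,
                                              dispersed = 410L),
                             block_length = 5L,
                             family_size = 60L,
                             family_bias = NULL,
                             family_event_quota = NULL,
                             proximal_max_rank_distance = 20L,
                             dispersed_min_rank_distance = 21L,
                             gene_size_bp = 1000L,
                             gene_spacing_bp = 4000L,
                             expression_samples = 500L,
                             rho_by_mode = c(wgd_segmental = 0.7,
                                             tandem = 0.4,
                                             proximal = 0.1,
                                             dispersed = 0.05,
                                             transposed = 0.0),
                             phenotype_class_probs = c(
                               none = 0.900,
                               conditional = 0.045,
                               morphological = 0.029,
                               essential = 0.018,
                               `cellular-biochemical` = 0.008),
                             degree_lambda = 4.7,
                             seed = 1L) {
  modes <- c("wgd_segmental", "tandem", "proximal", "transposed", "dispersed")
  full <- stats::setNames(integer(5), modes)
  full[names(event_counts)] <- as.integer(event_counts)
  if (any(full < 0)) stop_validation("event counts must be >= 0")
  if (abs(sum(phenotype_class_probs) - 1) > 1e-8)
    stop_validation("phenotype class probabilities must sum to 1")
  if (any(rho_by_mode < -1 | rho_by_mode > 1))
    stop_validation("rho_by_mode values must lie in [-1, 1]")
  structure(list(
    n_chromosomes = as.integer(n_chromosomes),
    n_ancestral_genes = as.integer(n_ancestral_genes),
    event_counts = full,
    block_length = as.integer(block_length),
    family_size = as.integer(family_size),
    family_bias = family_bias,
    family_event_quota = family_event_quota,
    proximal_max_rank_distance = as.integer(proximal_max_rank_distance),
    dispersed_min_rank_distance = as.integer(dispersed_min_rank_distance),
    gene_size_bp = as.integer(gene_size_bp),
    gene_spacing_bp = as.integer(gene_spacing_bp),
    expression_samples = as.integer(expression_samples),
    rho_by_mode = rho_by_mode,
    phenotype_class_probs = phenotype_class_probs,
    degree_lambda = degree_lambda,
    seed = as.integer(seed)),
    class = "synthetic_config")
}

#' Generate a synthetic genome with planted duplication events
#'
#' Each gene participates in at most one event, sources are drawn from the
#' unused ancestral pool, and insertion points that would break an earlier
#' tandem adjacency or stretch an earlier proximal span beyond the window
#' are never used; under a noise-free hit set the planted modes are
#' therefore recovered exactly by the classifier.
#'
#' Event mechanics: a tandem copy is inserted at rank distance 1 from its
#' source; a proximal copy at a uniform rank distance 2..20 on the same
#' chromosome; a segmental event copies \code{block_length} consecutive
#' unused genes to another location preserving order and emits the matching
#' collinear block; a transposed copy lands on a uniformly chosen other
#' chromosome with its ancestral locus recorded; a dispersed copy lands
#' anywhere at least 21 ranks from its source. Remaining genes are
#' singletons. Coordinates are laid out on a uniform grid after all
#' insertions.
#'
#' @param config a [synthetic_config()].
#' @return list with \code{genome} (a \code{genome_table}) and \code{truth}
#'   (ground-truth record: \code{true_mode}, \code{true_pairs},
#'   \code{planted_blocks}, \code{family_of}, \code{outgroup_anchored},
#'   \code{event_log}).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(substream_seed(config$seed, "genome"), generate_genome_impl(config))
}

generate_genome_impl <- function(config) {
  n_anc <- config$n_ancestral_genes
  nchr <- config$n_chromosomes
  ev <- config$event_counts
  blk <- config$block_length

  sources_needed <- ev[["tandem"]] + ev[["proximal"]] + ev[["transposed"]] +
    ev[["dispersed"]] + ev[["wgd_segmental"]] * blk
  if (sources_needed > n_anc)
    stop_validation("event counts exceed placeable capacity: need ",
                    sources_needed, " source genes but only ", n_anc,
                    " ancestral genes")

  ids <- sprintf("g%05d", seq_len(n_anc))
  chrom_names <- sprintf("chr%d", seq_len(nchr))
  # contiguous, near-equal chromosome fills
  sizes <- diff(floor(seq(0, n_anc, length.out = nchr + 1)))
  chrom_of_anc <- rep(chrom_names, times = sizes)
  chroms <- split(ids, factor(chrom_of_anc, levels = chrom_names))

  # family assignment: random partition of ancestral genes into families
  n_fam <- max(1L, ceiling(n_anc / config$family_size))
  fam_names <- sprintf("fam%03d", seq_len(n_fam))
  fam_assign <- sample(rep(fam_names, length.out = n_anc))
  family_of <- stats::setNames(fam_assign, ids)

  used <- stats::setNames(rep(FALSE, n_anc), ids)
  protected <- new.env(hash = TRUE)  # keys "chrom|left_gene_id"
  protect <- function(chrom, left_ids)
    for (g in left_ids) assign(paste0(chrom, "|", g), TRUE, envir = protected)
  is_protected <- function(chrom, left_id)
    !is.null(protected[[paste0(chrom, "|", left_id)]])

  true_mode <- stats::setNames(rep("singleton", n_anc), ids)
  pairs <- list()
  blocks <- list()
  event_log <- list()
  outgroup_anchored <- character()
  copy_counter <- 0L
  new_copy_id <- function() {
    copy_counter <<- copy_counter + 1L
    sprintf("c%05d", copy_counter)
  }

  chrom_of <- function(g) {
    for (cn in chrom_names) if (g %in% chroms[[cn]]) return(cn)
    stop("gene not found: ", g)
  }

  insert_after <- function(chrom, pos, new_ids) {
    # pos = 0 inserts at chromosome start
    v <- chroms[[chrom]]
    chroms[[chrom]] <<- append(v, new_ids, after = pos)
  }

  quota <- lapply(config$family_event_quota, function(q)
    stats::setNames(as.integer(q), names(q)))

  pick_source <- function(mode) {
    pool <- names(used)[!used]
    if (length(pool) == 0L) stop_validation("no unused source genes left")
    q <- quota[[mode]]
    if (!is.null(q) && any(q > 0L)) {
      f <- names(q)[q > 0L][1]
      fpool <- pool[family_of[pool] == f]
      if (length(fpool) == 0L)
        stop_validation("family ", f, " exhausted before its ", mode,
                        " event quota was met")
      return(if (length(fpool) == 1L) fpool else sample(fpool, 1L))
    }
    w <- rep(1, length(pool))
    bias <- config$family_bias[[mode]]
    if (!is.null(bias)) {
      fam <- family_of[pool]
      idx <- match(fam, names(bias))
      w[!is.na(idx)] <- w[!is.na(idx)] * bias[idx[!is.na(idx)]]
      # quota-free events under a quota regime avoid the quota families
    }
    if (!is.null(q)) w[family_of[pool] %in% names(q)] <- 0
    if (all(w == 0)) w <- rep(1, length(pool))
    sample(pool, 1L, prob = w)
  }

  # segmental events first, while long runs of untouched genes still exist
  # (they are also the oldest events in real genomes); the rest interleave
  # in random order
  queue <- c(rep("wgd_segmental", ev[["wgd_segmental"]]),
             sample(rep(setdiff(names(ev), "wgd_segmental"),
                        times = ev[setdiff(names(ev), "wgd_segmental")])))
  for (mode in queue) {
    placed <- FALSE
    for (try in seq_len(500L)) {
      if (mode == "tandem") {
        s <- pick_source(mode)
        cn <- chrom_of(s)
        if (is_protected(cn, s)) next
        cp <- new_copy_id()
        insert_after(cn, match(s, chroms[[cn]]), cp)
        protect(cn, s)
        used[s] <- TRUE
        true_mode[s] <- "tandem"; true_mode[cp] <- "tandem"
        family_of[cp] <- family_of[[s]]
        pairs[[length(pairs) + 1L]] <-
          data.frame(gene1 = s, gene2 = cp, mode = mode,
                     ancestral = NA_character_)
        event_log[[length(event_log) + 1L]] <-
          list(mode = mode, source = s, copies = cp, chrom = cn)
        placed <- TRUE
      } else if (mode == "proximal") {
        s <- pick_source(mode)
        cn <- chrom_of(s)
        v <- chroms[[cn]]
        r <- match(s, v)  # 1-based position
        d <- sample(2:config$proximal_max_rank_distance, 1L)
        # copy goes after position r + d - 1 so final rank distance is d
        if (r + d - 1L > length(v)) next
        span_left <- v[r:(r + d - 1L)]
        if (any(vapply(span_left, is_protected, TRUE, chrom = cn))) next
        cp <- new_copy_id()
        insert_after(cn, r + d - 1L, cp)
        protect(cn, span_left)
        used[s] <- TRUE
        true_mode[s] <- "proximal"; true_mode[cp] <- "proximal"
        family_of[cp] <- family_of[[s]]
        pairs[[length(pairs) + 1L]] <-
          data.frame(gene1 = s, gene2 = cp, mode = mode,
                     ancestral = NA_character_)
        event_log[[length(event_log) + 1L]] <-
          list(mode = mode, source = s, copies = cp, chrom = cn,
               rank_distance = d)
        placed <- TRUE
      } else if (mode == "wgd_segmental") {
        # need block_length consecutive unused ancestral genes
        cn <- sample(chrom_names, 1L)
        v <- chroms[[cn]]
        if (length(v) < blk) next
        ok_gene <- v %in% names(used)[!used]
        run <- which(stats::filter(as.numeric(ok_gene), rep(1, blk),
                                   sides = 1) == blk)
        if (length(run) == 0L) next
        end_pos <- sample(run, 1L)
        src_run <- v[(end_pos - blk + 1L):end_pos]
        # destination: any chromosome, unprotected gap
        dst <- sample(chrom_names, 1L)
        w <- chroms[[dst]]
        gaps <- 0:length(w)  # insert after these positions
        gap_ok <- vapply(gaps, function(p) {
          if (p == 0L) return(TRUE)
          !is_protected(dst, w[p])
        }, TRUE)
        # avoid inserting inside the source run itself
        if (dst == cn) {
          inside <- gaps >= (end_pos - blk + 1L) & gaps < end_pos
          gap_ok <- gap_ok & !inside
        }
        gaps <- gaps[gap_ok]
        if (length(gaps) == 0L) next
        p <- sample(gaps, 1L)
        cps <- vapply(src_run, function(x) new_copy_id(), "")
        insert_after(dst, p, unname(cps))
        used[src_run] <- TRUE
        true_mode[src_run] <- "wgd_segmental"
        true_mode[cps] <- "wgd_segmental"
        family_of[cps] <- family_of[src_run]
        names(family_of)[match(cps, names(family_of))] <- cps
        for (k in seq_len(blk))
          pairs[[length(pairs) + 1L]] <-
            data.frame(gene1 = src_run[k], gene2 = unname(cps[k]),
                       mode = mode, ancestral = NA_character_)
        bid <- as.character(length(blocks))
        blocks[[length(blocks) + 1L]] <-
          list(block_id = bid,
               anchor_pairs = cbind(src_run, unname(cps), deparse.level = 0),
               chrom_pair = c(cn, dst), score = NA_real_, e_value = NA_real_)
        event_log[[length(event_log) + 1L]] <-
          list(mode = mode, source = paste(src_run, collapse = ","),
               copies = paste(cps, collapse = ","), chrom = cn,
               dest_chrom = dst, block_id = bid)
        placed <- TRUE
      } else if (mode == "transposed") {
        if (nchr < 2L)
          stop_validation("transposed events need >= 2 chromosomes")
        s <- pick_source(mode)
        cn <- chrom_of(s)
        dst <- sample(setdiff(chrom_names, cn), 1L)
        w <- chroms[[dst]]
        gaps <- Filter(function(p) p == 0L || !is_protected(dst, w[p]),
                       0:length(w))
        if (length(gaps) == 0L) next
        p <- if (length(gaps) == 1L) gaps[[1]] else sample(gaps, 1L)
        cp <- new_copy_id()
        insert_after(dst, p, cp)
        used[s] <- TRUE
        # the copy is transposed; the ancestral locus, having no other
        # duplication evidence, classifies as dispersed (rule fall-through)
        true_mode[cp] <- "transposed"
        true_mode[s] <- "dispersed"
        outgroup_anchored <- c(outgroup_anchored, s)
        family_of[cp] <- family_of[[s]]
        pairs[[length(pairs) + 1L]] <-
          data.frame(gene1 = cp, gene2 = s, mode = mode, ancestral = s)
        event_log[[length(event_log) + 1L]] <-
          list(mode = mode, source = s, copies = cp, chrom = cn,
               dest_chrom = dst)
        placed <- TRUE
      } else { # dispersed
        s <- pick_source(mode)
        cn <- chrom_of(s)
        dst <- sample(chrom_names, 1L)
        w <- chroms[[dst]]
        gaps <- 0:length(w)
        gap_ok <- vapply(gaps, function(p)
          p == 0L || !is_protected(dst, w[p]), TRUE)
        if (dst == cn) {
          r <- match(s, w)
          # final rank distance: p < r gives r + 1 - p ; p >= r gives p - r + 1
          dist_after <- ifelse(gaps < r, r - gaps, gaps - r + 1L)
          gap_ok <- gap_ok & dist_after >= config$dispersed_min_rank_distance
        }
        gaps <- gaps[gap_ok]
        if (length(gaps) == 0L) next
        p <- if (length(gaps) == 1L) gaps[[1]] else sample(gaps, 1L)
        cp <- new_copy_id()
        insert_after(dst, p, cp)
        used[s] <- TRUE
        true_mode[s] <- "dispersed"; true_mode[cp] <- "dispersed"
        family_of[cp] <- family_of[[s]]
        pairs[[length(pairs) + 1L]] <-
          data.frame(gene1 = s, gene2 = cp, mode = mode,
                     ancestral = NA_character_)
        event_log[[length(event_log) + 1L]] <-
          list(mode = mode, source = s, copies = cp, chrom = cn,
               dest_chrom = dst)
        placed <- TRUE
      }
      if (placed) {
        # count a fulfilled event against the family's quota, if any
        q <- quota[[mode]]
        if (!is.null(q)) {
          ev <- event_log[[length(event_log)]]
          f <- family_of[[strsplit(ev$source, ",")[[1]][1]]]
          if (!is.na(match(f, names(q))) && q[[f]] > 0L)
            quota[[mode]][f] <- q[[f]] - 1L
        }
        break
      }
    }
    if (!placed)
      stop_validation("could not place a ", mode,
                      " event after 500 attempts; capacity exceeded")
  }

  # lay out coordinates on a uniform grid
  rows <- do.call(rbind, lapply(chrom_names, function(cn) {
    v <- chroms[[cn]]
    if (length(v) == 0L) return(NULL)
    st <- (seq_along(v) - 1L) * config$gene_spacing_bp + 1L
    data.frame(gene_id = v, chromosome = cn, start = st,
               end = st + config$gene_size_bp - 1L, strand = "+",
               stringsAsFactors = FALSE)
  }))
  genome <- as_genome_table(rows)

  true_pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(gene1 = character(), gene2 = character(),
               mode = character(), ancestral = character())
  rownames(true_pairs) <- NULL

  truth <- list(
    true_mode = true_mode[genome$gene_id],
    true_pairs = true_pairs,
    planted_blocks = blocks,
    family_of = family_of[genome$gene_id],
    outgroup_anchored = outgroup_anchored,
    event_log = event_log,
    config = config)
  list(genome = genome, truth = truth)
}
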