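#' Generate homology hits for a synthetic genome
#'
#' Every planted duplicate pair yields a reciprocal hit pair with E-values
#' drawn well below the downstream cutoff (10^-50..10^-10); spurious hits
#' are drawn between random unrelated genes with E-values straddling the
#' cutoff (10^-8..10^-2), so roughly half survive filtering.
#'
#' @param truth ground truth from [generate_genome()].
#' @param noise spurious-hit rate relative to the number of true hits, in
#'   [0, 1).
#' @param seed optional seed override (defaults to the config substream).
#' @return data.frame with columns \code{query}, \code{subject},
#'   \code{e_value}.
#' @export
generate_hits <- function(truth, noise = 0, seed = NULL) {
  stopifnot(noise >= 0, noise < 1)
  if (is.null(seed)) seed <- substream_seed(truth$config$seed, "hits")
  with_seed(seed, {
    tp <- truth$true_pairs
    n_true <- nrow(tp)
    if (n_true > 0) {
      e1 <- 10^(-stats::runif(n_true, 10, 50))
      e2 <- 10^(-stats::runif(n_true, 10, 50))
      hits <- data.frame(
        query = c(tp$gene1, tp$gene2),
        subject = c(tp$gene2, tp$gene1),
        e_value = c(e1, e2), stringsAsFactors = FALSE)
    } else {
      hits <- data.frame(query = character(), subject = character(),
                         e_value = numeric())
    }
    n_spur <- round(noise * nrow(hits))
    if (n_spur > 0) {
      genes <- names(truth$true_mode)
      true_key <- c(paste(tp$gene1, tp$gene2), paste(tp$gene2, tp$gene1))
      got <- 0L
      spur <- vector("list", n_spur)
      while (got < n_spur) {
        g <- sample(genes, 2L)
        if (paste(g[1], g[2]) %in% true_key) next
        got <- got + 1L
        spur[[got]] <- data.frame(query = g[1], subject = g[2],
                                  e_value = 10^(-stats::runif(1, 2, 8)),
                                  stringsAsFactors = FALSE)
      }
      hits <- rbind(hits, do.call(rbind, spur))
    }
    rownames(hits) <- NULL
    hits
  })
}

#' Generate expression profiles whose pairwise correlation depends on
#' duplication mode
#'
#' Ancestral genes receive independent standard-normal profiles; each
#' duplicate's profile is \code{rho * source + sqrt(1 - rho^2) * noise}
#' with \code{rho = rho_by_mode[mode]}, so the population correlation of a
#' planted pair equals rho exactly.
#'
#' @param truth ground truth from [generate_genome()].
#' @param config the [synthetic_config()] used to generate it.
#' @param seed optional seed override.
#' @return numeric matrix, genes x samples.
#' @export
generate_expression <- function(truth, config = truth$config, seed = NULL) {
  stopifnot(config$expression_samples >= 3)
  if (is.null(seed)) seed <- substream_seed(config$seed, "expression")
  with_seed(seed, {
    genes <- names(truth$true_mode)
    n <- config$expression_samples
    copies <- truth$true_pairs$gene2
    # for transposed pairs gene1 is the copy and gene2 the ancestral locus
    is_tp <- truth$true_pairs$mode == "transposed"
    copies[is_tp] <- truth$true_pairs$gene1[is_tp]
    sources <- truth$true_pairs$gene1
    sources[is_tp] <- truth$true_pairs$gene2[is_tp]
    base_genes <- setdiff(genes, copies)
    m <- matrix(NA_real_, nrow = length(genes), ncol = n,
                dimnames = list(genes, sprintf("s%03d", seq_len(n))))
    m[base_genes, ] <- stats::rnorm(length(base_genes) * n)
    if (length(copies)) {
      rho <- config$rho_by_mode[truth$true_pairs$mode]
      for (k in seq_along(copies)) {
        r <- rho[k]
        m[copies[k], ] <- r * m[sources[k], ] +
          sqrt(1 - r^2) * stats::rnorm(n)
      }
    }
    m
  })
}

#' Build a family phylogeny that encodes planted event order
#'
#' The ancestral members of the family form a caterpillar backbone; each
#' planted event replaces its source tip with a cherry \code{(source,copy)},
#' so the pair's most recent common ancestor is exactly the node created by
#' the event.
#'
#' @param truth ground truth from [generate_genome()].
#' @param family family name.
#' @return an [ape::read.tree()] \code{phylo} object.
#' @export
generate_family_tree <- function(truth, family) {
  members <- names(truth$family_of)[truth$family_of == family]
  if (length(members) == 0L) stop_validation("empty family: ", family)
  newick_body <- family_newick(truth, family)
  ape::read.tree(text = paste0(newick_body, ";"))
}

family_newick <- function(truth, family) {
  members <- names(truth$family_of)[truth$family_of == family]
  tp <- truth$true_pairs
  copies <- tp$gene2
  is_tp <- tp$mode == "transposed"
  copies[is_tp] <- tp$gene1[is_tp]
  anc_members <- setdiff(members, copies)
  if (length(anc_members) == 0L) anc_members <- members[1]
  s <- anc_members[1]
  for (a in anc_members[-1]) s <- paste0("(", s, ",", a, ")")
  # graft each copy as a cherry on its source, in event order
  for (k in seq_len(nrow(tp))) {
    cp <- copies[k]
    src <- if (is_tp[k]) tp$gene2[k] else tp$gene1[k]
    if (!cp %in% members) next
    s <- sub_tip(s, src, paste0("(", src, ",", cp, ")"))
  }
  if (!grepl("^\\(", s)) s <- paste0("(", s, ")")
  s
}

# replace a tip token in a newick fragment, respecting delimiters
sub_tip <- function(newick, tip, replacement) {
  if (newick == tip) return(replacement)
  gsub(paste0("([(,])", tip, "([,)])"),
       paste0("\\1", replacement, "\\2"), newick)
}

#' Join several family trees under one root
#'
#' Produces a multi-family phylogeny in which every family is monophyletic;
#' used to exercise clade-based annotation and MRCA mapping.
#'
#' @param truth ground truth from [generate_genome()].
#' @param families character vector of family names (default: all families
#'   with at least 2 members).
#' @return a \code{phylo} object.
#' @export
generate_kinome_tree <- function(truth, families = NULL) {
  if (is.null(families)) {
    tab <- table(truth$family_of)
    families <- names(tab)[tab >= 2]
  }
  if (length(families) < 1L) stop_validation("no families to join")
  parts <- vapply(families, function(f) family_newick(truth, f), "")
  # bifurcating backbone over family subtrees
  s <- parts[1]
  for (p in parts[-1]) s <- paste0("(", s, ",", p, ")")
  if (length(parts) == 1L) s <- paste0("(", s, ")")
  ape::read.tree(text = paste0(s, ";"))
}

#' Generate phenotype class labels with an optional planted enrichment
#'
#' Classes are drawn independently per gene from the configured class
#' probabilities. For genes in \code{focal}, the probability of
#' \code{boost_class} is multiplied by \code{boost_odds} and the vector
#' renormalized, planting a known enrichment for power tests.
#'
#' @param truth ground truth from [generate_genome()].
#' @param config the [synthetic_config()].
#' @param focal optional character vector of focal ("kinase") genes.
#' @param boost_class class whose probability is boosted among focal genes.
#' @param boost_odds multiplicative boost (1 = no enrichment; the spec value
#'   \code{Inf}-like "boost 1.0" case is expressed as a probability-1
#'   assignment via \code{boost_odds = Inf}).
#' @param seed optional seed override.
#' @return named character vector gene -> class.
#' @export
generate_phenotypes <- function(truth, config = truth$config, focal = NULL,
                                boost_class = NULL, boost_odds = 1,
                                seed = NULL) {
  if (is.null(seed)) seed <- substream_seed(config$seed, "phenotype")
  with_seed(seed, {
    genes <- names(truth$true_mode)
    p <- config$phenotype_class_probs
    classes <- names(p)
    lab <- sample(classes, length(genes), replace = TRUE, prob = p)
    names(lab) <- genes
    if (!is.null(focal) && !is.null(boost_class) && boost_odds != 1) {
      if (!boost_class %in% classes)
        stop_validation("unknown phenotype class: ", boost_class)
      pf <- p
      if (is.infinite(boost_odds)) {
        pf[] <- 0; pf[boost_class] <- 1
      } else {
        pf[boost_class] <- pf[boost_class] * boost_odds
        pf <- pf / sum(pf)
      }
      focal <- intersect(focal, genes)
      lab[focal] <- sample(classes, length(focal), replace = TRUE, prob = pf)
    }
    lab
  })
}

#' Generate an interaction edge list with configurable degrees and hubs
#'
#' Each non-hub gene draws an out-degree from Poisson(lambda/2) and connects
#' to uniformly chosen partners, giving final degrees around lambda. Planted
#' hubs are wired first to exactly \code{hub_degree} distinct partners.
#'
#' @param truth ground truth from [generate_genome()].
#' @param config the [synthetic_config()].
#' @param hub_genes optional character vector of planted hub genes.
#' @param hub_degree degree assigned to each planted hub.
#' @param seed optional seed override.
#' @return data.frame with columns \code{gene1}, \code{gene2}
#'   (deduplicated, undirected, no self-loops).
#' @export
generate_interactions <- function(truth, config = truth$config,
                                  hub_genes = NULL, hub_degree = 25L,
                                  seed = NULL) {
  if (is.null(seed)) seed <- substream_seed(config$seed, "interaction")
  with_seed(seed, {
    genes <- names(truth$true_mode)
    edges <- list()
    others <- setdiff(genes, hub_genes)
    for (h in hub_genes) {
      partners <- sample(others, min(hub_degree, length(others)))
      edges[[length(edges) + 1L]] <-
        data.frame(gene1 = h, gene2 = partners, stringsAsFactors = FALSE)
    }
    lam <- config$degree_lambda / 2
    d <- stats::rpois(length(others), lam)
    for (i in seq_along(others)) {
      if (d[i] == 0L) next
      partners <- sample(setdiff(others, others[i]), d[i])
      edges[[length(edges) + 1L]] <-
        data.frame(gene1 = others[i], gene2 = partners,
                   stringsAsFactors = FALSE)
    }
    e <- do.call(rbind, edges)
    if (is.null(e)) return(data.frame(gene1 = character(),
                                      gene2 = character()))
    key <- ifelse(e$gene1 < e$gene2, paste(e$gene1, e$gene2),
                  paste(e$gene2, e$gene1))
    e <- e[!duplicated(key) & e$gene1 != e$gene2, , drop = FALSE]
    rownames(e) <- NULL
    e
  })
}
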