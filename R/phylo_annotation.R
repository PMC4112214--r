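#' Clade-based family annotation of unlabeled tips
#'
#' For each unlabeled tip, its sister clade is inspected: if the sister's
#' labeled tips are unanimous, that family is proposed with evidence
#' "sister-clade unanimity". Otherwise the smallest enclosing clade with at
#' least one labeled tip is found and its majority label (> 50% of labeled
#' tips) proposed with evidence "clade majority"; without a majority the
#' proposal is "ambiguous". Existing labels are never changed; a labeled
#' tip whose sister clade is unanimously a different family is reported as
#' a potential mis-annotation.
#'
#' @param tree a rooted \code{phylo} object.
#' @param known named character vector tip -> family for labeled tips.
#' @return list with \code{proposals} (data.frame gene_id, proposed_family,
#'   evidence, majority_fraction, support) and \code{conflicts} (data.frame
#'   gene_id, current_family, sister_family).
#' @export
annotate_by_clade <- function(tree, known) {
  tips <- tree$tip.label
  known <- known[names(known) %in% tips]
  if (length(known) == 0L) stop_validation("no labeled tips")
  ntip <- length(tips)
  unlabeled <- setdiff(tips, names(known))

  node_support <- function(node) {
    if (is.null(tree$node.label)) return(NA_real_)
    lab <- tree$node.label[node - ntip]
    suppressWarnings(as.numeric(lab))
  }
  labeled_under <- function(node) {
    if (node <= ntip) {
      tp <- tips[node]
      if (tp %in% names(known)) return(known[[tp]]) else return(character())
    }
    dt <- tips[unlist(phangorn_descendants(tree, node))]
    unname(known[intersect(dt, names(known))])
  }

  parent_of <- function(node) tree$edge[tree$edge[, 2] == node, 1]
  children_of <- function(node) tree$edge[tree$edge[, 1] == node, 2]

  propose <- function(tip_idx) {
    par <- parent_of(tip_idx)
    sibs <- setdiff(children_of(par), tip_idx)
    sister_labels <- unlist(lapply(sibs, labeled_under))
    if (length(sister_labels) > 0 &&
        length(unique(sister_labels)) == 1L) {
      # support of the deciding clade: the sister clade itself when it is
      # a single internal node, otherwise the joining parent
      sup <- if (length(sibs) == 1L && sibs > ntip)
        node_support(sibs) else node_support(par)
      return(list(family = unique(sister_labels),
                  evidence = "sister-clade unanimity",
                  fraction = 1, support = sup))
    }
    # ascend to the smallest enclosing clade with labeled tips
    node <- par
    repeat {
      labs <- labeled_under(node)
      if (length(labs) > 0) {
        tab <- sort(table(labs), decreasing = TRUE)
        frac <- tab[1] / sum(tab)
        if (frac > 0.5)
          return(list(family = names(tab)[1], evidence = "clade majority",
                      fraction = unname(frac),
                      support = node_support(node)))
        return(list(family = "ambiguous", evidence = "clade majority",
                    fraction = unname(frac), support = node_support(node)))
      }
      up <- parent_of(node)
      if (length(up) == 0L)
        return(list(family = "ambiguous", evidence = "clade majority",
                    fraction = 0, support = NA_real_))
      node <- up
    }
  }

  proposals <- do.call(rbind, lapply(unlabeled, function(tp) {
    p <- propose(match(tp, tips))
    data.frame(gene_id = tp, proposed_family = p$family,
               evidence = p$evidence, majority_fraction = p$fraction,
               support = p$support, stringsAsFactors = FALSE)
  }))
  if (is.null(proposals))
    proposals <- data.frame(gene_id = character(),
                            proposed_family = character(),
                            evidence = character(),
                            majority_fraction = numeric(),
                            support = numeric())

  conflicts <- do.call(rbind, lapply(names(known), function(tp) {
    par <- parent_of(match(tp, tips))
    sibs <- setdiff(children_of(par), match(tp, tips))
    sl <- unlist(lapply(sibs, labeled_under))
    if (length(sl) > 0 && length(unique(sl)) == 1L &&
        unique(sl) != known[[tp]])
      data.frame(gene_id = tp, current_family = known[[tp]],
                 sister_family = unique(sl), stringsAsFactors = FALSE)
    else NULL
  }))
  if (is.null(conflicts))
    conflicts <- data.frame(gene_id = character(),
                            current_family = character(),
                            sister_family = character())
  list(proposals = proposals, conflicts = conflicts)
}

# tip indices (as list) descending from an internal node
phangorn_descendants <- function(tree, node) {
  ntip <- length(tree$tip.label)
  out <- integer()
  stack <- node
  while (length(stack)) {
    nd <- stack[[1]]; stack <- stack[-1]
    if (nd <= ntip) out <- c(out, nd)
    else stack <- c(stack, tree$edge[tree$edge[, 1] == nd, 2])
  }
  list(out)
}

#' Map duplicate pairs to their most recent common ancestor
#'
#' Each typed duplicate pair is assigned to the MRCA node of its two tips;
#' several pairs may share a node.
#'
#' @param tree a \code{phylo} object.
#' @param pairs data.frame with columns gene1, gene2, mode.
#' @return data.frame with gene1, gene2, mode, node (internal node id; for
#'   ape, tips are 1..Ntip and the root is Ntip + 1).
#' @export
map_duplications_to_tree <- function(tree, pairs) {
  tips <- tree$tip.label
  missing <- setdiff(unique(c(pairs$gene1, pairs$gene2)), tips)
  if (length(missing))
    stop_validation("pair members absent from tree: ",
                    paste(missing, collapse = ", "))
  node <- vapply(seq_len(nrow(pairs)), function(i)
    ape::getMRCA(tree, c(pairs$gene1[i], pairs$gene2[i])), 0L)
  cbind(pairs, node = node)
}
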