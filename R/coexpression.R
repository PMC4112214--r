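#' Pairwise Pearson correlation of expression profiles
#'
#' Correlation is computed across all samples pooled. Genes with zero
#' expression variance yield undefined (NA) entries, flagged in the result
#' and excluded downstream.
#'
#' @param expr genes x samples numeric matrix.
#' @param genes optional subset of gene ids (default: all rows).
#' @return list with \code{correlations} (symmetric matrix, diagonal 1
#'   where defined) and \code{undefined} (character vector of zero-variance
#'   genes).
#' @export
pairwise_correlation <- function(expr, genes = rownames(expr)) {
  if (ncol(expr) < 3L) stop_validation("need at least 3 samples")
  missing <- setdiff(genes, rownames(expr))
  if (length(missing))
    stop_validation("genes absent from expression matrix: ",
                    paste(utils::head(missing, 5), collapse = ", "))
  m <- expr[genes, , drop = FALSE]
  v <- apply(m, 1, stats::sd)
  undefined <- rownames(m)[v == 0 | is.na(v)]
  r <- suppressWarnings(stats::cor(t(m)))
  r[undefined, ] <- NA_real_
  r[, undefined] <- NA_real_
  diag(r)[!rownames(r) %in% undefined] <- 1
  list(correlations = r, undefined = undefined)
}

#' Dual gene orderings: coexpression clustering vs phylogeny
#'
#' The clustering order comes from average-linkage agglomerative clustering
#' on distance 1 - r (genes sorted lexicographically beforehand so ties in
#' merge order resolve deterministically); the phylogeny order is the
#' left-to-right tip order of the tree.
#'
#' @param correlations symmetric correlation matrix (NA entries treated as
#'   r = 0 for the clustering distance).
#' @param tree a \code{phylo} object whose tips are a subset of the
#'   correlation gene set.
#' @return list with \code{clustering_order} and \code{phylogeny_order}
#'   (character vectors; the clustering order covers the tree's tip set).
#' @export
order_genes <- function(correlations, tree) {
  tips <- tree$tip.label
  missing <- setdiff(tips, rownames(correlations))
  if (length(missing))
    stop_validation("tree tips absent from correlations: ",
                    paste(utils::head(missing, 5), collapse = ", "))
  g <- sort(tips)
  r <- correlations[g, g, drop = FALSE]
  r[is.na(r)] <- 0
  d <- stats::as.dist(1 - r)
  hc <- stats::hclust(d, method = "average")
  clustering_order <- g[hc$order]
  tr <- ape::reorder.phylo(tree, "cladewise")
  tip_idx <- tr$edge[tr$edge[, 2] <= length(tips), 2]
  phylogeny_order <- tr$tip.label[tip_idx]
  list(clustering_order = clustering_order,
       phylogeny_order = phylogeny_order)
}

#' Correlation distributions stratified by duplication mode
#'
#' Collects the correlation of every typed duplicate pair per mode and adds
#' a random-pair baseline of \code{n_random} uniformly sampled unordered
#' gene pairs that are not duplicate pairs. Histograms use fixed bins of
#' width 0.1 on [-1, 1].
#'
#' @param correlations symmetric correlation matrix.
#' @param pairs data.frame with columns gene1, gene2, mode.
#' @param n_random size of the random baseline.
#' @param seed seed for the random baseline.
#' @return list with \code{values} (named list mode -> numeric r vector,
#'   including \code{random}), \code{summary} (data.frame mode, n, mean,
#'   median) and \code{histogram} (data.frame mode, bin_low, bin_high,
#'   count).
#' @export
correlation_by_mode <- function(correlations, pairs, n_random = 1000L,
                                seed = 1L) {
  genes <- rownames(correlations)
  missing <- setdiff(unique(c(pairs$gene1, pairs$gene2)), genes)
  if (length(missing))
    stop_validation("pair genes absent from correlations: ",
                    paste(utils::head(missing, 5), collapse = ", "))
  modes <- c("wgd_segmental", "tandem", "proximal", "transposed",
             "dispersed")
  values <- lapply(modes, function(m) {
    p <- pairs[pairs$mode == m, , drop = FALSE]
    if (nrow(p) == 0L) return(numeric())
    r <- correlations[cbind(p$gene1, p$gene2)]
    r[!is.na(r)]
  })
  names(values) <- modes
  values$random <- with_seed(substream_seed(seed, "random_pairs"), {
    out <- numeric(0)
    if (n_random > 0L && length(genes) >= 2L) {
      pair_key <- c(paste(pairs$gene1, pairs$gene2),
                    paste(pairs$gene2, pairs$gene1))
      got <- 0L
      out <- numeric(n_random)
      while (got < n_random) {
        g <- sample(genes, 2L)
        if (paste(g[1], g[2]) %in% pair_key) next
        r <- correlations[g[1], g[2]]
        if (is.na(r)) next
        got <- got + 1L
        out[got] <- r
      }
    }
    out
  })
  summary <- do.call(rbind, lapply(names(values), function(m) {
    v <- values[[m]]
    data.frame(mode = m, n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               median = if (length(v)) stats::median(v) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  breaks <- seq(-1, 1, by = 0.1)
  histogram <- do.call(rbind, lapply(names(values), function(m) {
    v <- values[[m]]
    h <- if (length(v))
      as.integer(table(cut(pmin(pmax(v, -1), 1), breaks = breaks,
                           include.lowest = TRUE)))
    else rep(0L, length(breaks) - 1L)
    data.frame(mode = m, bin_low = breaks[-length(breaks)],
               bin_high = breaks[-1], count = h, stringsAsFactors = FALSE)
  }))
  list(values = values, summary = summary, histogram = histogram)
}
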