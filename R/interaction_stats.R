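#' Degree statistics and hub identification on an interaction network
#'
#' Degrees count all distinct neighbors (focal or not) of each focal gene
#' after removing self-loops and collapsing duplicate edges. Hubs are focal
#' genes with degree at or above the threshold. Per-mode mean degrees use
#' the supplied duplication labeling.
#'
#' @param edges data.frame with two gene-id columns (undirected edge list).
#' @param focal character vector of focal genes (genes absent from the edge
#'   list get degree 0).
#' @param labeling optional \code{duplication_labeling} for per-mode means.
#' @param hub_threshold minimum degree for hub status (default 20, i.e.
#'   20 or more interaction partners).
#' @return list with \code{degree_of} (named integer over focal genes),
#'   \code{mean_degree}, \code{hubs} and \code{mean_degree_by_mode}.
#' @export
degree_stats <- function(edges, focal, labeling = NULL,
                         hub_threshold = 20L) {
  stopifnot(length(focal) > 0)
  e <- data.frame(gene1 = as.character(edges[[1]]),
                  gene2 = as.character(edges[[2]]),
                  stringsAsFactors = FALSE)
  e <- e[e$gene1 != e$gene2, , drop = FALSE]
  key <- ifelse(e$gene1 < e$gene2, paste(e$gene1, e$gene2),
                paste(e$gene2, e$gene1))
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sum(dup), " duplicate edge entries collapsed", call. = FALSE)
    e <- e[!dup, , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(e, directed = FALSE,
                                     vertices = unique(c(e$gene1, e$gene2,
                                                         focal)))
  deg <- igraph::degree(g)
  degree_of <- stats::setNames(as.integer(deg[focal]), focal)
  out <- list(degree_of = degree_of,
              mean_degree = mean(degree_of),
              hubs = names(degree_of)[degree_of >= hub_threshold])
  if (!is.null(labeling)) {
    md <- labeling$mode_of[focal]
    out$mean_degree_by_mode <- tapply(degree_of, md, mean)
  }
  out
}
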