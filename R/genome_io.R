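#' Read a gene position table
#'
#' Builds the gene-order backbone used by the duplication classifier: one row
#' per gene with chromosome, 1-based inclusive coordinates, strand and a
#' 0-based rank within its chromosome's gene order. Ranks are assigned by
#' start coordinate, ties broken by end then gene id, so the order is total
#' and reproducible.
#'
#' @param path path to a GFF3 file (rows of type \code{gene}, id taken from
#'   the \code{ID} attribute) or a 5-column TSV \code{id, chrom, start, end,
#'   strand} with no header.
#' @param format either \code{"gff3"} or \code{"tsv"}.
#' @return a \code{genome_table}: data.frame with columns \code{gene_id},
#'   \code{chromosome}, \code{start}, \code{end}, \code{strand}, \code{rank}.
#' @export
read_gene_table <- function(path, format = c("tsv", "gff3")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_validation("file not found: ", path)
  if (format == "tsv") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop_validation("no gene records in ", path)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(fields) < 5L)
    if (length(bad))
      stop_validation("malformed gene table row at line ", bad[1],
                      " (expected 5 tab-separated fields)")
    df <- data.frame(
      gene_id    = vapply(fields, `[[`, "", 1L),
      chromosome = vapply(fields, `[[`, "", 2L),
      start      = suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L))),
      end        = suppressWarnings(as.integer(vapply(fields, `[[`, "", 4L))),
      strand     = vapply(fields, `[[`, "", 5L),
      stringsAsFactors = FALSE)
    if (anyNA(df$start) || anyNA(df$end)) {
      bad <- which(is.na(df$start) | is.na(df$end))[1]
      stop_validation("malformed coordinates at line ", bad)
    }
  } else {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop_validation("reading GFF3 requires the rtracklayer package")
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[as.character(gr$type) == "gene"]
    if (length(gr) == 0L) stop_validation("no gene records in ", path)
    df <- data.frame(
      gene_id    = as.character(gr$ID),
      chromosome = as.character(GenomicRanges::seqnames(gr)),
      start      = GenomicRanges::start(gr),
      end        = GenomicRanges::end(gr),
      strand     = as.character(GenomicRanges::strand(gr)),
      stringsAsFactors = FALSE)
    df$strand[df$strand == "*"] <- "unknown"
  }
  as_genome_table(df)
}

#' Construct a genome table from a data frame
#'
#' Validates coordinates and uniqueness, sorts by (chromosome, start, end,
#' gene_id) and assigns 0-based per-chromosome ranks.
#'
#' @param df data.frame with columns gene_id, chromosome, start, end, strand.
#' @return a \code{genome_table} data.frame.
#' @export
as_genome_table <- function(df) {
  stopifnot(all(c("gene_id", "chromosome", "start", "end", "strand") %in%
                  names(df)))
  if (nrow(df) == 0L) stop_validation("no gene records")
  if (anyDuplicated(df$gene_id))
    stop_validation("duplicate gene_id: ",
                    df$gene_id[duplicated(df$gene_id)][1])
  if (any(df$start < 1L) || any(df$end < df$start))
    stop_validation("invalid coordinates (need 1 <= start <= end)")
  ok <- df$strand %in% c("+", "-", "unknown")
  df$strand[!ok] <- "unknown"
  o <- order(df$chromosome, df$start, df$end, df$gene_id)
  df <- df[o, c("gene_id", "chromosome", "start", "end", "strand"),
           drop = FALSE]
  df$rank <- stats::ave(seq_len(nrow(df)), df$chromosome,
                        FUN = function(i) seq_along(i) - 1L)
  rownames(df) <- NULL
  class(df) <- c("genome_table", "data.frame")
  df
}

#' Write a genome table as TSV
#' @param genome a genome_table.
#' @param path output path.
#' @export
write_gene_table <- function(genome, path) {
  utils::write.table(
    genome[, c("gene_id", "chromosome", "start", "end", "strand")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an MCScanX-style collinearity file
#'
#' Parses the \code{.collinearity} dialect: comment lines starting with
#' \code{#}, block headers of the form
#' \code{## Alignment k: score=... e_value=... N=... chrA&chrB orientation}
#' and anchor lines \code{k-i: geneA geneB e-value}. One block is produced
#' per header; if the anchor count disagrees with the header's \code{N} a
#' warning is emitted but parsing continues.
#'
#' @param path path to the collinearity file.
#' @return list of blocks, each a list with \code{block_id},
#'   \code{anchor_pairs} (2-column character matrix), \code{chrom_pair},
#'   \code{score}, \code{e_value}.
#' @export
read_collinearity <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: ", path)
  lines <- readLines(path)
  blocks <- list()
  cur <- NULL
  flush <- function(cur) {
    if (is.null(cur)) return(NULL)
    if (!is.na(cur$n_declared) && nrow(cur$anchor_pairs) != cur$n_declared)
      warning(sprintf("block %s: header N=%d but %d anchor lines",
                      cur$block_id, cur$n_declared, nrow(cur$anchor_pairs)),
              call. = FALSE)
    cur$n_declared <- NULL
    cur
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^##\\s*Alignment", ln)) {
      b <- flush(cur)
      if (!is.null(b)) blocks[[length(blocks) + 1L]] <- b
      id <- sub("^##\\s*Alignment\\s+([^:]+):.*$", "\\1", ln)
      score <- if (grepl("score=", ln))
        as.numeric(sub(".*score=([0-9eE.+-]+).*", "\\1", ln)) else NA_real_
      ev <- if (grepl("e_value=", ln))
        as.numeric(sub(".*e_value=([0-9eE.+-]+).*", "\\1", ln)) else NA_real_
      n <- if (grepl("N=", ln))
        as.integer(sub(".*N=([0-9]+).*", "\\1", ln)) else NA_integer_
      chrom_pair <- c(NA_character_, NA_character_)
      m <- regmatches(ln, regexpr("[^ ]+&[^ ]+", ln))
      if (length(m)) chrom_pair <- strsplit(m, "&", fixed = TRUE)[[1]][1:2]
      cur <- list(block_id = id,
                  anchor_pairs = matrix(character(), 0, 2),
                  chrom_pair = chrom_pair, score = score, e_value = ev,
                  n_declared = n)
    } else if (grepl("^#", ln) || !nzchar(trimws(ln))) {
      next
    } else {
      if (is.null(cur))
        stop_validation("anchor line before any block header at line ", i)
      # strip the "k-i:" anchor prefix (MCScanX pads it with spaces)
      body <- sub("^\\s*\\S+-\\s*[0-9]+:\\s*", "", ln)
      f <- strsplit(trimws(body), "[ \t]+")[[1]]
      f <- f[f != ""]
      if (length(f) < 2L)
        stop_validation("malformed anchor line at line ", i,
                        " (need two gene ids)")
      cur$anchor_pairs <- rbind(cur$anchor_pairs, f[1:2])
    }
  }
  b <- flush(cur)
  if (!is.null(b)) blocks[[length(blocks) + 1L]] <- b
  blocks
}

#' Write collinear blocks in the MCScanX dialect
#' @param blocks list of blocks as returned by [read_collinearity()].
#' @param path output path.
#' @export
write_collinearity <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("############### Collinear blocks ###############", con)
  for (b in blocks) {
    writeLines(sprintf("## Alignment %s: score=%s e_value=%s N=%d %s&%s plus",
                       b$block_id,
                       ifelse(is.na(b$score), "0", format(b$score)),
                       ifelse(is.na(b$e_value), "0", format(b$e_value)),
                       nrow(b$anchor_pairs),
                       b$chrom_pair[1], b$chrom_pair[2]), con)
    for (i in seq_len(nrow(b$anchor_pairs)))
      writeLines(sprintf("%s-%d:\t%s\t%s\t0", b$block_id, i - 1L,
                         b$anchor_pairs[i, 1], b$anchor_pairs[i, 2]), con)
  }
  invisible(path)
}

#' Filter homology hits by E-value and per-query rank
#'
#' Removes self-hits, keeps hits with \code{e_value <= max_e}, sorts each
#' query's hits ascending by E-value (ties broken by subject id so output is
#' deterministic) and truncates to the best \code{top_k}.
#'
#' @param hits data.frame with columns \code{query}, \code{subject},
#'   \code{e_value}.
#' @param max_e E-value cutoff (default 1e-5).
#' @param top_k maximum retained hits per query (default 5).
#' @return filtered hits data.frame.
#' @export
filter_hits <- function(hits, max_e = 1e-5, top_k = 5L) {
  stopifnot(max_e > 0, top_k >= 1)
  stopifnot(all(c("query", "subject", "e_value") %in% names(hits)))
  hits <- hits[hits$query != hits$subject & hits$e_value <= max_e, ,
               drop = FALSE]
  if (nrow(hits) == 0L) return(hits)
  o <- order(hits$query, hits$e_value, hits$subject)
  hits <- hits[o, , drop = FALSE]
  keep <- stats::ave(seq_len(nrow(hits)), hits$query,
                     FUN = seq_along) <= top_k
  hits <- hits[keep, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Read a profile alignment with a match-column mask
#'
#' The alignment is FASTA (gap character \code{-}); the sidecar mask file
#' holds one line of 0/1 characters, one per alignment column, with 1 marking
#' columns that belong to the profile HMM.
#'
#' @param fasta_path aligned FASTA path.
#' @param mask_path sidecar mask path.
#' @return list with \code{sequences} (named character vector) and
#'   \code{match_mask} (logical vector).
#' @export
read_profile_alignment <- function(fasta_path, mask_path) {
  lines <- readLines(fasta_path)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop_validation("no FASTA records in ", fasta_path)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  ends <- c(hdr[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i) {
    paste(lines[seq(hdr[i] + 1L, ends[i])], collapse = "")
  }, "")
  names(seqs) <- ids
  mask_line <- trimws(readLines(mask_path, n = 1L))
  mask <- strsplit(mask_line, "")[[1]] == "1"
  if (length(unique(nchar(seqs))) != 1L)
    stop_validation("aligned sequences have unequal lengths")
  if (nchar(seqs[1]) != length(mask))
    stop_validation("mask length does not match alignment width")
  list(sequences = seqs, match_mask = mask)
}

#' Coverage filter over profile-match columns
#'
#' Coverage of a sequence is the fraction of match columns in which it has a
#' non-gap residue. Sequences with coverage strictly below \code{threshold}
#' are removed; a sequence exactly at the threshold is retained.
#'
#' @param aln profile alignment as from [read_profile_alignment()].
#' @param threshold coverage fraction in (0, 1].
#' @return list with \code{retained} (filtered alignment) and \code{report}
#'   (named numeric vector of per-sequence coverages over all inputs).
#' @export
filter_alignment_coverage <- function(aln, threshold = 0.70) {
  stopifnot(threshold > 0 || threshold == 0, threshold <= 1)
  mask <- aln$match_mask
  if (!any(mask)) stop_validation("alignment has zero match columns")
  cov <- vapply(aln$sequences, function(s) {
    res <- strsplit(s, "")[[1]][mask]
    sum(res != "-") / sum(mask)
  }, 0)
  keep <- cov >= threshold
  list(retained = list(sequences = aln$sequences[keep],
                       match_mask = mask),
       report = cov)
}

#' Read a rooted phylogeny from newick
#' @param path newick file path.
#' @return an [ape::read.tree()] \code{phylo} object; unrooted trees are
#'   midpoint-rooted with a warning.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop_validation("could not parse newick in ", path)
  if (anyDuplicated(tr$tip.label))
    stop_validation("duplicate tip names in tree")
  if (!ape::is.rooted(tr)) {
    warning("input tree is unrooted; midpoint-rooting", call. = FALSE)
    tr <- phangorn_midpoint(tr)
  }
  tr
}

# midpoint rooting without importing phangorn wholesale
phangorn_midpoint <- function(tr) {
  if (requireNamespace("phangorn", quietly = TRUE))
    return(phangorn::midpoint(tr))
  ape::root(tr, outgroup = tr$tip.label[1], resolve.root = TRUE)
}

#' Read an expression matrix (genes x samples TSV with header)
#' @param path TSV path; first column gene ids, remaining columns samples.
#' @return numeric matrix with gene rownames.
#' @export
read_expression <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(df[[1]])) stop_validation("duplicate gene ids in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  if (ncol(m) > 0 && any(apply(m, 2, function(x) all(is.na(x)))))
    stop_validation("expression matrix has an entirely missing column")
  m
}

#' Write an expression matrix as TSV
#' @param m numeric matrix with gene rownames.
#' @param path output path.
#' @export
write_expression <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column gene -> label TSV
#' @param path TSV path, no header: gene_id, label.
#' @return named character vector keyed by gene id.
#' @export
read_label_table <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop_validation("label table needs 2 columns")
  dup <- duplicated(df[[1]])
  if (any(dup)) {
    # duplicates allowed only if the labels agree
    agg <- tapply(df[[2]], df[[1]], function(x) length(unique(x)))
    if (any(agg > 1))
      stop_validation("conflicting labels for gene: ",
                      names(agg)[agg > 1][1])
    df <- df[!dup, , drop = FALSE]
  }
  stats::setNames(as.character(df[[2]]), df[[1]])
}
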