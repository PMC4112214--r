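#' Family-by-mode enrichment with Fisher's exact test and Pearson residuals
#'
#' For every (family, mode) cell of the count matrix a 2x2 table is formed
#' against the aggregate of all other families in the matrix, and tested
#' with a two-sided Fisher's exact test (point-probability method). All
#' p-values are jointly Benjamini-Hochberg adjusted. The Pearson residual
#' (O - E)/sqrt(E) with E = row_total * col_total / grand_total gives the
#' direction and strength of the deviation.
#'
#' @param observed integer matrix, rows = families, columns = modes.
#' @return data.frame with columns family, mode, observed, expected,
#'   p_value, p_adjusted, pearson_residual, direction, degenerate.
#' @export
fisher_enrichment <- function(observed) {
  observed <- as.matrix(observed)
  if (nrow(observed) < 2L || ncol(observed) < 2L)
    stop_validation("need at least 2 families and 2 modes")
  if (any(observed < 0) || any(observed != round(observed)))
    stop_validation("counts must be non-negative integers")
  grand <- sum(observed)
  row_tot <- rowSums(observed)
  col_tot <- colSums(observed)
  res <- expand.grid(family = rownames(observed), mode = colnames(observed),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(res)
  res$observed <- NA_integer_; res$expected <- NA_real_
  res$p_value <- NA_real_; res$pearson_residual <- NA_real_
  res$degenerate <- FALSE
  for (i in seq_len(n)) {
    f <- res$family[i]; m <- res$mode[i]
    o <- observed[f, m]
    rf <- row_tot[f]; cm <- col_tot[m]
    res$observed[i] <- o
    if (rf == 0 || cm == 0 || grand == 0) {
      res$p_value[i] <- 1
      res$expected[i] <- 0
      res$pearson_residual[i] <- 0
      res$degenerate[i] <- TRUE
      next
    }
    e <- rf * cm / grand
    res$expected[i] <- e
    res$pearson_residual[i] <- (o - e) / sqrt(e)
    tab <- matrix(c(o, rf - o, cm - o, grand - rf - cm + o), 2, 2)
    res$p_value[i] <- stats::fisher.test(tab)$p.value
  }
  res$p_adjusted <- benjamini_hochberg(res$p_value)
  res$direction <- ifelse(res$pearson_residual > 0, "enriched", "depleted")
  res$direction[res$pearson_residual == 0] <- "depleted"
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validated wrapper over the standard step-up FDR adjustment: the adjusted
#' value of the i-th smallest p is min over j >= i of p_(j) * m / j,
#' clipped at 1.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return adjusted p-values in input order.
#' @export
benjamini_hochberg <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop_validation("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Phenotype-class enrichment of a focal gene set
#'
#' Per phenotype class, a two-sided Fisher's exact test on focal vs
#' background genes being in vs out of the class, BH-adjusted across
#' classes.
#'
#' @param phenotype_of named character vector gene -> class.
#' @param focal character vector of focal genes.
#' @return data.frame with class, focal_in, focal_out, bg_in, bg_out,
#'   odds_ratio, p_value, p_adjusted, direction.
#' @export
phenotype_enrichment <- function(phenotype_of, focal) {
  focal <- intersect(focal, names(phenotype_of))
  if (length(focal) == 0L) stop_validation("empty focal set")
  genes <- names(phenotype_of)
  bg <- setdiff(genes, focal)
  classes <- sort(unique(phenotype_of))
  rows <- lapply(classes, function(cl) {
    fi <- sum(phenotype_of[focal] == cl)
    fo <- length(focal) - fi
    bi <- sum(phenotype_of[bg] == cl)
    bo <- length(bg) - bi
    tab <- matrix(c(fi, fo, bi, bo), 2, 2)
    ft <- stats::fisher.test(tab)
    data.frame(class = cl, focal_in = fi, focal_out = fo,
               bg_in = bi, bg_out = bo,
               odds_ratio = unname(ft$estimate), p_value = ft$p.value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adjusted <- benjamini_hochberg(res$p_value)
  exp_in <- (res$focal_in + res$bg_in) * length(focal) / length(genes)
  res$direction <- ifelse(res$focal_in > exp_in, "enriched", "depleted")
  res
}
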