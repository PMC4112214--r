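#' Monte Carlo null expectation for tandem duplicate counts
#'
#' For each family size N on the grid, N gene start positions (genes of
#' \code{gene_size} kb) are placed uniformly on a genome of
#' \code{genome_length} kb and the number of unordered pairs whose starts
#' lie within \code{window} kb is counted; the mean over replicates is the
#' expected tandem count for that family size. Genes may overlap (no
#' exclusion volume).
#'
#' @param genome_length genome size in kb (default 100000).
#' @param gene_size gene size in kb (default 1).
#' @param window pairing window in kb (default 50).
#' @param family_sizes grid of family sizes N (default 10..300 step 10).
#' @param replicates Monte Carlo replicates per N (default 1000).
#' @param seed integer seed.
#' @return data.frame with columns \code{N}, \code{mean} (expected pair
#'   count), \code{se} (standard error of the mean).
#' @export
simulate_expected_tandem <- function(genome_length = 100000,
                                     gene_size = 1,
                                     window = 50,
                                     family_sizes = seq(10L, 300L, 10L),
                                     replicates = 1000L,
                                     seed = 1L) {
  stopifnot(window < genome_length, replicates >= 1)
  L <- genome_length - gene_size
  with_seed(substream_seed(seed, "null_model"), {
    res <- lapply(family_sizes, function(N) {
      if (N < 2L) return(data.frame(N = N, mean = 0, se = 0))
      counts <- vapply(seq_len(replicates), function(i) {
        s <- sort(stats::runif(N, 0, L))
        # for sorted starts, pairs within the window counted by sweep
        sum(findInterval(s + window, s) - seq_len(N))
      }, 0)
      data.frame(N = N, mean = mean(counts),
                 se = stats::sd(counts) / sqrt(replicates))
    })
    do.call(rbind, res)
  })
}

#' Closed-form expected tandem pair count
#'
#' Independent analytic counterpart of [simulate_expected_tandem()]:
#' for two starts uniform on [0, L'] with L' = genome_length - gene_size,
#' P(|s1 - s2| <= w) = 2w/L' - (w/L')^2, so the expected pair count is
#' C(N,2) times that probability.
#'
#' @param N family size.
#' @param genome_length,gene_size,window as in [simulate_expected_tandem()].
#' @return expected number of within-window pairs (0 for N < 2).
#' @export
analytic_expected_tandem <- function(N, genome_length = 100000,
                                     gene_size = 1, window = 50) {
  stopifnot(all(N >= 0))
  L <- genome_length - gene_size
  p <- 2 * window / L - (window / L)^2
  ifelse(N < 2, 0, choose(N, 2) * p)
}

#' Expected segmental duplicate count for a family
#'
#' About 75% of the genome lies in at least one segmentally duplicated
#' block, so under unbiased retention a family of N genes is expected to
#' contain 0.75 * N segmental duplicates.
#'
#' @param N family size.
#' @param fraction genome fraction in duplicated blocks (default 0.75).
#' @return expected segmental gene count.
#' @export
expected_segmental <- function(N, fraction = 0.75) {
  stopifnot(all(N >= 0))
  fraction * N
}

#' Interpolating tandem-expectation function from a simulated grid
#'
#' Returns a function N -> expected count that interpolates linearly on the
#' simulated grid (and extrapolates via the analytic form below the
#' smallest grid point, where the grid gives no information).
#'
#' @param grid data.frame from [simulate_expected_tandem()].
#' @return function of N.
#' @export
make_tandem_expectation <- function(grid) {
  stopifnot(all(c("N", "mean") %in% names(grid)))
  f <- stats::approxfun(grid$N, grid$mean, rule = 2)
  function(N) {
    out <- f(N)
    small <- N < min(grid$N)
    if (any(small))
      out[small] <- analytic_expected_tandem(N[small]) *
        (f(min(grid$N)) / analytic_expected_tandem(min(grid$N)))
    out
  }
}

#' Classify families by observed/expected ratio bands
#'
#' Per family and axis (tandem, segmental), ratio = observed / expected.
#' The median and sample standard deviation are computed across families,
#' and each family is assigned to one of five bands per axis: below -2SD,
#' -2SD..-1SD, box (within one SD of the median), +1SD..+2SD, above +2SD.
#' Band intervals are half-open away from the box: a ratio exactly at
#' median + 1SD belongs to +1SD..+2SD, and symmetrically below.
#'
#' Observed tandem counts are supplied in gene units (as tabulated) while
#' the null simulation counts pairs; both ratios are computed and the
#' pair-unit ratio (observed gene pairs approximated as observed/2 when
#' \code{units = "pairs"}) or the raw gene-count ratio
#' (\code{units = "genes"}, the default for display) is used for banding.
#'
#' @param family_counts data.frame as produced by [tabulate_summary()]
#'   (\code{$family_counts}): columns family, N, per-mode counts,
#'   expected_tandem, expected_segmental.
#' @param units "pairs" (observed tandem genes / 2 against the pair-based
#'   expectation; default) or "genes".
#' @return list with \code{table} (family, tandem_ratio, segmental_ratio,
#'   tandem_band, segmental_band), \code{median} and \code{sd} per axis.
#'   Families with a zero expectation are excluded with a warning.
#' @export
classify_ratios <- function(family_counts, units = c("pairs", "genes")) {
  units <- match.arg(units)
  fc <- family_counts
  if (nrow(fc) < 2L) stop_validation("need at least 2 families")
  obs_t <- fc$tandem
  if (units == "pairs") obs_t <- obs_t / 2
  obs_s <- fc$wgd_segmental
  ok <- fc$expected_tandem > 0 & fc$expected_segmental > 0
  if (!any(ok)) stop_validation("all expectations are zero")
  if (any(!ok))
    warning(sum(!ok), " families excluded (zero expectation)",
            call. = FALSE)
  fc <- fc[ok, , drop = FALSE]
  tr <- obs_t[ok] / fc$expected_tandem
  sr <- obs_s[ok] / fc$expected_segmental

  band_of <- function(x, med, s) {
    if (is.na(s) || s == 0) return(rep("box", length(x)))
    ifelse(x >= med + 2 * s, "above+2SD",
    ifelse(x >= med + 1 * s, "+1SD..+2SD",
    ifelse(x > med - 1 * s, "box",
    ifelse(x > med - 2 * s, "-2SD..-1SD", "below-2SD"))))
  }
  med_t <- stats::median(tr); sd_t <- stats::sd(tr)
  med_s <- stats::median(sr); sd_s <- stats::sd(sr)
  list(table = data.frame(family = fc$family,
                          tandem_ratio = tr,
                          segmental_ratio = sr,
                          tandem_band = band_of(tr, med_t, sd_t),
                          segmental_band = band_of(sr, med_s, sd_s),
                          stringsAsFactors = FALSE),
       median = c(tandem = med_t, segmental = med_s),
       sd = c(tandem = sd_t, segmental = sd_s))
}
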