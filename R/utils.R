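#' Round half away from zero
#'
#' Standard arithmetic rounding (0.5 always moves away from zero), as used in
#' the summary tables. Base R's `round()` rounds half to even, which differs
#' at exact midpoints.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# Derive a deterministic child seed for a named substream so that the
# generators stay independent under one global seed. Kept below 2^31.
substream_seed <- function(seed, stream) {
  offsets <- c(genome = 11L, hits = 23L, expression = 37L, tree = 53L,
               phenotype = 71L, interaction = 89L, random_pairs = 101L,
               null_model = 113L)
  if (!stream %in% names(offsets)) stop("unknown substream: ", stream)
  (as.integer(seed) %% 1000000L) * 1009L + offsets[[stream]]
}

stop_validation <- function(...) {
  stop(paste0(...), call. = FALSE)
}

# run expr with a local RNG state seeded by `seed` (NULL = use current state)
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}
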