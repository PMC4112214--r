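# Small genome configurations used across the unit tests.

small_config <- function(seed = 1, ...) {
  args <- list(
    n_chromosomes = 3L,
    n_ancestral_genes = 150L,
    event_counts = c(wgd_segmental = 2L, tandem = 3L, proximal = 3L,
                     transposed = 2L, dispersed = 2L),
    block_length = 3L,
    family_size = 10L,
    expression_samples = 50L,
    seed = seed)
  args[names(list(...))] <- list(...)
  do.call(synthetic_config, args)
}

# the 50-events-per-mode, 3000-gene condition used for recovery checks
recovery_config <- function(seed) {
  synthetic_config(
    n_ancestral_genes = 2550L,
    event_counts = c(wgd_segmental = 50L, tandem = 50L, proximal = 50L,
                     transposed = 50L, dispersed = 50L),
    seed = seed)
}

write_tsv_lines <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}
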