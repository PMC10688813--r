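# Tiny in-code fixtures shared across test files.

# Two species with known, disjoint k-mer sets at k = 4:
# A -> {ACGT, CGTA, GTAC, TACG}, B -> {CCCC}.
tiny_records <- function() {
  data.frame(record_id = c("rA", "rB"),
             species = c("A", "B"),
             sequence = c("ACGTACGT", "CCCCCCCC"))
}

tiny_training_set <- function() build_training_set(tiny_records(), k = 4L)

write_lines_tmp <- function(lines, ext = ".tsv") {
  f <- withr::local_tempfile(fileext = ext,
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

# Small but fully realistic synthetic experiment (short references keep the
# classifier fast while preserving every pipeline property).
small_config <- function(...) {
  defaults <- list(n_species = 5L, seq_length = 300L, depth = 20000L,
                   n_variants_per_species = 2L, rng_seed = 11L)
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}
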