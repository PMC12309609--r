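# small deterministic fixtures shared across test files

tiny_panel <- function(seqs, loci = NULL) {
  allele_panel(paste0("X*", sprintf("%02d", seq_along(seqs))), seqs,
               locus = loci %||% rep("B", length(seqs)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# standard small synthetic world used by several files (kept small for speed)
small_world <- function(seed = 11, n = 48) {
  panel <- generate_panel(n, seed = seed)
  pm <- planted_model(panel, seed = seed)
  gen <- generate_binding(panel, pm, seed = seed)
  list(panel = panel, pm = pm, gen = gen,
       bm = aggregate_replicates(gen$runs))
}
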