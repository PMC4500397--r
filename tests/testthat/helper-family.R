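# The three-genome fixture family (ancestor, collinear descendant, inverted
# descendant) at the documented seed, built once per test run and shared.

.family_cache <- new.env(parent = emptyenv())

get_family <- function() {
  if (is.null(.family_cache$fam)) {
    .family_cache$fam <- simulate_genome_family(sim_config(seed = 1234L))
  }
  .family_cache$fam
}

get_family_annotations <- function() {
  if (is.null(.family_cache$anns)) {
    fam <- get_family()
    .family_cache$anns <- lapply(fam, annotate_sim)
  }
  .family_cache$anns
}

get_family_orthologs <- function(which = c("collinear", "inverted")) {
  which <- match.arg(which)
  key <- paste0("orth_", which)
  if (is.null(.family_cache[[key]])) {
    anns <- get_family_annotations()
    .family_cache[[key]] <- ortholog_map(anns$ancestor, anns[[which]])
  }
  .family_cache[[key]]
}

# map truth ranks of a sim to annotation orf_ids via exact coordinates
truth_to_orf_ids <- function(sim, annot) {
  key <- paste(annot$orfs$start, annot$orfs$end, annot$orfs$strand)
  match(paste(sim$truth$orfs$start, sim$truth$orfs$end, sim$truth$orfs$strand),
        key)
}
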