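# Shared fixtures, memoised so the expensive training runs happen once per
# test session. All randomness flows from fixed seeds.

fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = fixture_cache))
    assign(key, force(expr), envir = fixture_cache)
  get(key, envir = fixture_cache)
}

# Default planted-marker fixture: 3 cancer types x 20 samples, 40 species,
# 5 markers per type at fold change 8.
fx_dataset <- function() memo("ds", generate_dataset(synthetic_spec()))

fx_graph <- function() memo("graph", {
  ds <- fx_dataset()
  norm <- normalize_samples(filter_low_abundance(ds$abundance))
  assemble_graph(norm,
                 build_metabolic_edges(rownames(norm), ds$metabolic),
                 build_phylogenetic_edges(rownames(norm), ds$taxonomy),
                 ds$metadata)
})

fx_embeddings <- function() memo("emb",
  initial_embeddings(fx_graph(), ae_config(seed = 1)))

# 80/20 stratified fit for held-out evaluation.
fx_fit_split <- function() memo("fit_split",
  fit_hgt(fx_graph(), train_config(seed = 1), embeddings = fx_embeddings()))

# Full-data fit for signature extraction.
fx_fit_full <- function() memo("fit_full",
  fit_hgt(fx_graph(), train_config(seed = 1, split_fraction = 1),
          embeddings = fx_embeddings()))

fx_truth_pairs <- function() {
  ds <- fx_dataset()
  unlist(lapply(names(ds$truth$markers),
                function(ty) paste(ty, ds$truth$markers[[ty]])))
}

# A very small graph for fast structural/gradient tests.
fx_tiny_graph <- function(seed = 5) {
  ds <- generate_dataset(synthetic_spec(
    n_types = 2, samples_per_type = 3, n_species = 5, markers_per_type = 1,
    n_genera = 2, n_compounds = 4, compounds_per_species = 2, seed = seed))
  norm <- normalize_samples(ds$abundance)
  list(ds = ds,
       graph = assemble_graph(norm,
                              build_metabolic_edges(rownames(norm), ds$metabolic),
                              build_phylogenetic_edges(rownames(norm), ds$taxonomy),
                              ds$metadata))
}
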