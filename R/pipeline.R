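# End-to-end orchestration: preprocess -> graph assembly -> embeddings ->
# training -> signature calling -> exports, with a checksum manifest so a run
# is verifiably reproducible from its config and seed.

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
}

as_input <- function(x, reader, what) {
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) stop(what, " path not found: ", x)
    reader(x)
  } else x
}

#' Run the full signature-discovery pipeline
#'
#' Executes filtering, per-sample normalization, relation-network
#' construction, heterogeneous-graph assembly, autoencoder embeddings,
#' transformer training (a stratified split for evaluation plus, when
#' `full_data = TRUE`, a full-data fit for signature extraction),
#' high-attention calling, hypergeometric enrichment, and all tabular exports.
#' Every artifact is listed in a manifest with its MD5 checksum; identical
#' inputs, config and seed yield identical checksums.
#'
#' @param abundance raw-count [abundance_matrix()] or TSV path.
#' @param metadata [sample_metadata()] or TSV path.
#' @param taxonomy [taxonomy_table()], TSV path, or `NULL`.
#' @param metabolic [metabolic_table()], TSV path, or `NULL`.
#' @param outdir output directory (created).
#' @param fraction low-abundance filter fraction (default 0.001).
#' @param config a [train_config()].
#' @param ae an [ae_config()]; its seed is tied to `config$seed`.
#' @param alpha,correction signature selection options.
#' @param full_data train a second, full-data model for signature extraction
#'   (default `TRUE`); otherwise signatures come from the split model's
#'   attention.
#' @param verbose print stage progress.
#' @return an object of class `microsig_run`: the fitted model(s), the
#'   signature table, metrics, and the artifact `manifest`.
#' @export
run_pipeline <- function(abundance, metadata, taxonomy = NULL, metabolic = NULL,
                         outdir, fraction = 0.001, config = train_config(),
                         ae = NULL, alpha = 0.05,
                         correction = c("none", "bh"), full_data = TRUE,
                         verbose = TRUE) {
  correction <- match.arg(correction)
  say <- function(...) if (verbose) message(sprintf(...))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(ae)) ae <- ae_config(seed = config$seed)

  abundance <- stage("input", as_input(abundance, read_abundance_matrix, "abundance"))
  metadata <- stage("input", as_input(metadata, read_metadata, "metadata"))
  taxonomy <- stage("input", as_input(taxonomy, read_taxonomy_table, "taxonomy"))
  metabolic <- stage("input", as_input(metabolic, read_metabolic_table, "metabolic"))

  say("preprocess: filtering (fraction %g) and normalizing", fraction)
  filtered <- stage("preprocess", filter_low_abundance(abundance, fraction))
  norm <- stage("preprocess", normalize_samples(filtered))
  species <- rownames(norm)
  met_net <- stage("preprocess", if (is.null(metabolic))
    relation_network(NULL, species) else build_metabolic_edges(species, metabolic))
  phy_net <- stage("preprocess", if (is.null(taxonomy))
    relation_network(NULL, species) else build_phylogenetic_edges(species, taxonomy))

  say("graph: %d species x %d samples, %d metabolic + %d phylogenetic edges",
      nrow(norm), ncol(norm), nrow(met_net), nrow(phy_net))
  graph <- stage("graph", assemble_graph(norm, met_net, phy_net, metadata))
  emb <- stage("embeddings", initial_embeddings(graph, ae))

  say("train: %d epochs, %d heads, lr %g", config$epochs, config$n_heads,
      config$learning_rate)
  fit <- stage("train", fit_hgt(graph, config, embeddings = emb))
  sig_fit <- fit
  if (full_data && config$split_fraction < 1) {
    full_cfg <- config
    full_cfg$split_fraction <- 1
    sig_fit <- stage("train", fit_hgt(graph, full_cfg, embeddings = emb))
  }

  say("signatures: thres %g, alpha %g, correction %s", config$thres, alpha,
      correction)
  mask <- stage("signatures", call_high_attention(sig_fit$attention, config$thres))
  idx <- match(graph$samples, metadata$sample_id)
  meta_sub <- sample_metadata(metadata$sample_id[idx], metadata$label[idx])
  enr <- stage("signatures", enrichment_test(mask, meta_sub))
  sig <- stage("signatures", select_signatures(enr, sig_fit$attention, metadata,
                                               alpha, correction, taxonomy))

  say("export: writing artifacts to %s", outdir)
  paths <- c(normalized = file.path(outdir, "normalized_abundance.tsv"),
             metabolic_network = file.path(outdir, "metabolic_network.tsv"),
             phylogenetic_network = file.path(outdir, "phylogenetic_network.tsv"),
             signatures = file.path(outdir, "signatures.tsv"),
             enrichment = file.path(outdir, "enrichment_all.tsv"),
             upset = file.path(outdir, "upset_membership.tsv"),
             metrics = file.path(outdir, "metrics.tsv"),
             training_log = file.path(outdir, "training_log.tsv"))
  stage("export", {
    write_abundance_matrix(norm, paths["normalized"])
    write_relation_network(met_net, paths["metabolic_network"])
    write_relation_network(phy_net, paths["phylogenetic_network"])
    write_signature_table(sig, paths["signatures"])
    write_tsv_raw(as.data.frame(enr), paths["enrichment"])
    write_upset_membership(export_upset_membership(sig), paths["upset"])
    write_tsv_raw(fit$metrics$per_class, paths["metrics"])
    write_tsv_raw(fit$history, paths["training_log"])
  })
  rel_all <- relation_network(rbind(as.data.frame(met_net), as.data.frame(phy_net)),
                              species)
  cy <- stage("export", export_cytoscape(sig, rel_all,
                                         file.path(outdir, "cytoscape")))
  paths <- c(paths, cytoscape_edges = cy$edges, cytoscape_nodes = cy$nodes,
             cytoscape_sif = cy$sif)
  manifest <- data.frame(artifact = names(paths), path = unname(paths),
                         md5 = unname(tools::md5sum(unname(paths))),
                         stringsAsFactors = FALSE)
  write_tsv_raw(manifest, file.path(outdir, "manifest.tsv"))

  structure(list(fit = fit, signature_fit = sig_fit, signatures = sig,
                 enrichment = enr, mask = mask, metrics = fit$metrics,
                 graph = graph, manifest = manifest, outdir = outdir),
            class = "microsig_run")
}

#' @export
print.microsig_run <- function(x, ...) {
  cat("microsig pipeline run\n")
  print(x$fit$metrics)
  cat(sprintf("  signatures: %d (species, cancer type) associations over %d species\n",
              nrow(x$signatures), length(unique(x$signatures$taxid))))
  cat(sprintf("  artifacts: %d files in %s\n", nrow(x$manifest), x$outdir))
  invisible(x)
}
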