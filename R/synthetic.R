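# Self-contained synthetic fixtures: sparse negative-binomial abundance
# matrices with planted cancer-type-specific marker species, plus matching
# taxonomy (genus blocks) and metabolic (shared-compound) tables, so every
# pipeline stage is testable without access-controlled cohort data.

CANCER_CODES <- c("COAD", "THCA", "READ", "LUAD", "LUSC", "BRCA",
                  "PRAD", "SKCM", "STAD", "PAAD", "KIRC", "GBM")

#' Specification for a synthetic tumor-microbiome dataset
#'
#' Counts are drawn per cell from a negative binomial with mean
#' `baseline_mean` and size (inverse-dispersion) `dispersion`, then zeroed
#' independently with probability `sparsity` (zero inflation). Each cancer
#' type owns `markers_per_type` planted marker species whose mean is
#' multiplied by `fold_change` in that type's samples only; `shared_markers`
#' additional species are elevated in every type (emulating signatures shared
#' across all types). Genera are assigned round-robin over `n_genera` so
#' shared-genus edges exist; each species receives `compounds_per_species`
#' compounds drawn uniformly from `n_compounds` so shared-compound edges exist.
#'
#' @param n_types number of cancer types.
#' @param samples_per_type samples per type.
#' @param n_species total species count.
#' @param markers_per_type planted type-specific marker species per type.
#' @param fold_change marker mean multiplier in the marker's own type
#'   (>= 1; 1 plants nothing and gives a null dataset).
#' @param baseline_mean negative-binomial mean of background counts.
#' @param dispersion negative-binomial size parameter.
#' @param sparsity independent zero-inflation rate, in `[0, 1)`.
#' @param n_genera number of genus blocks (round-robin assignment).
#' @param n_compounds size of the compound universe.
#' @param compounds_per_species compounds drawn per species.
#' @param shared_markers species planted as markers of every type.
#' @param seed RNG seed; everything downstream is reproducible from it.
#' @return a validated `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_types = 3, samples_per_type = 20, n_species = 40,
                           markers_per_type = 5, fold_change = 8,
                           baseline_mean = 50, dispersion = 2, sparsity = 0.3,
                           n_genera = 8, n_compounds = 15,
                           compounds_per_species = 3, shared_markers = 0,
                           seed = 1) {
  spec <- list(n_types = as.integer(n_types),
               samples_per_type = as.integer(samples_per_type),
               n_species = as.integer(n_species),
               markers_per_type = as.integer(markers_per_type),
               fold_change = fold_change, baseline_mean = baseline_mean,
               dispersion = dispersion, sparsity = sparsity,
               n_genera = as.integer(n_genera),
               n_compounds = as.integer(n_compounds),
               compounds_per_species = as.integer(compounds_per_species),
               shared_markers = as.integer(shared_markers),
               seed = as.integer(seed))
  with(spec, {
    if (n_types < 1 || samples_per_type < 1 || n_species < 1 ||
        n_genera < 1 || n_compounds < 1)
      stop("all synthetic counts must be positive")
    if (markers_per_type < 0 || shared_markers < 0)
      stop("marker counts must be nonnegative")
    if (markers_per_type * n_types + shared_markers > n_species)
      stop("infeasible spec: markers_per_type * n_types + shared_markers > n_species")
    if (fold_change < 1) stop("fold_change must be >= 1")
    if (baseline_mean <= 0 || dispersion <= 0) stop("mean and dispersion must be positive")
    if (sparsity < 0 || sparsity >= 1) stop("sparsity must lie in [0, 1)")
    if (compounds_per_species > n_compounds)
      stop("infeasible spec: compounds_per_species > n_compounds")
  })
  structure(spec, class = "synthetic_spec")
}

type_labels <- function(n) {
  if (n <= length(CANCER_CODES)) CANCER_CODES[seq_len(n)]
  else c(CANCER_CODES, sprintf("TYPE%02d", seq_len(n - length(CANCER_CODES))))
}

#' Generate a synthetic dataset with planted cancer-type markers
#'
#' @param spec a [synthetic_spec()].
#' @return a list of class `synthetic_dataset` with elements `abundance`
#'   (raw-count [abundance_matrix()]), `metadata` ([sample_metadata()]),
#'   `taxonomy` ([taxonomy_table()]), `metabolic` ([metabolic_table()]),
#'   `truth` (planted markers per type, genus and compound assignments) and
#'   `spec`.
#' @export
generate_dataset <- function(spec = synthetic_spec()) {
  if (!inherits(spec, "synthetic_spec")) stop("spec must come from synthetic_spec()")
  set.seed(spec$seed)
  n_sa <- spec$n_types * spec$samples_per_type
  taxids <- as.character(1000L + seq_len(spec$n_species))
  samples <- sprintf("S%03d", seq_len(n_sa))
  types <- type_labels(spec$n_types)
  labels <- rep(types, each = spec$samples_per_type)

  n_mark <- spec$markers_per_type * spec$n_types + spec$shared_markers
  pool <- if (n_mark > 0) sample(taxids, n_mark) else character(0)
  shared <- if (spec$shared_markers > 0) pool[seq_len(spec$shared_markers)] else character(0)
  own <- pool[spec$shared_markers + seq_len(spec$markers_per_type * spec$n_types)]
  markers <- lapply(seq_len(spec$n_types), function(i) {
    mine <- own[(i - 1L) * spec$markers_per_type + seq_len(spec$markers_per_type)]
    sort(c(shared, if (spec$markers_per_type > 0) mine))
  })
  names(markers) <- types

  mu <- matrix(spec$baseline_mean, spec$n_species, n_sa,
               dimnames = list(taxids, samples))
  for (ty in types) {
    cols <- labels == ty
    mu[markers[[ty]], cols] <- mu[markers[[ty]], cols] * spec$fold_change
  }
  counts <- matrix(stats::rnbinom(length(mu), size = spec$dispersion, mu = as.vector(mu)),
                   spec$n_species, n_sa, dimnames = dimnames(mu))
  if (spec$sparsity > 0)
    counts[stats::runif(length(counts)) < spec$sparsity] <- 0L

  genus_names <- sprintf("Genus%02d", seq_len(spec$n_genera))
  genus <- rep(genus_names, length.out = spec$n_species)
  tax <- taxonomy_table(taxids, paste0("Species ", taxids), genus)
  compound_names <- sprintf("C%03d", seq_len(spec$n_compounds))
  comp <- lapply(taxids, function(t) sample(compound_names, spec$compounds_per_species))
  names(comp) <- taxids

  structure(list(
    abundance = abundance_matrix(counts),
    metadata = sample_metadata(samples, labels),
    taxonomy = tax,
    metabolic = metabolic_table(comp),
    truth = list(markers = markers, shared_markers = shared,
                 genus = stats::setNames(genus, taxids), compounds = comp),
    spec = spec), class = "synthetic_dataset")
}

#' Write a synthetic dataset bundle as TSV files
#'
#' Writes `abundance.tsv`, `metadata.tsv`, `taxonomy.tsv`, `metabolic.tsv` and
#' `ground_truth.tsv` (long-format `cancer_type`, `taxid`) into `dir`.
#'
#' @param ds a [generate_dataset()] result.
#' @param dir output directory (created if absent).
#' @return invisibly, the named vector of file paths.
#' @export
write_dataset <- function(ds, dir) {
  if (!inherits(ds, "synthetic_dataset")) stop("ds must come from generate_dataset()")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(abundance = file.path(dir, "abundance.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             taxonomy = file.path(dir, "taxonomy.tsv"),
             metabolic = file.path(dir, "metabolic.tsv"),
             ground_truth = file.path(dir, "ground_truth.tsv"))
  write_abundance_matrix(ds$abundance, paths["abundance"])
  write_metadata(ds$metadata, paths["metadata"])
  write_taxonomy_table(ds$taxonomy, paths["taxonomy"])
  write_metabolic_table(ds$metabolic, paths["metabolic"])
  truth <- data.frame(
    cancer_type = rep(names(ds$truth$markers), lengths(ds$truth$markers)),
    taxid = unlist(ds$truth$markers, use.names = FALSE),
    stringsAsFactors = FALSE)
  write_tsv_raw(truth, paths["ground_truth"])
  invisible(paths)
}

#' A hand-sized worked example with brute-force expected values
#'
#' Four species, six samples, two cancer types; all intermediate quantities
#' (normalized matrix, metabolic and phylogenetic edge lists, hypergeometric
#' enrichment p-values for a fixed high-attention mask) were computed once by
#' exhaustive enumeration and are shipped as frozen constants for exact
#' regression tests.
#'
#' @return a list with the input tables, a fixed high-attention `mask`, and an
#'   `expected` list of precomputed values.
#' @export
tiny_worked_example <- function() {
  counts <- matrix(c(5, 1, 0, 4,
                     0, 2, 3, 5,
                     4, 0, 1, 5,
                     0, 3, 2, 5,
                     1, 0, 2, 7,
                     0, 1, 0, 9),
                   nrow = 4, ncol = 6,
                   dimnames = list(c("101", "102", "103", "104"),
                                   c("s1", "s2", "s3", "s4", "s5", "s6")))
  meta <- sample_metadata(colnames(counts), rep(c("A", "B"), each = 3))
  tax <- taxonomy_table(c("101", "102", "103", "104"),
                        c("Bacteroides fragilis", "Bacteroides ovatus",
                          "Odoribacter splanchnicus", "Bacillus subtilis"),
                        c("Bacteroides", "Bacteroides", "Odoribacter", "Bacillus"))
  met <- metabolic_table(list(
    "101" = c("butyrate", "acetate"),
    "102" = "acetate",
    "103" = c("butyrate", "propionate")))
  mask <- matrix(0L, 4, 6, dimnames = dimnames(counts))
  mask["104", c("s4", "s5", "s6")] <- 1L
  mask["101", c("s1", "s3")] <- 1L
  expected <- list(
    normalized = counts / 10,          # every column sums to 10 by construction
    met_edges = data.frame(taxid_a = c("101", "101"), taxid_b = c("102", "103"),
                           relation_type = "metabolic",
                           annotation = c("acetate", "butyrate"),
                           stringsAsFactors = FALSE),
    phy_edges = data.frame(taxid_a = "101", taxid_b = "102",
                           relation_type = "phylogenetic",
                           annotation = "Bacteroides", stringsAsFactors = FALSE),
    # exact upper-tail hypergeometric probabilities, enumerated by hand:
    # (104, B): N=6, K=3, n=3, k=3 -> C(3,3)C(3,0)/C(6,3) = 1/20
    # (101, A): N=6, K=3, n=2, k=2 -> C(3,2)C(3,0)/C(6,2) = 3/15
    hyper = data.frame(taxid = c("104", "104", "101", "101"),
                       cancer_type = c("B", "A", "A", "B"),
                       p_value = c(0.05, 1, 0.2, 1),
                       stringsAsFactors = FALSE))
  list(counts = abundance_matrix(counts), metadata = meta, taxonomy = tax,
       metabolic = met, mask = mask, expected = expected)
}
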