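# Abundance filtering/normalization and construction of the two
# species-species relation networks (shared metabolic compound, shared genus).

#' Construct a typed species-species relation network
#'
#' Undirected, stored with `taxid_a < taxid_b` (numeric-aware ordering). One row
#' per (pair, relation type, annotation); a pair sharing several compounds
#' therefore appears once per shared compound.
#'
#' @param edges data frame with columns `taxid_a`, `taxid_b`, `relation_type`
#'   (`"metabolic"` or `"phylogenetic"`) and `annotation` (the shared compound
#'   or genus).
#' @param species character vector: the species universe; both endpoints of
#'   every edge must belong to it.
#' @return a `relation_network` data frame with a `species` attribute.
#' @export
relation_network <- function(edges = NULL, species = character(0)) {
  species <- as.character(species)
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0) {
    edges <- data.frame(taxid_a = character(0), taxid_b = character(0),
                        relation_type = character(0), annotation = character(0),
                        stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  need <- c("taxid_a", "taxid_b", "relation_type", "annotation")
  if (!all(need %in% colnames(edges)))
    stop("relation network needs columns: ", paste(need, collapse = ", "))
  edges <- edges[, need]
  for (cl in need) edges[[cl]] <- as.character(edges[[cl]])
  if (nrow(edges)) {
    if (any(edges$taxid_a == edges$taxid_b)) stop("self-loop in relation network")
    if (!all(edges$relation_type %in% c("metabolic", "phylogenetic")))
      stop("relation_type must be 'metabolic' or 'phylogenetic'")
    miss <- setdiff(unique(c(edges$taxid_a, edges$taxid_b)), species)
    if (length(miss))
      stop("edge endpoint(s) outside species universe: ",
           paste(utils::head(miss, 5), collapse = ", "))
    swap <- id_rank(c(edges$taxid_a, edges$taxid_b))
    swap <- swap[seq_len(nrow(edges))] >
      swap[nrow(edges) + seq_len(nrow(edges))]
    tmp <- edges$taxid_a[swap]
    edges$taxid_a[swap] <- edges$taxid_b[swap]
    edges$taxid_b[swap] <- tmp
    if (anyDuplicated(edges)) stop("duplicate relation edge")
    edges <- edges[order(id_rank(edges$taxid_a), id_rank(edges$taxid_b),
                         edges$relation_type, edges$annotation), ]
    rownames(edges) <- NULL
  }
  structure(edges, species = species,
            class = c("relation_network", "data.frame"))
}

#' Write / read a relation network as TSV
#' @param net a [relation_network()].
#' @param path file path.
#' @export
write_relation_network <- function(net, path) write_tsv_raw(net, path)

#' @rdname write_relation_network
#' @param species species universe for validation on read.
#' @export
read_relation_network <- function(path, species) {
  df <- read_tsv_raw(path, n_min_cols = 4)
  if (is.null(df)) df <- NULL
  relation_network(df, species)
}

#' Filter species by total abundance
#'
#' Removes species expressed at less than `fraction` (default 0.1%) of the
#' matrix. Under the default `grand_total` basis a species is removed when its
#' summed count across all samples is strictly less than
#' `fraction x grand total`; a species sitting exactly at the threshold is
#' retained. The alternative `per_sample_prevalence` basis retains a species
#' when its relative abundance reaches `fraction` in at least one sample.
#'
#' @param matrix an [abundance_matrix()] of raw counts.
#' @param fraction retention threshold, in (0, 1); default `0.001`.
#' @param basis `"grand_total"` (default) or `"per_sample_prevalence"`.
#' @return the filtered [abundance_matrix()]; sample set and the ordering of
#'   surviving species are unchanged.
#' @export
filter_low_abundance <- function(matrix, fraction = 0.001,
                                 basis = c("grand_total", "per_sample_prevalence")) {
  basis <- match.arg(basis)
  if (!inherits(matrix, "abundance_matrix")) matrix <- abundance_matrix(matrix)
  if (is_normalized(matrix))
    stop("filter_low_abundance expects raw counts, not a normalized matrix")
  if (nrow(matrix) == 0 || ncol(matrix) == 0) stop("empty abundance matrix")
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop("fraction must lie in (0, 1)")
  keep <- if (basis == "grand_total") {
    rowSums(matrix) >= fraction * sum(matrix)
  } else {
    cs <- colSums(matrix)
    rel <- sweep(unclass(matrix), 2, ifelse(cs == 0, 1, cs), "/")
    apply(rel, 1, max) >= fraction
  }
  abundance_matrix(unclass(matrix)[keep, , drop = FALSE], normalized = FALSE)
}

#' Scale each sample column to sum to 1
#'
#' All-zero sample columns are left all-zero (so sample ids stay aligned with
#' the metadata) and reported in a warning and in the `empty_samples`
#' attribute; set `drop_empty = TRUE` to remove them instead.
#'
#' @param matrix an [abundance_matrix()] of raw counts.
#' @param drop_empty drop all-zero sample columns?
#' @return a normalized [abundance_matrix()].
#' @export
normalize_samples <- function(matrix, drop_empty = FALSE) {
  if (!inherits(matrix, "abundance_matrix")) matrix <- abundance_matrix(matrix)
  vals <- unclass(matrix)
  cs <- colSums(vals)
  empty <- colnames(vals)[cs == 0]
  if (length(empty))
    warning("all-zero sample column(s): ", paste(empty, collapse = ", "))
  out <- sweep(vals, 2, ifelse(cs == 0, 1, cs), "/")
  if (drop_empty) out <- out[, cs > 0, drop = FALSE]
  out <- abundance_matrix(out, normalized = TRUE)
  attr(out, "empty_samples") <- if (drop_empty) character(0) else empty
  out
}

#' Build metabolic (shared-compound) species-species edges
#'
#' One edge per unordered species pair and shared compound; species absent from
#' the metabolic table contribute no edges.
#'
#' @param species deduplicated character vector of taxids.
#' @param table a [metabolic_table()].
#' @return a [relation_network()] of metabolic edges.
#' @export
build_metabolic_edges <- function(species, table) {
  species <- as.character(species)
  if (anyDuplicated(species)) stop("species list must be deduplicated")
  sets <- lapply(species, function(s) compound_set(table, s))
  names(sets) <- species
  comp2sp <- split(rep(species, lengths(sets)), unlist(sets, use.names = FALSE))
  rows <- lapply(names(comp2sp), function(cmp) {
    sp <- comp2sp[[cmp]][id_order(comp2sp[[cmp]])]
    if (length(sp) < 2) return(NULL)
    pr <- utils::combn(sp, 2)
    data.frame(taxid_a = pr[1, ], taxid_b = pr[2, ],
               relation_type = "metabolic", annotation = cmp,
               stringsAsFactors = FALSE)
  })
  relation_network(do.call(rbind, rows), species)
}

#' Build phylogenetic (shared-genus) species-species edges
#'
#' One edge per unordered pair of species with identical, non-missing genus;
#' species with missing genus contribute no edges.
#'
#' @param species deduplicated character vector of taxids.
#' @param taxonomy a [taxonomy_table()].
#' @return a [relation_network()] of phylogenetic edges.
#' @export
build_phylogenetic_edges <- function(species, taxonomy) {
  species <- as.character(species)
  if (anyDuplicated(species)) stop("species list must be deduplicated")
  genus <- taxonomy$genus[match(species, taxonomy$taxid)]
  keep <- !is.na(genus)
  groups <- split(species[keep], genus[keep])
  rows <- lapply(names(groups), function(g) {
    sp <- groups[[g]][id_order(groups[[g]])]
    if (length(sp) < 2) return(NULL)
    pr <- utils::combn(sp, 2)
    data.frame(taxid_a = pr[1, ], taxid_b = pr[2, ],
               relation_type = "phylogenetic", annotation = g,
               stringsAsFactors = FALSE)
  })
  relation_network(do.call(rbind, rows), species)
}
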