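# Readers and writers for every external table the pipeline touches, plus
# visualization-ready exports (Cytoscape tables/SIF, UpSet membership).
# Dialect: tab separator, UTF-8, no quoting, "." decimal, header row required
# except for sample metadata (configurable).

# ---- internal helpers --------------------------------------------------------

# Numeric-aware ranking of identifier vectors: taxids sort numerically when all
# ids are integer-like, lexicographically otherwise.
id_rank <- function(x) {
  x <- as.character(x)
  if (length(x) && all(grepl("^[0-9]+$", x))) rank(as.numeric(x), ties.method = "first")
  else rank(x, ties.method = "first")
}

id_order <- function(x) order(id_rank(x))

# Full-precision number formatting so write -> read round trips are exact.
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("")
    if (is.finite(v) && v == round(v) && abs(v) < 1e15) return(sprintf("%.0f", v))
    formatC(v, digits = 17, format = "g")
  }, character(1))
  out
}

write_tsv_raw <- function(df, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(colnames(df), collapse = "\t"), con)
  if (nrow(df)) {
    cols <- lapply(df, function(col) {
      if (is.numeric(col)) fmt_num(col) else {
        col <- as.character(col)
        col[is.na(col)] <- ""
        col
      }
    })
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}

read_tsv_raw <- function(path, n_min_cols = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) return(NULL)
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          quote = "", comment.char = "", colClasses = "character",
                          stringsAsFactors = FALSE, encoding = "UTF-8")
  if (ncol(df) < n_min_cols) stop("expected at least ", n_min_cols, " columns in ", path)
  df
}

as_num_strict <- function(x, what) {
  out <- suppressWarnings(as.numeric(x))
  if (anyNA(out[!is.na(x) & x != ""])) stop("nonnumeric ", what)
  out
}

# ---- AbundanceMatrix ---------------------------------------------------------

#' Construct a species-by-sample abundance matrix
#'
#' A thin validated wrapper around a numeric matrix: rows are species (named by
#' taxonomy id), columns are samples. Values are raw counts or, after
#' [normalize_samples()], per-sample relative abundances.
#'
#' @param values numeric matrix, species in rows, samples in columns; must have
#'   unique, nonempty row and column names and nonnegative finite entries.
#' @param normalized logical; `TRUE` marks per-sample relative abundances, in
#'   which case every nonzero column must sum to 1 within `1e-9`.
#' @return an object of class `abundance_matrix` (a numeric matrix with a
#'   `normalized` attribute).
#' @export
abundance_matrix <- function(values, normalized = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("abundance values must be a numeric matrix")
  # R normalizes the dimnames of an empty dimension to NULL, so names are
  # only required along non-empty dimensions
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      (ncol(values) > 0 && is.null(colnames(values))))
    stop("abundance matrix needs row (species) and column (sample) names")
  if (anyDuplicated(rownames(values))) stop("duplicate species ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (any(!is.finite(values))) stop("non-finite abundance values")
  if (any(values < 0)) stop("negative abundance values")
  if (normalized) {
    cs <- colSums(values)
    bad <- abs(cs - 1) > 1e-9 & cs != 0
    if (any(bad))
      stop("matrix flagged normalized but column(s) do not sum to 1: ",
           paste(colnames(values)[bad], collapse = ", "))
  }
  structure(values, normalized = normalized,
            class = c("abundance_matrix", class(values)))
}

is_normalized <- function(x) isTRUE(attr(x, "normalized"))

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix: %d species x %d samples (%s)\n",
              nrow(x), ncol(x),
              if (is_normalized(x)) "normalized" else "raw counts"))
  cat(sprintf("  nonzero cells: %d (%.1f%%)\n", sum(x > 0),
              if (length(x)) 100 * mean(x > 0) else 0))
  invisible(x)
}

#' Read an abundance matrix from a tab-separated file
#'
#' The file must have one header row and one leading ID column; the remaining
#' cells must be nonnegative numbers. `orientation` says which axis the file's
#' rows represent; the returned matrix is always species x samples.
#'
#' @param path path to a TSV file.
#' @param orientation `"species_rows"` (default) or `"samples_rows"`.
#' @param normalized logical, mark the values as per-sample relative abundances.
#' @return an [abundance_matrix()].
#' @export
read_abundance_matrix <- function(path,
                                  orientation = c("species_rows", "samples_rows"),
                                  normalized = FALSE) {
  orientation <- match.arg(orientation)
  df <- read_tsv_raw(path, n_min_cols = 2)
  if (is.null(df)) stop("empty abundance file: ", path)
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicate row IDs in abundance table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (anyDuplicated(colnames(df)[-1]))
    stop("duplicate column IDs in abundance table")
  raw <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(raw), nrow(raw), ncol(raw)))
  if (anyNA(num)) stop("nonnumeric cell(s) in abundance table")
  dimnames(num) <- list(ids, colnames(df)[-1])
  if (orientation == "samples_rows") num <- t(num)
  abundance_matrix(num, normalized = normalized)
}

#' Write an abundance matrix as TSV (species in rows)
#'
#' @param x an [abundance_matrix()].
#' @param path output path.
#' @param id_col name of the leading ID column.
#' @export
write_abundance_matrix <- function(x, path, id_col = "taxid") {
  df <- data.frame(rownames(x), stringsAsFactors = FALSE)
  names(df) <- id_col
  for (j in seq_len(ncol(x))) df[[colnames(x)[j]]] <- unname(x[, j])
  write_tsv_raw(df, path)
}

# ---- SampleMetadata ----------------------------------------------------------

#' Construct sample metadata (sample id -> cancer type label)
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param label character vector of nonempty cancer-type labels, same length.
#' @return a `sample_metadata` data frame with a `label_set` attribute listing
#'   the distinct labels in first-appearance order.
#' @export
sample_metadata <- function(sample_id, label) {
  sample_id <- as.character(sample_id)
  label <- as.character(label)
  if (length(sample_id) != length(label))
    stop("sample_id and label must have equal length")
  if (anyDuplicated(sample_id))
    stop("duplicate sample id: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  if (any(is.na(label) | label == "")) stop("empty label")
  df <- data.frame(sample_id = sample_id, label = label,
                   stringsAsFactors = FALSE)
  structure(df, label_set = unique(label),
            class = c("sample_metadata", "data.frame"))
}

#' Read a two-column sample metadata table
#'
#' @param path TSV with columns (sample_id, label).
#' @param header logical; does the file carry a header row?
#' @return a [sample_metadata()] object; an empty file yields 0 samples.
#' @export
read_metadata <- function(path, header = TRUE) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  if (file.size(path) == 0) return(sample_metadata(character(0), character(0)))
  df <- utils::read.table(path, sep = "\t", header = header, check.names = FALSE,
                          quote = "", comment.char = "", colClasses = "character",
                          stringsAsFactors = FALSE, encoding = "UTF-8")
  if (ncol(df) < 2) stop("metadata must have two columns (sample_id, label)")
  sample_metadata(df[[1]], df[[2]])
}

#' Write sample metadata as TSV
#' @param meta a [sample_metadata()] object.
#' @param path output path.
#' @param header write a header row?
#' @export
write_metadata <- function(meta, path, header = TRUE) {
  if (header) return(invisible(write_tsv_raw(meta, path)))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (nrow(meta)) writeLines(paste(meta$sample_id, meta$label, sep = "\t"), con)
  invisible(path)
}

label_set <- function(meta) attr(meta, "label_set")

# ---- TaxonomyTable -----------------------------------------------------------

#' Construct a taxonomy table (taxid -> name, genus)
#'
#' @param taxid vector of unique taxon identifiers.
#' @param name character vector of nonempty canonical species names.
#' @param genus character vector of genus names; `NA` or `""` means missing.
#' @return a `taxonomy_table` data frame.
#' @export
taxonomy_table <- function(taxid, name, genus = NA_character_) {
  taxid <- as.character(taxid)
  name <- as.character(name)
  genus <- as.character(genus)
  if (length(genus) == 1) genus <- rep(genus, length(taxid))
  if (anyDuplicated(taxid))
    stop("duplicated taxid: ",
         paste(unique(taxid[duplicated(taxid)]), collapse = ", "))
  if (any(is.na(name) | name == "")) stop("empty taxonomy name")
  genus[!is.na(genus) & genus == ""] <- NA_character_
  structure(data.frame(taxid = taxid, name = name, genus = genus,
                       stringsAsFactors = FALSE),
            class = c("taxonomy_table", "data.frame"))
}

#' Read a taxonomy table from TSV
#'
#' Columns: taxid (numeric), name, genus (may be blank, recorded as missing).
#'
#' @param path TSV path.
#' @return a [taxonomy_table()].
#' @export
read_taxonomy_table <- function(path) {
  df <- read_tsv_raw(path, n_min_cols = 3)
  if (is.null(df)) return(taxonomy_table(character(0), character(0), character(0)))
  if (!all(grepl("^[0-9]+$", df[[1]]))) stop("nonnumeric taxid in taxonomy table")
  taxonomy_table(df[[1]], df[[2]], df[[3]])
}

#' Write a taxonomy table as TSV
#' @param tax a [taxonomy_table()].
#' @param path output path.
#' @export
write_taxonomy_table <- function(tax, path) write_tsv_raw(tax, path)

# ---- MetabolicTable ----------------------------------------------------------

#' Construct a metabolic table (taxid -> set of compound ids)
#'
#' Species absent from the table are treated downstream as having the empty
#' compound set.
#'
#' @param compounds named list; names are taxids, elements are character
#'   vectors of compound identifiers (duplicates collapse to a set).
#' @return a `metabolic_table` (named list of sorted unique compound vectors).
#' @export
metabolic_table <- function(compounds = list()) {
  if (length(compounds) && is.null(names(compounds)))
    stop("metabolic table entries must be named by taxid")
  out <- lapply(compounds, function(x) sort(unique(as.character(x))))
  structure(out, class = "metabolic_table")
}

#' Read a long-format metabolic table from TSV
#'
#' One (taxid, compound) pair per row; duplicate pairs collapse.
#'
#' @param path TSV path with columns (taxid, compound).
#' @return a [metabolic_table()]; an empty file yields an empty mapping.
#' @export
read_metabolic_table <- function(path) {
  df <- read_tsv_raw(path, n_min_cols = 2)
  if (is.null(df) || nrow(df) == 0) return(metabolic_table())
  tx <- df[[1]]; cp <- df[[2]]
  if (any(is.na(tx) | tx == "" | is.na(cp) | cp == ""))
    stop("malformed row(s) in metabolic table (blank taxid or compound)")
  metabolic_table(split(cp, factor(tx, levels = unique(tx))))
}

#' Write a metabolic table as long-format TSV
#' @param tab a [metabolic_table()].
#' @param path output path.
#' @export
write_metabolic_table <- function(tab, path) {
  df <- data.frame(
    taxid = rep(names(tab), lengths(tab)),
    compound = unlist(tab, use.names = FALSE),
    stringsAsFactors = FALSE)
  if (!nrow(df)) df <- data.frame(taxid = character(0), compound = character(0))
  write_tsv_raw(df, path)
}

compound_set <- function(tab, taxid) {
  x <- tab[[as.character(taxid)]]
  if (is.null(x)) character(0) else x
}

# ---- SignatureTable ----------------------------------------------------------

SIGNATURE_COLS <- c("cancer_type", "taxid", "species_name",
                    "n_high_attention_samples", "p_value", "normalized_attention")

#' Construct a microbial signature table
#'
#' One row per (cancer type, species) association that passed the enrichment
#' test, carrying the high-attention sample count, the enrichment p-value, and
#' the within-type max-rescaled mean attention weight.
#'
#' @param df data frame with columns `cancer_type`, `taxid`, `species_name`,
#'   `n_high_attention_samples`, `p_value`, `normalized_attention`.
#' @return a validated `signature_table` data frame, rows grouped by cancer
#'   type (first-appearance order) and sorted within group by descending
#'   normalized attention, ties broken by ascending taxid.
#' @export
signature_table <- function(df = NULL) {
  if (is.null(df) || nrow(as.data.frame(df)) == 0) {
    df <- data.frame(cancer_type = character(0), taxid = character(0),
                     species_name = character(0),
                     n_high_attention_samples = integer(0),
                     p_value = numeric(0), normalized_attention = numeric(0),
                     stringsAsFactors = FALSE)
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_cols <- setdiff(SIGNATURE_COLS, colnames(df))
  if (length(missing_cols))
    stop("signature table missing column(s): ", paste(missing_cols, collapse = ", "))
  df <- df[, SIGNATURE_COLS]
  df$cancer_type <- as.character(df$cancer_type)
  df$taxid <- as.character(df$taxid)
  df$species_name <- as.character(df$species_name)
  df$n_high_attention_samples <- as.integer(df$n_high_attention_samples)
  df$p_value <- as.numeric(df$p_value)
  df$normalized_attention <- as.numeric(df$normalized_attention)
  if (anyDuplicated(df[, c("cancer_type", "taxid")]))
    stop("duplicate (cancer_type, taxid) row in signature table")
  if (nrow(df)) {
    if (any(df$p_value < 0 | df$p_value > 1)) stop("p_value outside [0, 1]")
    if (any(df$normalized_attention < 0 | df$normalized_attention > 1 + 1e-12))
      stop("normalized_attention outside [0, 1]")
    if (any(df$n_high_attention_samples < 0)) stop("negative high-attention count")
    grp <- match(df$cancer_type, unique(df$cancer_type))
    df <- df[order(grp, -df$normalized_attention, id_rank(df$taxid)), ]
    rownames(df) <- NULL
  }
  structure(df, class = c("signature_table", "data.frame"))
}

#' Write a signature table as TSV
#' @param table a [signature_table()].
#' @param path output path.
#' @export
write_signature_table <- function(table, path) {
  table <- signature_table(table)
  write_tsv_raw(table, path)
}

#' Read a signature table written by [write_signature_table()]
#' @param path TSV path.
#' @return a [signature_table()].
#' @export
read_signature_table <- function(path) {
  df <- read_tsv_raw(path, n_min_cols = 6)
  if (is.null(df) || nrow(df) == 0) return(signature_table())
  df$n_high_attention_samples <- as.integer(as_num_strict(
    df$n_high_attention_samples, "n_high_attention_samples"))
  df$p_value <- as_num_strict(df$p_value, "p_value")
  df$normalized_attention <- as_num_strict(df$normalized_attention,
                                           "normalized_attention")
  signature_table(df)
}

# ---- Cytoscape / UpSet exports ----------------------------------------------

#' Export signature associations and relation edges for Cytoscape
#'
#' Writes plain node/edge attribute tables importable through Cytoscape's table
#' import, plus a SIF file. Cancer-association edges carry the normalized
#' attention weight (rendered as edge thickness); metabolic/phylogenetic edges
#' between signature species are included with an empty weight. Relation edges
#' touching species absent from the signature table are excluded.
#'
#' @param table a [signature_table()].
#' @param relations a [relation_network()] (or `NULL` for none).
#' @param out_prefix path prefix; writes `<prefix>_edges.tsv`,
#'   `<prefix>_nodes.tsv` and `<prefix>.sif`.
#' @return invisibly, a list with the three paths and the edge table.
#' @export
export_cytoscape <- function(table, relations = NULL, out_prefix) {
  table <- signature_table(table)
  assoc <- data.frame(source = table$cancer_type, target = table$taxid,
                      interaction = rep("cancer_association", nrow(table)),
                      weight = table$normalized_attention,
                      stringsAsFactors = FALSE)
  rel <- data.frame(source = character(0), target = character(0),
                    interaction = character(0), weight = numeric(0),
                    stringsAsFactors = FALSE)
  if (!is.null(relations) && nrow(relations)) {
    keep <- relations$taxid_a %in% table$taxid & relations$taxid_b %in% table$taxid
    rr <- as.data.frame(relations)[keep, , drop = FALSE]
    if (nrow(rr))
      rel <- data.frame(source = rr$taxid_a, target = rr$taxid_b,
                        interaction = rr$relation_type,
                        weight = NA_real_, stringsAsFactors = FALSE)
  }
  edges <- rbind(assoc, rel)
  sp <- !duplicated(table$taxid)
  nodes <- rbind(
    data.frame(id = unique(table$cancer_type),
               node_type = rep("cancer", length(unique(table$cancer_type))),
               name = unique(table$cancer_type), stringsAsFactors = FALSE),
    data.frame(id = table$taxid[sp], node_type = rep("species", sum(sp)),
               name = table$species_name[sp], stringsAsFactors = FALSE))
  paths <- list(edges = paste0(out_prefix, "_edges.tsv"),
                nodes = paste0(out_prefix, "_nodes.tsv"),
                sif = paste0(out_prefix, ".sif"))
  write_tsv_raw(edges, paths$edges)
  write_tsv_raw(nodes, paths$nodes)
  con <- file(paths$sif, open = "wt", encoding = "UTF-8")
  if (nrow(edges))
    writeLines(paste(edges$source, edges$interaction, edges$target), con)
  close(con)
  invisible(c(paths, list(edge_table = edges, node_table = nodes)))
}

#' Binary species-by-cancer-type membership matrix for UpSet plots
#'
#' @param table a [signature_table()].
#' @return integer 0/1 matrix, rows = species (taxid), columns = cancer types;
#'   entry 1 iff the (species, cancer type) association is in the table.
#' @export
export_upset_membership <- function(table) {
  table <- signature_table(table)
  sp <- unique(table$taxid)
  ty <- unique(table$cancer_type)
  m <- matrix(0L, nrow = length(sp), ncol = length(ty),
              dimnames = list(sp, ty))
  if (nrow(table)) m[cbind(table$taxid, table$cancer_type)] <- 1L
  m
}

#' Write an UpSet membership matrix as TSV
#' @param m matrix from [export_upset_membership()].
#' @param path output path.
#' @export
write_upset_membership <- function(m, path) {
  df <- data.frame(taxid = rownames(m), stringsAsFactors = FALSE)
  for (j in seq_len(ncol(m))) df[[colnames(m)[j]]] <- unname(m[, j])
  if (!nrow(df)) df <- df[, , drop = FALSE]
  write_tsv_raw(df, path)
}
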