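# Filtering, normalization and relation-network construction.

mk_counts <- function(vals, species, samples) {
  abundance_matrix(matrix(vals, nrow = length(species),
                          dimnames = list(species, samples), byrow = TRUE))
}

test_that("low-abundance filter removes species below the grand-total fraction", {
  m <- mk_counts(c(750, 750, 250, 249, 1, 0), c("A", "B", "C"),
                 c("s1", "s2"))
  # totals A=1500 B=499 C=1, grand 2000, threshold 2 -> C removed
  f <- filter_low_abundance(m, 0.001)
  expect_equal(rownames(f), c("A", "B"))
  expect_equal(colnames(f), c("s1", "s2"))

  # a species sitting exactly at the threshold is retained (strict less-than)
  m2 <- mk_counts(c(998, 1000, 2, 0), c("A", "C"), c("s1", "s2"))
  expect_equal(rownames(filter_low_abundance(m2, 0.001)), c("A", "C"))

  # identical totals: nobody is below 0.1% of the grand total
  m3 <- abundance_matrix(matrix(5, 100, 4,
                                dimnames = list(paste0("sp", 1:100),
                                                paste0("s", 1:4))))
  expect_equal(nrow(filter_low_abundance(m3, 0.001)), 100)

  expect_error(filter_low_abundance(normalize_samples(m), 0.001), "raw counts")
  expect_error(filter_low_abundance(m, 0), "fraction")
})

test_that("filter matches the brute-force oracle on random matrices", {
  set.seed(401)
  for (rep in 1:100) {
    n_sp <- sample(2:8, 1); n_sa <- sample(1:5, 1)
    counts <- matrix(rpois(n_sp * n_sa, 3), n_sp, n_sa,
                     dimnames = list(paste0("sp", 1:n_sp), paste0("s", 1:n_sa)))
    counts[1, ] <- counts[1, ] + 1   # keep the matrix non-empty
    frac <- runif(1, 0.001, 0.3)
    got <- as.character(rownames(filter_low_abundance(abundance_matrix(counts), frac)))
    expect_identical(got, oracle_filter(counts, frac))
  }
})

test_that("per-sample normalization sums to one and flags empty samples", {
  m <- mk_counts(c(2, 0, 3, 0, 5, 0), c("A", "B", "C"), c("s1", "s2"))
  expect_warning(norm <- normalize_samples(m), "all-zero")
  expect_equal(unname(norm[, "s1"]), c(0.2, 0.3, 0.5))
  expect_equal(unname(norm[, "s2"]), c(0, 0, 0))
  expect_equal(attr(norm, "empty_samples"), "s2")
  expect_true(isTRUE(attr(norm, "normalized")))

  # single-species column
  m1 <- mk_counts(7, "A", "s1")
  expect_equal(unname(normalize_samples(m1)[1, 1]), 1)

  # dropping empty samples keeps ids aligned
  expect_warning(nd <- normalize_samples(m, drop_empty = TRUE))
  expect_equal(colnames(nd), "s1")
})

test_that("normalization is invariant to per-sample scaling and commutes with a no-op filter", {
  set.seed(7)
  counts <- matrix(rpois(40, 5) + 1, 8, 5,
                   dimnames = list(paste0("sp", 1:8), paste0("s", 1:5)))
  m <- abundance_matrix(counts)
  scaled <- abundance_matrix(sweep(counts, 2, c(2, 10, 1, 7, 3), "*"))
  expect_equal(unclass(normalize_samples(m)), unclass(normalize_samples(scaled)),
               ignore_attr = TRUE)
  # nothing removed at a tiny fraction -> filtering first changes nothing
  expect_equal(unclass(normalize_samples(filter_low_abundance(m, 1e-6))),
               unclass(normalize_samples(m)), ignore_attr = TRUE)
})

test_that("metabolic edges: one edge per shared compound per pair", {
  tab <- metabolic_table(list(A = c("butyrate", "acetate"), B = "butyrate",
                              C = "propionate"))
  net <- build_metabolic_edges(c("A", "B", "C"), tab)
  expect_equal(nrow(net), 1)
  expect_equal(net$taxid_a, "A")
  expect_equal(net$taxid_b, "B")
  expect_equal(net$annotation, "butyrate")

  # all four species share one compound -> C(4,2) = 6 edges
  tab2 <- metabolic_table(stats::setNames(rep(list("x"), 4), c("A", "B", "C", "D")))
  expect_equal(nrow(build_metabolic_edges(c("A", "B", "C", "D"), tab2)), 6)

  expect_equal(nrow(build_metabolic_edges(c("A", "B"), metabolic_table())), 0)
  expect_error(build_metabolic_edges(c("A", "A"), tab), "deduplicated")
})

test_that("phylogenetic edges: shared non-missing genus only", {
  tax <- taxonomy_table(c("X", "Y", "Z", "W", "V"), paste0("n", 1:5),
                        c("Bacteroides", "Bacteroides", "Pseudomonas",
                          "Pseudomonas", "Pseudomonas"))
  net <- build_phylogenetic_edges(c("X", "Y", "Z", "W", "V"), tax)
  expect_equal(nrow(net), 1 + 3)

  tax2 <- taxonomy_table(c("X", "Y", "Z"), paste0("n", 1:3),
                         c("Ga", "Gb", "Gc"))
  expect_equal(nrow(build_phylogenetic_edges(c("X", "Y", "Z"), tax2)), 0)

  # missing genus never matches, not even another missing genus
  tax3 <- taxonomy_table(c("X", "Y"), c("n1", "n2"), c(NA, NA))
  expect_equal(nrow(build_phylogenetic_edges(c("X", "Y"), tax3)), 0)
})

test_that("edge builders match the O(n^2) brute-force oracles on random inputs", {
  set.seed(402)
  for (rep in 1:100) {
    n <- sample(2:8, 1)
    species <- as.character(sample(1:500, n))
    compounds <- paste0("c", 1:5)
    sets <- lapply(seq_len(n), function(i)
      sample(compounds, sample(0:3, 1)))
    names(sets) <- species
    net <- build_metabolic_edges(species, metabolic_table(sets))
    got <- sort(paste(net$taxid_a, net$taxid_b, net$annotation))
    expect_identical(got, oracle_met_edges(species, sets))

    genus <- sample(c(paste0("g", 1:3), NA), n, replace = TRUE)
    names(genus) <- species
    tax <- taxonomy_table(species, paste0("name", seq_len(n)), genus)
    netp <- build_phylogenetic_edges(species, tax)
    gotp <- sort(paste(netp$taxid_a, netp$taxid_b, netp$annotation))
    expect_identical(gotp, oracle_phy_edges(species, genus))
  }
})

test_that("relation networks are canonical, symmetric-free and validated", {
  expect_error(relation_network(data.frame(
    taxid_a = "A", taxid_b = "A", relation_type = "metabolic",
    annotation = "x"), species = "A"), "self-loop")
  expect_error(relation_network(data.frame(
    taxid_a = "A", taxid_b = "B", relation_type = "metabolic",
    annotation = "x"), species = "A"), "outside species universe")
  # endpoints are stored in ascending (numeric-aware) order
  net <- relation_network(data.frame(
    taxid_a = "110", taxid_b = "12", relation_type = "phylogenetic",
    annotation = "g"), species = c("12", "110"))
  expect_equal(net$taxid_a, "12")
  expect_error(relation_network(data.frame(
    taxid_a = c("A", "B"), taxid_b = c("B", "A"),
    relation_type = "metabolic", annotation = "x"),
    species = c("A", "B")), "duplicate")
  # round trip through TSV
  p <- tempfile()
  write_relation_network(net, p)
  expect_equal(as.data.frame(read_relation_network(p, c("12", "110"))),
               as.data.frame(net))
})
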