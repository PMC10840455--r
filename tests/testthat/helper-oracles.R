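# Independent brute-force oracles, deliberately written with plain loops and
# kept free of any package internals, used to cross-check the implementation.

oracle_filter <- function(counts, fraction) {
  totals <- apply(counts, 1, sum)
  grand <- sum(counts)
  keep <- logical(nrow(counts))
  for (i in seq_len(nrow(counts))) keep[i] <- !(totals[i] < fraction * grand)
  rownames(counts)[keep]
}

# O(n^2) pairwise set intersection: one (pair, compound) edge per shared
# compound, pair stored in canonical (numeric-aware ascending) order.
oracle_met_edges <- function(species, sets) {
  out <- character(0)
  for (i in seq_along(species)) for (j in seq_along(species)) {
    if (i >= j) next
    shared <- intersect(sets[[species[i]]], sets[[species[j]]])
    for (cmp in shared) {
      pair <- sort_ids(c(species[i], species[j]))
      out <- c(out, paste(pair[1], pair[2], cmp))
    }
  }
  sort(out)
}

oracle_phy_edges <- function(species, genus) {
  out <- character(0)
  for (i in seq_along(species)) for (j in seq_along(species)) {
    if (i >= j) next
    gi <- genus[species[i]]; gj <- genus[species[j]]
    if (!is.na(gi) && !is.na(gj) && gi == gj) {
      pair <- sort_ids(c(species[i], species[j]))
      out <- c(out, paste(pair[1], pair[2], gi))
    }
  }
  sort(out)
}

sort_ids <- function(x) {
  if (all(grepl("^[0-9]+$", x))) x[order(as.numeric(x))] else sort(x)
}

# Confusion-matrix metrics by direct counting loops.
oracle_metrics <- function(pred, truth, classes) {
  n <- length(truth)
  acc <- 0
  for (i in seq_len(n)) if (pred[i] == truth[i]) acc <- acc + 1
  acc <- acc / n
  prec <- rec <- f1 <- numeric(length(classes))
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    tp <- fp <- fn <- 0
    for (i in seq_len(n)) {
      if (pred[i] == cl && truth[i] == cl) tp <- tp + 1
      if (pred[i] == cl && truth[i] != cl) fp <- fp + 1
      if (pred[i] != cl && truth[i] == cl) fn <- fn + 1
    }
    prec[ci] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[ci] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[ci] <- if (prec[ci] + rec[ci] > 0)
      2 * prec[ci] * rec[ci] / (prec[ci] + rec[ci]) else 0
  }
  list(accuracy = acc, macro_precision = mean(prec),
       macro_recall = mean(rec), macro_f1 = mean(f1))
}

# Exact upper-tail hypergeometric probability from the closed combinatorial
# form: P(X >= k) = sum_j C(K, j) C(N-K, n-j) / C(N, n).
oracle_hyper <- function(N, K, n, k) {
  js <- max(k, 0):min(n, K)
  if (!length(js) || k > min(n, K)) return(if (k <= 0) 1 else 0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Exhaustive enumeration over all C(N, n) draws (tiny N only).
oracle_hyper_enum <- function(N, K, n, k) {
  if (n == 0) return(if (k <= 0) 1 else 0)
  draws <- utils::combn(N, n)
  inside <- colSums(draws <= K)  # samples 1..K are "in the type"
  mean(inside >= k)
}
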