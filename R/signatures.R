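# From attention scores to cancer-type-specific microbial signatures:
# high-attention thresholding against the uniform-attention baseline, one-sided
# hypergeometric enrichment of high-attention samples within each cancer type,
# and selection at P < 0.05 with within-type max-rescaled attention weights.

#' Call high-attention (species, sample) cells
#'
#' Under the default `"uniform_multiple"` rule, species `s` is high-attention
#' in sample `t` when its attention strictly exceeds `thres` times the uniform
#' baseline `1 / deg(t)`, where `deg(t)` is the number of species incident to
#' the sample; the rule is scale-free across samples of different richness.
#' Alternative rules: `"quantile"` (above the global `quantile_p` quantile of
#' supported scores) and `"mean_sd"` (above the per-sample mean + `thres`
#' standard deviations among incident species).
#'
#' @param att an [attention_matrix()].
#' @param thres positive multiple of the uniform baseline (default 3).
#' @param rule thresholding rule; see above.
#' @param quantile_p global quantile for `rule = "quantile"` (default 0.95).
#' @return integer 0/1 species x samples matrix (class `high_attention_mask`).
#' @export
call_high_attention <- function(att, thres = 3,
                                rule = c("uniform_multiple", "quantile", "mean_sd"),
                                quantile_p = 0.95) {
  rule <- match.arg(rule)
  if (!inherits(att, "attention_matrix")) stop("att must be an attention_matrix")
  if (thres <= 0) stop("thres must be positive")
  S <- att$scores
  sup <- att$support
  mask <- matrix(0L, nrow(S), ncol(S), dimnames = dimnames(S))
  if (rule == "uniform_multiple") {
    deg <- colSums(sup)
    cutoff <- ifelse(deg > 0, thres / deg, Inf)
    mask[sup & sweep(S, 2, cutoff, ">")] <- 1L
  } else if (rule == "quantile") {
    if (!any(sup)) return(structure(mask, class = c("high_attention_mask", "matrix")))
    q <- stats::quantile(S[sup], quantile_p, names = FALSE)
    mask[sup & S > q] <- 1L
  } else {
    for (j in seq_len(ncol(S))) {
      v <- S[sup[, j], j]
      if (length(v) < 2) next
      cut <- mean(v) + thres * stats::sd(v)
      mask[sup[, j] & S[, j] > cut, j] <- 1L
    }
  }
  structure(mask, class = c("high_attention_mask", "matrix"))
}

#' Hypergeometric enrichment of high-attention samples within cancer types
#'
#' For each species with at least one high-attention sample and each cancer
#' type, tests whether the species' high-attention samples concentrate in the
#' type: with `N` samples overall, `K` of the type, `n` high-attention for the
#' species and `k` of those inside the type, the one-sided upper-tail p-value
#' is `P(X >= k)` for `X ~ Hypergeometric(N, K, n)` (Fisher exact upper tail).
#' Species with `n = 0` are skipped.
#'
#' @param mask a [call_high_attention()] mask (samples in columns).
#' @param meta a [sample_metadata()] over exactly the mask's samples.
#' @return an `enrichment_result` data frame with columns `cancer_type`,
#'   `taxid`, `k`, `n`, `K`, `N`, `p_value`.
#' @export
enrichment_test <- function(mask, meta) {
  samples <- colnames(mask)
  if (is.null(samples) || !setequal(samples, meta$sample_id) ||
      length(samples) != nrow(meta))
    stop("mask and metadata sample sets differ")
  lab <- meta$label[match(samples, meta$sample_id)]
  types <- label_set(meta)
  N <- length(samples)
  n_sp <- rowSums(mask)
  keep <- which(n_sp > 0)
  rows <- vector("list", length(keep) * length(types))
  ri <- 0L
  for (si in keep) {
    n <- n_sp[si]
    for (ty in types) {
      inside <- lab == ty
      K <- sum(inside)
      k <- sum(mask[si, inside] > 0)
      p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(cancer_type = ty, taxid = rownames(mask)[si],
                               k = k, n = n, K = K, N = N, p_value = p,
                               stringsAsFactors = FALSE)
    }
  }
  out <- if (ri) do.call(rbind, rows[seq_len(ri)]) else
    data.frame(cancer_type = character(0), taxid = character(0),
               k = integer(0), n = integer(0), K = integer(0), N = integer(0),
               p_value = numeric(0), stringsAsFactors = FALSE)
  structure(out, class = c("enrichment_result", "data.frame"))
}

#' Select significant microbial signatures
#'
#' Keeps (cancer type, species) pairs with (optionally BH-adjusted) p-value
#' strictly below `alpha`. The reported `normalized_attention` is the species'
#' mean attention over the samples of the cancer type, rescaled within each
#' type by the maximum among that type's selected species (so each nonempty
#' type has a top species at 1.0).
#'
#' @param results an [enrichment_test()] result.
#' @param att the [attention_matrix()] the mask was derived from.
#' @param meta the [sample_metadata()].
#' @param alpha significance level (default 0.05, matching raw `P < 0.05`).
#' @param correction `"none"` (default) or `"bh"` (Benjamini-Hochberg over all
#'   tested pairs).
#' @param taxonomy optional [taxonomy_table()] for display names; species
#'   absent from it are named by taxid.
#' @return a [signature_table()].
#' @export
select_signatures <- function(results, att, meta, alpha = 0.05,
                              correction = c("none", "bh"), taxonomy = NULL) {
  correction <- match.arg(correction)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  p <- results$p_value
  if (correction == "bh") p <- stats::p.adjust(p, method = "BH")
  sel <- results[which(p < alpha), , drop = FALSE]
  if (!nrow(sel)) return(signature_table())
  lab <- meta$label[match(colnames(att$scores), meta$sample_id)]
  mean_att <- vapply(seq_len(nrow(sel)), function(i) {
    cols <- which(lab == sel$cancer_type[i])
    mean(att$scores[sel$taxid[i], cols])
  }, numeric(1))
  type_max <- tapply(mean_att, sel$cancer_type, max)
  norm_att <- mean_att / as.numeric(type_max[sel$cancer_type])
  nm <- if (!is.null(taxonomy)) taxonomy$name[match(sel$taxid, taxonomy$taxid)]
        else rep(NA_character_, nrow(sel))
  nm[is.na(nm)] <- sel$taxid[is.na(nm)]
  signature_table(data.frame(
    cancer_type = sel$cancer_type, taxid = sel$taxid, species_name = nm,
    n_high_attention_samples = sel$k,
    p_value = sel$p_value, normalized_attention = norm_att,
    stringsAsFactors = FALSE))
}
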