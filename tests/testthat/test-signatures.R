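# High-attention calling, hypergeometric enrichment, signature selection.

mk_att <- function(scores, support = scores > 0) {
  attention_matrix(scores, support)
}

test_that("high-attention rule: strict multiple of the uniform baseline", {
  # one sample with 10 incident species, thres = 3 -> cutoff 0.3
  s <- matrix(0.35 / 8, 10, 1, dimnames = list(paste0("sp", 1:10), "s1"))
  s[1, 1] <- 0.35; s[2, 1] <- 0.30
  sup <- matrix(TRUE, 10, 1, dimnames = dimnames(s))
  m <- call_high_attention(mk_att(s, sup), thres = 3)
  expect_equal(unname(m[1, 1]), 1L)   # 0.35 > 0.3
  expect_equal(unname(m[2, 1]), 0L)   # 0.30 is not strictly greater

  # uniform attention is never high for thres > 1
  u <- matrix(1 / 10, 10, 1, dimnames = dimnames(s))
  expect_equal(sum(call_high_attention(mk_att(u, sup), 3)), 0)

  # singleton sample: attention 1.0 against cutoff 3.0
  s1 <- matrix(1, 1, 1, dimnames = list("sp1", "s1"))
  expect_equal(sum(call_high_attention(mk_att(s1), 3)), 0)

  # degree-zero sample contributes nothing
  z <- matrix(0, 2, 1, dimnames = list(c("a", "b"), "s1"))
  expect_equal(sum(call_high_attention(mk_att(z, z > 0), 3)), 0)
  expect_error(call_high_attention(mk_att(s1), thres = 0), "positive")
})

test_that("enrichment p-values match the worked examples", {
  # N=10, K=4, n=3, k=3 -> C(4,3)/C(10,3) = 4/120
  mask <- matrix(0L, 1, 10, dimnames = list("sp1", paste0("s", 1:10)))
  mask[1, 1:3] <- 1L
  meta <- sample_metadata(paste0("s", 1:10), rep(c("A", "B"), c(4, 6)))
  enr <- enrichment_test(mask, meta)
  expect_equal(enr$p_value[enr$cancer_type == "A"], 4 / 120, tolerance = 1e-12)
  # k = 0 is the certain event
  mask2 <- mask; mask2[1, ] <- 0L; mask2[1, 5:7] <- 1L
  enr2 <- enrichment_test(mask2, meta)
  expect_equal(enr2$p_value[enr2$cancer_type == "A"], 1, tolerance = 1e-12)
  expect_equal(enr2$k[enr2$cancer_type == "A"], 0)
  # species high everywhere: k = K deterministically, p = 1
  mask3 <- mask; mask3[1, ] <- 1L
  enr3 <- enrichment_test(mask3, meta)
  expect_equal(enr3$p_value, c(1, 1))
  # species with n = 0 are skipped entirely
  mask4 <- mask; mask4[1, ] <- 0L
  expect_equal(nrow(enrichment_test(mask4, meta)), 0)
  expect_error(enrichment_test(mask, sample_metadata("s1", "A")), "differ")
})

test_that("enrichment matches exhaustive draw enumeration for all N <= 12", {
  set.seed(70)
  for (rep in 1:60) {
    N <- sample(2:12, 1)
    K <- sample(1:(N - 1), 1)
    n <- sample(1:N, 1)
    mask <- matrix(0L, 1, N, dimnames = list("sp", paste0("s", 1:N)))
    mask[1, sample(N, n)] <- 1L
    meta <- sample_metadata(paste0("s", 1:N), rep(c("T", "O"), c(K, N - K)))
    enr <- enrichment_test(mask, meta)
    k <- enr$k[enr$cancer_type == "T"]
    expect_equal(enr$p_value[enr$cancer_type == "T"],
                 oracle_hyper_enum(N, K, n, k), tolerance = 1e-12)
  }
})

test_that("signature selection thresholds, rescales and orders correctly", {
  sc <- matrix(c(0.6, 0.2, 0.1,
                 0.4, 0.5, 0.3), nrow = 2, byrow = TRUE,
               dimnames = list(c("101", "102"), c("s1", "s2", "s3")))
  att <- mk_att(sc, matrix(TRUE, 2, 3, dimnames = dimnames(sc)))
  meta <- sample_metadata(c("s1", "s2", "s3"), c("A", "A", "B"))
  res <- data.frame(cancer_type = c("A", "A"), taxid = c("101", "102"),
                    k = c(2L, 2L), n = c(2L, 3L), K = 2L, N = 3L,
                    p_value = c(0.03, 0.06), stringsAsFactors = FALSE)
  sig <- select_signatures(res, att, meta, alpha = 0.05)
  expect_equal(nrow(sig), 1)          # only p = 0.03 survives alpha 0.05
  expect_equal(sig$taxid, "101")
  expect_equal(sig$normalized_attention, 1)  # top species in its type

  # Benjamini-Hochberg with m = 2: (0.03, 0.04) -> both adjusted to 0.04
  res$p_value <- c(0.03, 0.04)
  sig_bh <- select_signatures(res, att, meta, alpha = 0.05, correction = "bh")
  expect_equal(nrow(sig_bh), 2)
  # rescaling: mean att of 101 over A = 0.4, of 102 over A = 0.45 -> max 0.45
  expect_equal(sig_bh$normalized_attention[sig_bh$taxid == "102"], 1)
  expect_equal(sig_bh$normalized_attention[sig_bh$taxid == "101"], 0.4 / 0.45)
  # names fall back to taxid without a taxonomy, adopt it when given
  expect_equal(sig_bh$species_name, sig_bh$taxid)
  tax <- taxonomy_table(c("101", "102"), c("Alpha one", "Beta two"),
                        c("Ga", "Gb"))
  sig_nm <- select_signatures(res, att, meta, correction = "bh", taxonomy = tax)
  expect_setequal(sig_nm$species_name, c("Alpha one", "Beta two"))
})

test_that("signature attention weights lie in [0,1] with a 1.0 per nonempty type", {
  fit <- fx_fit_full()
  ds <- fx_dataset()
  mask <- call_high_attention(fit$attention, 3)
  enr <- enrichment_test(mask, ds$metadata)
  sig <- select_signatures(enr, fit$attention, ds$metadata,
                           taxonomy = ds$taxonomy)
  expect_true(nrow(sig) > 0)
  expect_true(all(sig$normalized_attention >= 0 & sig$normalized_attention <= 1))
  tops <- tapply(sig$normalized_attention, sig$cancer_type, max)
  expect_true(all(abs(tops - 1) < 1e-12))
  # counts never exceed the type's sample size
  Ktab <- table(ds$metadata$label)
  expect_true(all(sig$n_high_attention_samples <=
                    as.numeric(Ktab[sig$cancer_type])))
})

test_that("label permutation calibration matches the attainable discrete level", {
  fit <- fx_fit_full()
  ds <- fx_dataset()
  mask <- call_high_attention(fit$attention, 3)
  meta <- ds$metadata
  N <- nrow(meta)
  Ktab <- table(meta$label)
  ns <- rowSums(mask)
  ns <- ns[ns > 0]
  # expected null fraction = mean attainable level P(p < 0.05) over tested
  # (species, type) pairs, exact under the permutation null
  exp_frac <- mean(unlist(lapply(ns, function(n) {
    vapply(as.numeric(Ktab), function(K) {
      ks <- 0:min(n, K)
      p_at_k <- phyper(ks - 1, K, N - K, n, lower.tail = FALSE)
      kstar <- ks[which(p_at_k < 0.05)[1]]
      if (is.na(kstar)) 0 else phyper(kstar - 1, K, N - K, n, lower.tail = FALSE)
    }, numeric(1))
  })))
  set.seed(77)
  obs <- replicate(200, {
    perm <- sample_metadata(meta$sample_id, sample(meta$label))
    enr <- enrichment_test(mask, perm)
    mean(enr$p_value < 0.05)
  })
  se <- sd(obs) / sqrt(length(obs))
  expect_lt(abs(mean(obs) - exp_frac), max(4 * se, 0.005))
})
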