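# Graph transformer internals: attention structure, gradients, focal loss,
# scheduler, metrics, determinism.

rand_emb <- function(graph, d, seed) {
  set.seed(seed)
  list(species = matrix(rnorm(length(graph$species) * d),
                        length(graph$species), d),
       samples = matrix(rnorm(length(graph$samples) * d),
                        length(graph$samples), d),
       d_embed = d)
}

test_that("analytic gradients match central finite differences", {
  tiny <- fx_tiny_graph()
  g <- tiny$graph
  cfg <- train_config(n_heads = 2, n_hid = 8, n_layers = 2, kl_coef = 1e-3,
                      use_edge_weights = TRUE, seed = 9)
  emb <- rand_emb(g, 6, 42)
  edges <- microsig:::hgt_edges(g)
  X0 <- list(species = emb$species, sample = emb$samples)
  set.seed(1)
  params <- hgt_init_params(g, 6, cfg)
  y <- as.integer(g$labels)
  loss_fn <- function(p) {
    fw <- microsig:::hgt_forward_impl(p, edges, X0, cfg)
    logits <- sweep(fw$X$sample %*% p$Wc, 2, p$bc, "+")
    P <- microsig:::softmax_rows(logits)
    focal_loss(P, y, cfg$focal_gamma, cfg$focal_alpha) +
      cfg$kl_coef * microsig:::hgt_kl(fw, edges, cfg)
  }
  fw <- microsig:::hgt_forward_impl(params, edges, X0, cfg)
  logits <- sweep(fw$X$sample %*% params$Wc, 2, params$bc, "+")
  P <- microsig:::softmax_rows(logits)
  dlog <- microsig:::focal_logit_grad(P, y, cfg$focal_gamma, cfg$focal_alpha,
                                      seq_along(y))
  gr <- microsig:::hgt_backward_impl(
    params, edges, X0, cfg, fw,
    list(species = matrix(0, nrow(X0$species), cfg$n_hid),
         sample = dlog %*% t(params$Wc)))
  gr$Wc <- t(fw$X$sample) %*% dlog
  gr$bc <- colSums(dlog)

  bump <- function(p, path, idx, delta) {
    rec <- function(p, path) {
      k <- path[[1]]
      if (length(path) == 1) {
        x <- p[[k]]; x[matrix(idx, nrow = 1)] <- x[matrix(idx, nrow = 1)] + delta
        p[[k]] <- x
      } else p[[k]] <- rec(p[[k]], path[-1])
      p
    }
    rec(p, path)
  }
  getp <- function(p, path) { for (k in path) p <- p[[k]]; p }
  checks <- list(
    list(list("W_in", "species"), c(2, 3)),
    list(list("layers", 1L, "K", "species"), c(1, 5)),
    list(list("layers", 1L, "Q", "sample"), c(2, 2)),
    list(list("layers", 2L, "V", "species"), c(3, 7)),
    list(list("layers", 1L, "O", "sample"), c(8, 1)),
    list(list("layers", 1L, "Watt", "sp2sa"), c(2, 3, 1)),
    list(list("layers", 1L, "Wmsg", "met"), c(1, 4, 2)),
    list(list("layers", 1L, "mu", "sa2sp"), 1),
    list(list("layers", 2L, "beta", "sp2sa"), 1),
    list(list("Wc"), c(3, 2)))
  eps <- 1e-6
  for (ch in checks) {
    num <- (loss_fn(bump(params, ch[[1]], ch[[2]], eps)) -
              loss_fn(bump(params, ch[[1]], ch[[2]], -eps))) / (2 * eps)
    ana <- getp(gr, ch[[1]])[matrix(ch[[2]], nrow = 1)]
    expect_lt(abs(num - ana) / max(abs(num), abs(ana), 1e-8), 1e-4)
  }
})

test_that("a sample with a single incident species receives attention 1 in every head", {
  norm <- normalize_samples(abundance_matrix(matrix(
    c(3, 0,
      0, 2,
      0, 5), nrow = 3, byrow = TRUE,
    dimnames = list(c("1", "2", "3"), c("s1", "s2")))))
  g <- assemble_graph(norm, NULL, NULL,
                      sample_metadata(c("s1", "s2"), c("A", "B")))
  emb <- rand_emb(g, 8, 2)
  out <- hgt_attention_layer(g, emb, config = train_config(n_heads = 4,
                                                           n_hid = 16, seed = 1))
  a <- out$attention$sp2sa
  s1_edges <- which(a$tgt == 1)     # sample s1 has only species 1 incident
  expect_length(s1_edges, 1)
  expect_equal(unname(a$att[s1_edges, ]), rep(1, 4))
})

test_that("identical source embeddings yield uniform attention without the weight bias", {
  norm <- normalize_samples(abundance_matrix(matrix(
    c(1, 2, 4, 8), nrow = 4,
    dimnames = list(as.character(1:4), "s1"))))
  g <- assemble_graph(norm, NULL, NULL, sample_metadata("s1", "A"))
  set.seed(3)
  one <- rnorm(8)
  emb <- list(species = matrix(rep(one, each = 4), 4, 8),
              samples = matrix(rnorm(8), 1, 8), d_embed = 8)
  out <- hgt_attention_layer(g, emb,
                             config = train_config(n_heads = 2, n_hid = 8,
                                                   use_edge_weights = FALSE,
                                                   seed = 4))
  expect_equal(unname(out$attention$sp2sa$att),
               matrix(0.25, 4, 2), tolerance = 1e-12)
})

test_that("focal loss reduces to cross-entropy at gamma 0 and matches hand values", {
  # single sample, p_true = 0.5, gamma = 2, alpha = 1 -> 0.25 * ln 2
  expect_equal(focal_loss(matrix(c(0.5, 0.5), 1), 1, gamma = 2, alpha = 1),
               0.25 * log(2), tolerance = 1e-12)
  # perfectly confident predictions give zero loss
  P <- diag(3)[c(1, 2, 3), ]
  expect_equal(focal_loss(P, 1:3, gamma = 2), 0)
  # gamma = 0, alpha = 1 equals mean cross-entropy
  set.seed(50)
  P <- matrix(rgamma(300, 1), 100, 3); P <- P / rowSums(P)
  y <- sample(3, 100, replace = TRUE)
  ce <- -mean(log(P[cbind(1:100, y)]))
  expect_equal(focal_loss(P, y, gamma = 0, alpha = 1), ce, tolerance = 1e-12)
  # focal loss never exceeds cross-entropy for gamma > 0, alpha = 1
  expect_lte(focal_loss(P, y, gamma = 2), ce)
  # zero probability is clamped with a warning
  expect_warning(focal_loss(matrix(c(0, 1), 1), 1, gamma = 0), "clamped")
  expect_error(focal_loss(matrix(c(0.7, 0.2), 1), 1), "sum to 1")
})

test_that("plateau scheduler halves the rate after the configured stagnation", {
  # frozen metric: first epoch sets the best, decay after each 5 stagnant epochs
  lr <- reduce_lr_on_plateau(rep(0.5, 12), lr0 = 0.003)
  expect_equal(lr[1:6], rep(0.003, 6))
  expect_identical(lr[7], 0.003 * 0.5)
  expect_identical(lr[12], 0.003 * 0.25)
  # an improving metric keeps the rate untouched
  expect_equal(reduce_lr_on_plateau(seq(0.1, 1, length.out = 10), 0.003),
               rep(0.003, 10))
  # improvement resets the stagnation counter
  m <- c(0.5, 0.4, 0.4, 0.4, 0.6, 0.4, 0.4, 0.4, 0.4, 0.4)
  expect_equal(reduce_lr_on_plateau(m, 1, patience = 5),
               c(rep(1, 10))[1:10] * c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1))
  m2 <- c(0.5, rep(0.4, 5), rep(0.4, 5))
  expect_equal(unique(reduce_lr_on_plateau(m2, 1, patience = 5)), c(1, 0.5))
})

test_that("classification metrics follow the one-vs-rest confusion definitions", {
  # perfect prediction
  r <- evaluate_classification(c("a", "b"), c("a", "b"), c("a", "b"))
  expect_equal(r$accuracy, 1); expect_equal(r$macro_f1, 1)
  # hand-computed: per class TP=(2,1,1), FP=(1,0,1), FN=(0,1,1), n=6
  pred <- c("x", "x", "x", "y", "z", "z")
  truth <- c("x", "x", "y", "y", "y", "z")
  r <- evaluate_classification(pred, truth, c("x", "y", "z"))
  expect_equal(r$per_class$TP, c(2, 1, 1))
  expect_equal(r$per_class$FP, c(1, 0, 1))
  expect_equal(r$per_class$FN, c(0, 2, 0))
  expect_equal(r$accuracy, 4 / 6)
  expect_equal(r$macro_precision, (2 / 3 + 1 + 1 / 2) / 3)
  # TP+FP+TN+FN = n in every class
  expect_true(all(rowSums(r$per_class[, c("TP", "FP", "TN", "FN")]) == 6))
  # constant predictor on balanced 2-class truth
  r2 <- evaluate_classification(rep("a", 4), c("a", "a", "b", "b"), c("a", "b"))
  expect_equal(r2$accuracy, 0.5)
  expect_equal(r2$macro_recall, 0.5)
  expect_equal(r2$zero_denominator, "b")   # precision denominator 0 for b
  expect_error(evaluate_classification("c", "a", c("a", "b")), "outside")
})

test_that("metrics agree with the brute-force oracle on random label vectors", {
  set.seed(60)
  for (rep in 1:100) {
    k <- sample(2:5, 1); n <- sample(3:30, 1)
    classes <- paste0("c", 1:k)
    truth <- sample(classes, n, replace = TRUE)
    pred <- sample(classes, n, replace = TRUE)
    got <- evaluate_classification(pred, truth, classes)
    want <- oracle_metrics(pred, truth, classes)
    expect_equal(got$accuracy, want$accuracy)
    expect_equal(got$macro_precision, want$macro_precision)
    expect_equal(got$macro_recall, want$macro_recall)
    expect_equal(got$macro_f1, want$macro_f1)
  }
})

test_that("training is deterministic given the seed and rejects degenerate graphs", {
  tiny <- fx_tiny_graph()
  cfg <- train_config(n_heads = 2, n_hid = 8, n_layers = 1, epochs = 5,
                      split_fraction = 1, seed = 11)
  emb <- rand_emb(tiny$graph, 6, 8)
  f1 <- fit_hgt(tiny$graph, cfg, embeddings = emb)
  f2 <- fit_hgt(tiny$graph, cfg, embeddings = emb)
  expect_identical(f1$history$loss, f2$history$loss)
  expect_identical(f1$attention$scores, f2$attention$scores)

  ds1 <- generate_dataset(synthetic_spec(n_types = 1, samples_per_type = 4,
                                         n_species = 5, markers_per_type = 1,
                                         seed = 2))
  g1 <- assemble_graph(normalize_samples(ds1$abundance), NULL, NULL,
                       ds1$metadata)
  expect_error(fit_hgt(g1, cfg), "two label classes")
})

test_that("the fitted-model interface exposes predictions, coefficients and history", {
  fit <- fx_fit_split()
  pr <- predict(fit, type = "prob")
  expect_equal(dim(pr), c(60, 3))
  expect_equal(unname(rowSums(pr)), rep(1, 60), tolerance = 1e-9)
  cl <- predict(fit, which = "val")
  expect_length(cl, length(fit$split$val))
  expect_true(all(as.character(cl) %in% levels(fit$labels)))
  expect_equal(dim(coef(fit)), c(fit$config$n_hid, 3))
  expect_equal(nrow(fit$history), fit$config$epochs)
  expect_output(print(fit), "hgt_fit")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
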