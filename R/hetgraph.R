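# Heterogeneous graph assembly (species + sample nodes; abundance, metabolic
# and phylogenetic edges) and 256-dimensional initial node embeddings produced
# by two seedable autoencoders (one over species feature rows, one over sample
# feature columns).

# ---- generic Adam over nested parameter lists --------------------------------

zeros_like <- function(p) {
  if (is.list(p)) lapply(p, zeros_like)
  else if (is.array(p)) array(0, dim(p)) else numeric(length(p)) * 0
}

adam_new <- function(params) list(m = zeros_like(params), v = zeros_like(params), t = 0L)

adam_walk <- function(p, g, m, v, lr, b1, b2, eps, t) {
  if (is.list(p)) {
    out_p <- p; out_m <- m; out_v <- v
    for (nm in seq_along(p)) {
      r <- adam_walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]], lr, b1, b2, eps, t)
      out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
    }
    list(p = out_p, m = out_m, v = out_v)
  } else {
    m2 <- b1 * m + (1 - b1) * g
    v2 <- b2 * v + (1 - b2) * g * g
    mh <- m2 / (1 - b1^t)
    vh <- v2 / (1 - b2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m2, v = v2)
  }
}

adam_step <- function(state, params, grads, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  t <- state$t + 1L
  r <- adam_walk(params, grads, state$m, state$v, lr, beta1, beta2, eps, t)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}

xavier <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / (nin + nout))), nin, nout)
}

# ---- graph assembly ----------------------------------------------------------

#' Assemble the heterogeneous species-sample graph
#'
#' Node sets are the species and samples of the normalized abundance matrix.
#' Abundance edges connect a species to a sample iff its normalized value is
#' > 0 (weight = the value); metabolic edges collapse multi-compound pairs to a
#' single structural edge weighted by the number of shared compounds;
#' phylogenetic edges have weight 1. Relation edges touching species absent
#' from the matrix are dropped. Every sample must carry a cancer-type label.
#'
#' @param matrix a normalized [abundance_matrix()].
#' @param metabolic a metabolic [relation_network()] or `NULL`.
#' @param phylo a phylogenetic [relation_network()] or `NULL`.
#' @param meta a [sample_metadata()] covering every sample of the matrix.
#' @return a `hetero_graph` list: `species`, `samples`, `A` (normalized
#'   matrix), `labels` (factor over the metadata label set), `met` and `phy`
#'   structural edge data frames (`taxid_a`, `taxid_b`, `weight`).
#' @export
assemble_graph <- function(matrix, metabolic = NULL, phylo = NULL, meta) {
  if (!inherits(matrix, "abundance_matrix") || !is_normalized(matrix))
    stop("assemble_graph expects a normalized abundance_matrix")
  species <- rownames(matrix)
  samples <- colnames(matrix)
  missing <- setdiff(samples, meta$sample_id)
  if (length(missing))
    stop("sample(s) missing from metadata: ", paste(missing, collapse = ", "))
  labels <- factor(meta$label[match(samples, meta$sample_id)],
                   levels = label_set(meta))

  collapse <- function(net, weighted) {
    if (is.null(net) || nrow(net) == 0)
      return(data.frame(taxid_a = character(0), taxid_b = character(0),
                        weight = numeric(0), stringsAsFactors = FALSE))
    df <- as.data.frame(net)
    df <- df[df$taxid_a %in% species & df$taxid_b %in% species, , drop = FALSE]
    if (!nrow(df)) return(data.frame(taxid_a = character(0), taxid_b = character(0),
                                     weight = numeric(0), stringsAsFactors = FALSE))
    key <- paste(df$taxid_a, df$taxid_b, sep = "\r")
    cnt <- table(key)
    uk <- names(cnt)
    parts <- strsplit(uk, "\r", fixed = TRUE)
    out <- data.frame(taxid_a = vapply(parts, `[`, "", 1),
                      taxid_b = vapply(parts, `[`, "", 2),
                      weight = if (weighted) as.numeric(cnt) else rep(1, length(cnt)),
                      stringsAsFactors = FALSE)
    out[order(id_rank(out$taxid_a), id_rank(out$taxid_b)), , drop = FALSE]
  }

  structure(list(species = species, samples = samples,
                 A = unclass(matrix)[, , drop = FALSE],
                 labels = labels,
                 met = collapse(metabolic, weighted = TRUE),
                 phy = collapse(phylo, weighted = FALSE)),
            class = "hetero_graph")
}

#' @export
print.hetero_graph <- function(x, ...) {
  cat(sprintf("hetero_graph: %d species + %d samples\n",
              length(x$species), length(x$samples)))
  cat(sprintf("  abundance edges: %d | metabolic: %d | phylogenetic: %d\n",
              sum(x$A > 0), nrow(x$met), nrow(x$phy)))
  cat("  labels:", paste(levels(x$labels), collapse = ", "), "\n")
  invisible(x)
}

# ---- autoencoder -------------------------------------------------------------

#' Autoencoder configuration
#'
#' Symmetric two-layer encoder/decoder
#' (`feature_dim -> n_hid -> d_embed -> n_hid -> feature_dim`) with
#' mean-squared-error reconstruction loss, trained full-batch with Adam.
#'
#' @param d_embed embedding (code) dimension; default 256.
#' @param n_hid hidden width of the encoder/decoder.
#' @param epochs training epochs.
#' @param learning_rate Adam learning rate.
#' @param activation `"tanh"` (default) or `"linear"`.
#' @param seed RNG seed for the weight initialization.
#' @return an `ae_config` list.
#' @export
ae_config <- function(d_embed = 256, n_hid = 64, epochs = 100,
                      learning_rate = 0.01, activation = c("tanh", "linear"),
                      seed = 1) {
  activation <- match.arg(activation)
  if (d_embed < 1) stop("d_embed must be >= 1")
  if (n_hid < 1 || epochs < 1 || learning_rate <= 0) stop("invalid ae_config")
  structure(list(d_embed = as.integer(d_embed), n_hid = as.integer(n_hid),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 activation = activation, seed = as.integer(seed)),
            class = "ae_config")
}

#' Train an autoencoder and return the encoder outputs
#'
#' @param features numeric matrix (nodes x features), all finite.
#' @param cfg an [ae_config()].
#' @return a list of class `ae_fit`: `embeddings` (nodes x `d_embed`, row names
#'   preserved), `history` (per-epoch mean-squared reconstruction error),
#'   `config`.
#' @export
train_autoencoder <- function(features, cfg = ae_config()) {
  if (!is.matrix(features)) features <- as.matrix(features)
  if (!is.numeric(features) || any(!is.finite(features)))
    stop("features must be a finite numeric matrix")
  if (nrow(features) < 1 || ncol(features) < 1)
    stop("need at least one node and one feature")
  f <- ncol(features)
  set.seed(cfg$seed)
  act <- if (cfg$activation == "tanh") tanh else identity
  dact <- if (cfg$activation == "tanh") function(a) 1 - a^2 else function(a) 1
  params <- list(W1 = xavier(f, cfg$n_hid), b1 = numeric(cfg$n_hid),
                 W2 = xavier(cfg$n_hid, cfg$d_embed), b2 = numeric(cfg$d_embed),
                 W3 = xavier(cfg$d_embed, cfg$n_hid), b3 = numeric(cfg$n_hid),
                 W4 = xavier(cfg$n_hid, f), b4 = numeric(f))
  opt <- adam_new(params)
  n <- nrow(features)
  loss <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    H1 <- act(sweep(features %*% params$W1, 2, params$b1, "+"))
    Z <- sweep(H1 %*% params$W2, 2, params$b2, "+")
    H2 <- act(sweep(Z %*% params$W3, 2, params$b3, "+"))
    Xh <- sweep(H2 %*% params$W4, 2, params$b4, "+")
    R <- Xh - features
    loss[ep] <- mean(R^2)
    dXh <- 2 * R / length(R)
    g <- list()
    g$W4 <- t(H2) %*% dXh; g$b4 <- colSums(dXh)
    dH2 <- (dXh %*% t(params$W4)) * dact(H2)
    g$W3 <- t(Z) %*% dH2; g$b3 <- colSums(dH2)
    dZ <- dH2 %*% t(params$W3)
    g$W2 <- t(H1) %*% dZ; g$b2 <- colSums(dZ)
    dH1 <- (dZ %*% t(params$W2)) * dact(H1)
    g$W1 <- t(features) %*% dH1; g$b1 <- colSums(dH1)
    g <- g[names(params)]
    st <- adam_step(opt, params, g, cfg$learning_rate)
    params <- st$params; opt <- st$state
  }
  H1 <- act(sweep(features %*% params$W1, 2, params$b1, "+"))
  Z <- sweep(H1 %*% params$W2, 2, params$b2, "+")
  rownames(Z) <- rownames(features)
  structure(list(embeddings = Z,
                 history = data.frame(epoch = seq_len(cfg$epochs), loss = loss),
                 config = cfg, params = params),
            class = "ae_fit")
}

#' Initial node embeddings for the heterogeneous graph
#'
#' Species embeddings come from an autoencoder trained on the species feature
#' rows of the normalized matrix; sample embeddings from a second autoencoder
#' trained on the sample feature columns. Both share `cfg$d_embed` (default
#' 256) so all nodes get a common embedding dimension.
#'
#' @param graph a [assemble_graph()] result.
#' @param cfg an [ae_config()]; the sample autoencoder is seeded with
#'   `cfg$seed + 1`.
#' @return an `embedding_set` list: `species` and `samples` matrices,
#'   `d_embed`, and the two training histories.
#' @export
initial_embeddings <- function(graph, cfg = ae_config()) {
  if (!inherits(graph, "hetero_graph")) stop("graph must come from assemble_graph()")
  sp_fit <- train_autoencoder(graph$A, cfg)
  sa_cfg <- cfg; sa_cfg$seed <- cfg$seed + 1L
  sa_fit <- train_autoencoder(t(graph$A), sa_cfg)
  structure(list(species = sp_fit$embeddings, samples = sa_fit$embeddings,
                 d_embed = cfg$d_embed,
                 history = list(species = sp_fit$history, samples = sa_fit$history)),
            class = "embedding_set")
}

#' @export
print.embedding_set <- function(x, ...) {
  cat(sprintf("embedding_set: %d species + %d samples, dimension %d\n",
              nrow(x$species), nrow(x$samples), x$d_embed))
  invisible(x)
}
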