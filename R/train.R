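# Focal-loss training of the graph transformer with Adam, stratified
# train/validation split, reduce-on-plateau learning-rate scheduling, and
# one-vs-rest macro-averaged evaluation metrics.

#' Multiclass focal loss
#'
#' Mean over samples of `-alpha * (1 - p_true)^gamma * log(p_true)`. With
#' `gamma = 0`, `alpha = 1` this is the ordinary mean cross-entropy.
#' Probabilities of exactly 0 for the true class are clamped at `1e-12` with a
#' warning.
#'
#' @param prob numeric matrix of per-sample class probabilities (rows sum
#'   to 1).
#' @param labels integer class indices (1-based) or a factor whose levels
#'   match the probability columns.
#' @param gamma focusing parameter (>= 0).
#' @param alpha weighting factor.
#' @return scalar loss.
#' @export
focal_loss <- function(prob, labels, gamma = 2, alpha = 1) {
  if (!is.matrix(prob)) prob <- matrix(prob, nrow = 1)
  if (is.factor(labels)) labels <- as.integer(labels)
  labels <- as.integer(labels)
  if (length(labels) != nrow(prob)) stop("labels/probabilities length mismatch")
  if (any(labels < 1 | labels > ncol(prob))) stop("label index out of range")
  if (any(prob < 0)) stop("negative probabilities")
  if (any(abs(rowSums(prob) - 1) > 1e-6)) stop("probability rows must sum to 1")
  if (gamma < 0) stop("gamma must be >= 0")
  p <- prob[cbind(seq_along(labels), labels)]
  if (any(p < 1e-12)) {
    warning("true-class probability of 0 clamped at 1e-12")
    p <- pmax(p, 1e-12)
  }
  mean(-alpha * (1 - p)^gamma * log(p))
}

# d loss / d logits for softmax probabilities P (only rows in `idx` carry loss).
focal_logit_grad <- function(P, labels, gamma, alpha, idx) {
  n <- length(idx)
  D <- matrix(0, nrow(P), ncol(P))
  p <- pmax(P[cbind(idx, labels[idx])], 1e-12)
  gp <- if (gamma == 0) -alpha / p else {
    q <- pmax(1 - p, 1e-12)
    -alpha * (-gamma * q^(gamma - 1) * log(p) + (1 - p)^gamma / p)
  }
  gp <- gp / n
  cvec <- gp * p
  D[idx, ] <- -P[idx, , drop = FALSE] * cvec
  D[cbind(idx, labels[idx])] <- D[cbind(idx, labels[idx])] + cvec
  D
}

#' Reduce-on-plateau learning-rate schedule
#'
#' Stateless helper replaying the schedule over a metric trace: whenever the
#' monitored metric fails to improve for `patience` consecutive epochs, the
#' learning rate is multiplied by `factor` (and the stagnation counter
#' resets). Returns the learning rate in force at each epoch.
#'
#' @param metrics per-epoch metric values (larger is better; pass the negated
#'   loss to monitor a loss).
#' @param lr0 initial learning rate.
#' @param factor multiplicative decay (default 0.5).
#' @param patience stagnant epochs tolerated before decaying (default 5).
#' @return numeric vector: learning rate used at each epoch.
#' @export
reduce_lr_on_plateau <- function(metrics, lr0, factor = 0.5, patience = 5) {
  lr <- lr0; best <- -Inf; wait <- 0L
  out <- numeric(length(metrics))
  for (i in seq_along(metrics)) {
    out[i] <- lr
    if (metrics[i] > best + 1e-12) {
      best <- metrics[i]; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) {
        lr <- lr * factor
        wait <- 0L
      }
    }
  }
  out
}

#' One-vs-rest classification metrics
#'
#' Per class: TP = samples of the class predicted as the class, FP = samples
#' of other classes predicted as the class, FN = samples of the class
#' predicted otherwise, TN = the rest. Precision, recall and F1 are
#' macro-averaged; a class with zero denominator contributes 0 and is flagged.
#'
#' @param predicted,truth equal-length label vectors (character or factor).
#' @param label_set the class universe; labels outside it are an error.
#' @return a `metrics_report` list: `accuracy`, `macro_precision`,
#'   `macro_recall`, `macro_f1`, `per_class` (TP/FP/TN/FN counts and
#'   per-class precision/recall/F1), `zero_denominator` (flagged classes).
#' @export
evaluate_classification <- function(predicted, truth,
                                    label_set = sort(unique(as.character(truth)))) {
  predicted <- as.character(predicted)
  truth <- as.character(truth)
  if (length(predicted) != length(truth)) stop("label vectors differ in length")
  bad <- setdiff(unique(c(predicted, truth)), label_set)
  if (length(bad)) stop("label(s) outside label_set: ", paste(bad, collapse = ", "))
  n <- length(truth)
  per <- lapply(label_set, function(cl) {
    tp <- sum(predicted == cl & truth == cl)
    fp <- sum(predicted == cl & truth != cl)
    fn <- sum(predicted != cl & truth == cl)
    tn <- n - tp - fp - fn
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
      2 * prec * rec / (prec + rec) else if (isTRUE(prec == 0) || isTRUE(rec == 0)) 0
    else NA_real_
    data.frame(class = cl, TP = tp, FP = fp, TN = tn, FN = fn,
               precision = prec, recall = rec, f1 = f1,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  zero_flag <- per$class[is.na(per$precision) | is.na(per$recall) | is.na(per$f1)]
  fill0 <- function(x) ifelse(is.na(x), 0, x)
  structure(list(accuracy = sum(per$TP) / n,
                 macro_precision = mean(fill0(per$precision)),
                 macro_recall = mean(fill0(per$recall)),
                 macro_f1 = mean(fill0(per$f1)),
                 per_class = per, n = n, zero_denominator = zero_flag),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f | macro precision %.4f | macro recall %.4f | macro F1 %.4f (n = %d)\n",
              x$accuracy, x$macro_precision, x$macro_recall, x$macro_f1, x$n))
  if (length(x$zero_denominator))
    cat("  zero-denominator class(es) counted as 0:",
        paste(x$zero_denominator, collapse = ", "), "\n")
  invisible(x)
}

stratified_split <- function(labels, fraction) {
  n <- length(labels)
  if (fraction >= 1) return(list(train = seq_len(n), val = integer(0)))
  train <- integer(0)
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    k <- max(1L, floor(fraction * length(idx)))
    if (k >= length(idx)) k <- length(idx) - 1L
    if (k < 1L) k <- 1L
    train <- c(train, sample(idx, min(k, length(idx))))
  }
  train <- sort(train)
  list(train = train, val = setdiff(seq_len(n), train))
}

#' Fit the heterogeneous graph transformer
#'
#' Trains the node-type/edge-type-aware multi-head attention model to classify
#' sample nodes by cancer type with focal loss plus a KL(attention || uniform)
#' regularizer, full-batch Adam, and reduce-on-plateau learning-rate decay
#' monitored on the validation metric (or the training metric in full-data
#' mode). The species-to-sample attention of the final layer, averaged over
#' heads, is returned for signature calling.
#'
#' @param graph a [assemble_graph()] result with at least two label classes.
#' @param config a [train_config()].
#' @param embeddings optional precomputed [initial_embeddings()]; when `NULL`
#'   they are trained here with `ae` (seeded from `config$seed`).
#' @param ae an [ae_config()] used when `embeddings` is `NULL`.
#' @return an object of class `hgt_fit` with components `params`, `config`,
#'   `attention` (an [attention_matrix()]), `history` (per-epoch loss, metric
#'   and learning rate), `metrics` (final [evaluate_classification()] report
#'   on the held-out samples, or on all samples in full-data mode), `split`,
#'   `prob`, `predicted`, `graph`.
#' @export
fit_hgt <- function(graph, config = train_config(), embeddings = NULL,
                    ae = NULL) {
  if (!inherits(graph, "hetero_graph")) stop("graph must come from assemble_graph()")
  if (length(graph$samples) == 0 || length(graph$species) == 0)
    stop("empty graph")
  present <- droplevels(graph$labels)
  if (nlevels(present) < 2) stop("need at least two label classes to train")
  if (anyNA(graph$labels)) stop("sample(s) with missing label")
  if (is.null(embeddings)) {
    if (is.null(ae)) ae <- ae_config(seed = config$seed)
    embeddings <- initial_embeddings(graph, ae)
  }
  set.seed(config$seed)
  labels <- graph$labels
  split <- stratified_split(labels, config$split_fraction)
  edges <- hgt_edges(graph)
  X0 <- list(species = embeddings$species, sample = embeddings$samples)
  params <- hgt_init_params(graph, ncol(X0$species), config)
  opt <- adam_new(params)
  lr <- config$learning_rate
  y <- as.integer(labels)
  monitor_idx <- if (length(split$val)) split$val else split$train
  best <- -Inf; wait <- 0L
  hist <- data.frame(epoch = integer(0), loss = numeric(0), focal = numeric(0),
                     kl = numeric(0), metric = numeric(0), lr = numeric(0))
  fw <- NULL
  for (ep in seq_len(max(config$epochs, 1L))) {
    run_epoch <- ep <= config$epochs
    fw <- hgt_forward_impl(params, edges, X0, config)
    logits <- sweep(fw$X$sample %*% params$Wc, 2, params$bc, "+")
    P <- softmax_rows(logits)
    fl <- focal_loss(P[split$train, , drop = FALSE], y[split$train],
                     config$focal_gamma, config$focal_alpha)
    kl <- hgt_kl(fw, edges, config)
    loss <- fl + config$kl_coef * kl
    pred <- levels(labels)[max.col(P, ties.method = "first")]
    mrep <- evaluate_classification(pred[monitor_idx],
                                    as.character(labels)[monitor_idx],
                                    levels(labels))
    metric <- switch(config$monitor, macro_f1 = mrep$macro_f1,
                     accuracy = mrep$accuracy, loss = -loss)
    hist <- rbind(hist, data.frame(epoch = ep, loss = loss, focal = fl,
                                   kl = kl, metric = metric, lr = lr))
    if (!run_epoch) break
    dlog <- focal_logit_grad(P, y, config$focal_gamma, config$focal_alpha,
                             split$train)
    g <- hgt_backward_impl(params, edges, X0, config, fw,
                           list(species = matrix(0, nrow(X0$species), config$n_hid),
                                sample = dlog %*% t(params$Wc)))
    g$Wc <- t(fw$X$sample) %*% dlog
    g$bc <- colSums(dlog)
    st <- adam_step(opt, params, g, lr)
    params <- st$params; opt <- st$state
    if (metric > best + 1e-12) {
      best <- metric; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$lr_patience) {
        lr <- lr * config$lr_factor
        wait <- 0L
      }
    }
  }
  # final forward with trained parameters
  fw <- hgt_forward_impl(params, edges, X0, config)
  logits <- sweep(fw$X$sample %*% params$Wc, 2, params$bc, "+")
  P <- softmax_rows(logits)
  pred <- factor(levels(labels)[max.col(P, ties.method = "first")],
                 levels = levels(labels))
  e <- edges$sp2sa
  scores <- matrix(0, length(graph$species), length(graph$samples),
                   dimnames = list(graph$species, graph$samples))
  if (length(e$src))
    scores[cbind(e$src, e$tgt)] <-
      rowMeans(fw$layers[[config$n_layers]]$et$sp2sa$att)
  att <- attention_matrix(scores, graph$A > 0)
  eval_idx <- monitor_idx
  metrics <- evaluate_classification(as.character(pred)[eval_idx],
                                     as.character(labels)[eval_idx],
                                     levels(labels))
  structure(list(params = params, config = config, attention = att,
                 history = hist, metrics = metrics, split = split,
                 prob = P, predicted = pred, labels = labels,
                 graph = graph, embeddings = embeddings),
            class = "hgt_fit")
}

#' @export
print.hgt_fit <- function(x, ...) {
  cat(sprintf("hgt_fit: %d species + %d samples, %d classes, %d heads x %d hidden, %d layer(s)\n",
              length(x$graph$species), length(x$graph$samples),
              nlevels(x$labels), x$config$n_heads, x$config$n_hid,
              x$config$n_layers))
  mode <- if (length(x$split$val)) sprintf("%.0f/%.0f split",
                                           100 * x$config$split_fraction,
                                           100 * (1 - x$config$split_fraction))
          else "full-data"
  cat(sprintf("  %d epochs (%s), final loss %.5f\n", nrow(x$history), mode,
              utils::tail(x$history$loss, 1)))
  print(x$metrics)
  invisible(x)
}

#' @export
summary.hgt_fit <- function(object, ...) {
  print(object)
  cat("learning-rate schedule:",
      paste(unique(object$history$lr), collapse = " -> "), "\n")
  cat(sprintf("attention: %d supported species-sample cells, mean %.4f\n",
              sum(object$attention$support),
              mean(object$attention$scores[object$attention$support])))
  invisible(object)
}

#' Predicted cancer-type labels or class probabilities
#'
#' The model is transductive (it embeds the fixed species-sample graph), so
#' predictions refer to the samples of the fitted graph.
#'
#' @param object an `hgt_fit`.
#' @param type `"class"` (default) or `"prob"`.
#' @param which `"all"`, `"train"` or `"val"` samples.
#' @param ... unused.
#' @export
predict.hgt_fit <- function(object, type = c("class", "prob"),
                            which = c("all", "train", "val"), ...) {
  type <- match.arg(type)
  which <- match.arg(which)
  idx <- switch(which, all = seq_along(object$labels),
                train = object$split$train, val = object$split$val)
  if (type == "prob") {
    out <- object$prob[idx, , drop = FALSE]
    rownames(out) <- object$graph$samples[idx]
    colnames(out) <- levels(object$labels)
    out
  } else {
    stats::setNames(object$predicted[idx], object$graph$samples[idx])
  }
}

#' @export
coef.hgt_fit <- function(object, ...) {
  out <- object$params$Wc
  colnames(out) <- levels(object$labels)
  out
}

#' Plot the training history of a fitted graph transformer
#'
#' Left axis: training loss; right axis: monitored metric, with learning-rate
#' decays marked.
#'
#' @param x an `hgt_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.hgt_fit <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mar = c(4, 4, 2, 4))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$loss, type = "l", xlab = "epoch", ylab = "loss",
                 main = "training history", ...)
  graphics::par(new = TRUE)
  graphics::plot(h$epoch, h$metric, type = "l", lty = 2, col = "steelblue",
                 axes = FALSE, xlab = "", ylab = "")
  graphics::axis(4, col.axis = "steelblue")
  graphics::mtext(sprintf("monitored metric (%s)", x$config$monitor),
                  side = 4, line = 2.5, col = "steelblue")
  drops <- which(diff(h$lr) < 0) + 1
  if (length(drops)) graphics::abline(v = h$epoch[drops], lty = 3, col = "grey50")
  invisible(x)
}
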