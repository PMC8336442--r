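#' Training configuration
#'
#' Bundles every hyper-parameter of the optimisation. Defaults are the
#' settings used for the full-scale SL corpus: learning rate 0.002 and L2
#' weight 0.0039 (Adam), neighbour sample size `k = 64`, embedding
#' dimension `d = 256`, `H = 2` hops. Batch size, patience and the
#' maximum epoch count control cost and early stopping and can be scaled
#' down freely for small corpora.
#'
#' @param learning_rate Adam step size (> 0)
#' @param l2_alpha weight of the L2 penalty (>= 0)
#' @param batch_size mini-batch size
#' @param max_epochs hard cap on training epochs
#' @param patience epochs without validation-AUC improvement before
#'   stopping
#' @param k,d,H sampler width, embedding dimension, hop count
#' @param seed integer seed making the whole run reproducible
#' @param final_activation passed to [init_params()]
#' @param loss_on `"logit"` (default) feeds the raw inner product to the
#'   cross-entropy; `"probability"` feeds the sigmoid output instead
#' @return list of class `train_config`
#' @export
train_config <- function(learning_rate = 0.002, l2_alpha = 0.0039,
                         batch_size = 256L, max_epochs = 50L, patience = 10L,
                         k = 64L, d = 256L, H = 2L, seed = NULL,
                         final_activation = c("tanh", "relu"),
                         loss_on = c("logit", "probability")) {
  if (learning_rate <= 0) abort_config("learning_rate must be > 0")
  if (l2_alpha < 0) abort_config("l2_alpha must be >= 0")
  if (batch_size < 1L) abort_config("batch_size must be >= 1")
  if (max_epochs < 1L) abort_config("max_epochs must be >= 1")
  if (patience < 1L) abort_config("patience must be >= 1")
  structure(list(learning_rate = learning_rate, l2_alpha = l2_alpha,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 k = as.integer(k), d = as.integer(d), H = as.integer(H),
                 seed = seed,
                 final_activation = match.arg(final_activation),
                 loss_on = match.arg(loss_on)),
            class = "train_config")
}

#' Cross-entropy base loss on one pair
#'
#' The numerically stable form `J(x) = max(x, 0) - x * s + log(1 +
#' exp(-|x|))`, algebraically equal to the binary cross-entropy
#' `-(s log sigma(x) + (1 - s) log(1 - sigma(x)))` for logit `x` and
#' label `s`.
#'
#' @param logit finite real score (raw inner product)
#' @param label 0 or 1
#' @return loss value >= 0
#' @export
base_loss <- function(logit, label) {
  if (!all(label %in% c(0, 1))) abort_config("label must be 0 or 1")
  if (any(!is.finite(logit))) abort_numeric("logit must be finite")
  pmax(logit, 0) - logit * label + log1p(exp(-abs(logit)))
}

#' Sparse L2 penalty
#'
#' One half of the sum of squared entries of (a) the entity-embedding rows
#' touched by the current batch's receptive fields, (b) the touched
#' relation-embedding rows and (c) every layer transform `W`. Only touched
#' embedding rows are penalised per step so the effective decay does not
#' scale with vocabulary size; transform weights are always included.
#' Biases are not penalised. The 1/2 factor is the usual weight-decay
#' convention.
#'
#' @param params a [init_params()] object
#' @param batch_entities integer set of touched entity indices
#' @param batch_relations integer set of touched relation indices
#' @return penalty value >= 0
#' @export
l2_penalty <- function(params, batch_entities, batch_relations) {
  0.5 * (sum(params$entity_emb[unique(batch_entities), , drop = FALSE]^2) +
           sum(params$relation_emb[unique(batch_relations), , drop = FALSE]^2) +
           sum(vapply(params$W, function(W) sum(W^2), 0)))
}

#' Total loss of a batch with frozen receptive fields
#'
#' Sum of [base_loss()] over the batch plus `l2_alpha` times
#' [l2_penalty()] over the entities and relations appearing in the
#' supplied receptive fields. Uses the transparent per-gene
#' [encode_gene()] path; the training loop computes the identical
#' quantity in batched form.
#'
#' @param batch data.frame `gene_a`, `gene_b`, `label`
#' @param params a [init_params()] object
#' @param cfg a [train_config()]
#' @param fields list with elements `a` and `b`: per-pair receptive
#'   fields for each gene of each pair
#' @return scalar loss
#' @export
total_loss <- function(batch, params, cfg, fields) {
  n <- nrow(batch)
  if (length(fields$a) != n || length(fields$b) != n)
    abort_config("fields must cover both genes of every pair")
  base <- vapply(seq_len(n), function(i) {
    enc_a <- encode_gene(fields$a[[i]], batch$gene_b[i], params)
    enc_b <- encode_gene(fields$b[[i]], batch$gene_a[i], params)
    sc <- score_pair(enc_a, enc_b)
    x <- if (identical(cfg$loss_on, "probability")) sc$probability else sc$logit
    base_loss(x, batch$label[i])
  }, 0)
  ents <- unique(c(unlist(lapply(c(fields$a, fields$b),
                                 function(f) unlist(f$hop_entities))),
                   batch$gene_a, batch$gene_b))
  rels <- unique(unlist(lapply(c(fields$a, fields$b),
                               function(f) unlist(f$hop_relations))))
  sum(base) + cfg$l2_alpha * l2_penalty(params, ents, rels)
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  zero_like <- function(x) if (is.list(x)) lapply(x, zero_like) else array(0, dim(x) %||% length(x))
  list(m = list(entity_emb = array(0, dim(params$entity_emb)),
                relation_emb = array(0, dim(params$relation_emb)),
                W = lapply(params$W, function(W) array(0, dim(W))),
                b = lapply(params$b, function(b) numeric(length(b)))),
       v = list(entity_emb = array(0, dim(params$entity_emb)),
                relation_emb = array(0, dim(params$relation_emb)),
                W = lapply(params$W, function(W) array(0, dim(W))),
                b = lapply(params$b, function(b) numeric(length(b)))),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One dense Adam step (beta1 = 0.9, beta2 = 0.999, eps = 1e-8; standard
# constants). Gradients are zero outside the touched rows, which matches
# the dense-update semantics of mainstream frameworks.
adam_step <- function(params, state, grads, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  upd <- function(p, m, v, g) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    p <- p - lr * (m / corr1) / (sqrt(v / corr2) + eps)
    list(p = p, m = m, v = v)
  }
  for (nm in c("entity_emb", "relation_emb")) {
    r <- upd(params[[nm]], state$m[[nm]], state$v[[nm]], grads[[nm]])
    params[[nm]] <- r$p; state$m[[nm]] <- r$m; state$v[[nm]] <- r$v
  }
  for (l in seq_along(params$W)) {
    r <- upd(params$W[[l]], state$m$W[[l]], state$v$W[[l]], grads$W[[l]])
    params$W[[l]] <- r$p; state$m$W[[l]] <- r$m; state$v$W[[l]] <- r$v
    r <- upd(params$b[[l]], state$m$b[[l]], state$v$b[[l]], grads$b[[l]])
    params$b[[l]] <- r$p; state$m$b[[l]] <- r$m; state$v$b[[l]] <- r$v
  }
  list(params = params, state = state)
}

# ---- Evaluation -------------------------------------------------------------

#' Evaluate a model on labelled pairs
#'
#' Draws one receptive field per unique gene under `eval_seed` (frozen, so
#' repeated evaluation of the same parameters is bit-identical), scores
#' every pair and computes AUC, AUPR, F1 at threshold 0.5 and the mean
#' base loss.
#'
#' @param params a [init_params()] object
#' @param pairs data.frame `gene_a`, `gene_b`, `label` containing both
#'   classes
#' @param kg the [knowledge_graph()]
#' @param cfg a [train_config()] (supplies `k`, `H`, `loss_on`)
#' @param eval_seed integer seed for the evaluation receptive fields
#' @param fields_by_gene optional pre-built fields (overrides `eval_seed`)
#' @return list of class `eval_metrics`: `auc`, `aupr`, `f1`, `loss`, `n`
#' @export
evaluate <- function(params, pairs, kg, cfg, eval_seed = NULL,
                     fields_by_gene = NULL) {
  check_two_classes(pairs$label, "AUC/AUPR")
  if (is.null(fields_by_gene)) {
    genes <- unique(c(pairs$gene_a, pairs$gene_b))
    fields_by_gene <- build_fields_by_gene(
      kg, genes, sampler_config(cfg$k, cfg$H), seed = eval_seed)
  }
  pr <- kgnn_predict_with_fields(params, pairs, fields_by_gene)
  x <- if (identical(cfg$loss_on, "probability")) pr$probability else pr$logit
  structure(list(auc = auc_score(pr$probability, pairs$label),
                 aupr = aupr_score(pr$probability, pairs$label),
                 f1 = f1_score(pr$probability, pairs$label),
                 loss = mean(base_loss(x, pairs$label)),
                 n = nrow(pairs)),
            class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf("<eval_metrics> n=%d  AUC %.4f  AUPR %.4f  F1 %.4f  loss %.4f\n",
              x$n, x$auc, x$aupr, x$f1, x$loss))
  invisible(x)
}

# ---- Training loop ----------------------------------------------------------

#' Train the knowledge-graph SL model
#'
#' Mini-batch Adam on the batched forward/backward pass. Training-time
#' receptive fields are re-drawn fresh for every batch (stochastic
#' regularisation); evaluation fields for all three splits are drawn once
#' at the start and frozen. After every epoch the model is evaluated on
#' train/validation/test; training stops when the validation AUC has not
#' improved for `patience` epochs or at `max_epochs`, and the parameters
#' from the best validation epoch are returned. With a fixed `cfg$seed`
#' the run is fully deterministic (single-threaded reference mode).
#'
#' @param data an `sl_dataset` from [split_dataset()] with non-empty train
#'   and validation splits
#' @param kg the [knowledge_graph()] the pairs live in
#' @param cfg a [train_config()]
#' @param verbose print one line per epoch
#' @return object of class `kgnn_fit`: list with `params` (best-epoch
#'   parameters), `history` (data.frame `epoch`, `split`, `loss`, `auc`,
#'   `aupr`, `f1`), `best_epoch`, `cfg`
#' @export
train_model <- function(data, kg, cfg, verbose = FALSE) {
  splits <- lapply(c(train = "train", valid = "valid", test = "test"),
                   function(s) dataset_split(data, s))
  if (nrow(splits$train) == 0L || nrow(splits$valid) == 0L)
    abort_config("train and validation splits must be non-empty")
  genes <- unique(c(data$pairs$gene_a, data$pairs$gene_b))
  if (any(kg$entities$etype[genes] != "gene"))
    abort_type("SL dataset references non-gene entities")

  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  params <- init_params(nrow(kg$entities), length(kg$relations),
                        d = cfg$d, H = cfg$H,
                        final_activation = cfg$final_activation)
  sampler <- sampler_config(cfg$k, cfg$H)
  eval_fields <- build_fields_by_gene(kg, genes, sampler)
  state <- adam_init(params)

  history <- list()
  best <- list(auc = -Inf, epoch = 0L, params = params)
  wait <- 0L
  n_train <- nrow(splits$train)

  for (epoch in seq_len(cfg$max_epochs)) {
    perm <- sample.int(n_train)
    for (start in seq(1L, n_train, by = cfg$batch_size)) {
      rows <- perm[start:min(start + cfg$batch_size - 1L, n_train)]
      batch <- splits$train[rows, , drop = FALSE]
      fa <- lapply(batch$gene_a, build_receptive_field, kg = kg, cfg = sampler)
      fb <- lapply(batch$gene_b, build_receptive_field, kg = kg, cfg = sampler)
      g <- kgnn_batch_grad(params, batch, fa, fb,
                           alpha = cfg$l2_alpha, loss_on = cfg$loss_on)
      if (!is.finite(g$loss))
        abort_numeric(sprintf("loss diverged (non-finite) at epoch %d", epoch))
      r <- adam_step(params, state, g$grads, cfg$learning_rate)
      params <- r$params; state <- r$state
    }

    ep_metrics <- lapply(names(splits), function(s) {
      if (nrow(splits[[s]]) == 0L) return(NULL)
      m <- evaluate(params, splits[[s]], kg, cfg, fields_by_gene = eval_fields)
      data.frame(epoch = epoch, split = s, loss = m$loss,
                 auc = m$auc, aupr = m$aupr, f1 = m$f1)
    })
    history[[epoch]] <- do.call(rbind, ep_metrics)
    v_auc <- history[[epoch]]$auc[history[[epoch]]$split == "valid"]
    if (verbose)
      message(sprintf("epoch %3d  train loss %.4f  valid AUC %.4f",
                      epoch, history[[epoch]]$loss[1L], v_auc))
    if (v_auc > best$auc) {
      best <- list(auc = v_auc, epoch = epoch, params = params)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }

  structure(list(params = best$params,
                 history = do.call(rbind, history),
                 best_epoch = best$epoch,
                 cfg = cfg),
            class = "kgnn_fit")
}

#' @export
print.kgnn_fit <- function(x, ...) {
  h <- x$history[x$history$epoch == x$best_epoch, ]
  cat(sprintf("<kgnn_fit> %d epochs trained, best epoch %d\n",
              max(x$history$epoch), x$best_epoch))
  for (i in seq_len(nrow(h)))
    cat(sprintf("  %-5s loss %.4f  AUC %.4f  AUPR %.4f  F1 %.4f\n",
                h$split[i], h$loss[i], h$auc[i], h$aupr[i], h$f1[i]))
  invisible(x)
}

#' Predict SL probabilities for gene pairs
#'
#' @param fit a [train_model()] result (or a list with `params` and `cfg`)
#' @param pairs data.frame `gene_a`, `gene_b` (entity indices)
#' @param kg the [knowledge_graph()]
#' @param eval_seed seed for the frozen prediction receptive fields
#' @return `pairs` with added columns `probability` and `label` (0.5
#'   threshold)
#' @export
predict_pairs <- function(fit, pairs, kg, eval_seed = NULL) {
  cfg <- fit$cfg
  genes <- unique(c(pairs$gene_a, pairs$gene_b))
  fbg <- build_fields_by_gene(kg, genes, sampler_config(cfg$k, cfg$H),
                              seed = eval_seed)
  pr <- kgnn_predict_with_fields(fit$params, pairs, fbg)
  pairs$probability <- pr$probability
  pairs$label <- as.integer(pr$probability >= 0.5)
  pairs
}
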