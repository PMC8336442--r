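# Batched forward and backward pass.
#
# Pairs are processed in mini-batches with receptive fields stacked into
# flat pair-major index vectors (stack_fields): hop h of a batch of B
# pairs is one (B * k^h) x d matrix, so every hop update is a single BLAS
# call. The math is identical to the per-gene encode_gene() path (asserted
# by the oracle tests). Because no autodiff framework is available, the
# backward pass is derived by hand:
#
#   layer:    Z = X W' + b, A = phi(Z)         => dX = (dA * phi'(Z)) W
#   aggregate: agg[p] = sum_c w[c] E_child[c]  => dE_child[c] += w[c] dagg[p]
#                                                 dw[c] += <dagg[p], E_child[c]>
#   softmax (per group of k): ds = w * (dw - <dw, w>_group)
#   scores:   s[c] = <q_pair, rel_emb[c]>      => grads on both factors
#
# Entity-embedding gradients accumulate from the hop-0..H input rows and
# from the partner-conditioning vectors q.

forward_side <- function(params, sf, Q) {
  k <- sf$k; H <- sf$H; B <- sf$B
  E0 <- lapply(sf$ent, function(idx) params$entity_emb[idx, , drop = FALSE])
  w <- vector("list", H)
  for (h in seq_len(H)) {
    pair_of <- rep(seq_len(B), each = k^h)
    s <- rowSums(params$relation_emb[sf$rel[[h]], , drop = FALSE] *
                   Q[pair_of, , drop = FALSE])
    w[[h]] <- group_softmax(s, k)
  }
  E <- E0
  cache <- vector("list", H)
  for (l in seq_len(H)) {
    is_last <- l == H
    E_new <- vector("list", H - l + 1L)
    cache_l <- vector("list", H - l + 1L)
    for (h in seq_len(H - l + 1L)) {
      agg <- group_weighted_sum(E[[h + 1L]], w[[h]], k)
      X <- E[[h]] + agg
      Z <- X %*% t(params$W[[l]])
      Z <- Z + rep(params$b[[l]], each = nrow(Z))
      A <- activate(Z, is_last, params$final_activation)
      E_new[[h]] <- A
      cache_l[[h]] <- list(X = X, A = A)
    }
    cache[[l]] <- cache_l
    E <- E_new
  }
  list(enc = E[[1L]], E0 = E0, w = w, cache = cache)
}

backward_side <- function(params, sf, fw, Q, dEnc) {
  k <- sf$k; H <- sf$H; B <- sf$B
  dW <- lapply(params$W, function(W) array(0, dim(W)))
  db <- lapply(params$b, function(b) numeric(length(b)))
  dw_acc <- lapply(fw$w, function(w) numeric(length(w)))

  dE <- list(dEnc)
  for (l in rev(seq_len(H))) {
    is_last <- l == H
    Eprev <- if (l == 1L) fw$E0 else lapply(fw$cache[[l - 1L]], `[[`, "A")
    dE_prev <- lapply(Eprev[seq_len(H - l + 2L)], function(m) array(0, dim(m)))
    for (h in seq_len(H - l + 1L)) {
      ch <- fw$cache[[l]][[h]]
      dZ <- if (!is_last || identical(params$final_activation, "relu"))
        dE[[h]] * (ch$A > 0) else dE[[h]] * (1 - ch$A^2)
      dW[[l]] <- dW[[l]] + crossprod(dZ, ch$X)
      db[[l]] <- db[[l]] + colSums(dZ)
      dX <- dZ %*% params$W[[l]]
      dE_prev[[h]] <- dE_prev[[h]] + dX
      par_rep <- rep(seq_len(nrow(dX)), each = k)
      dXrep <- dX[par_rep, , drop = FALSE]
      Echild <- Eprev[[h + 1L]]
      dE_prev[[h + 1L]] <- dE_prev[[h + 1L]] + fw$w[[h]] * dXrep
      dw_acc[[h]] <- dw_acc[[h]] + rowSums(dXrep * Echild)
    }
    dE <- dE_prev
  }

  dQ <- array(0, dim(Q))
  rel_idx <- vector("list", H)
  rel_grad <- vector("list", H)
  for (h in seq_len(H)) {
    w <- fw$w[[h]]
    dw <- dw_acc[[h]]
    gdot <- colSums(matrix(w * dw, nrow = k))
    ds <- w * (dw - rep(gdot, each = k))
    pair_of <- rep(seq_len(B), each = k^h)
    Rl <- params$relation_emb[sf$rel[[h]], , drop = FALSE]
    dQ <- dQ + rowsum_into(ds * Rl, pair_of, B)
    rel_idx[[h]] <- sf$rel[[h]]
    rel_grad[[h]] <- ds * Q[pair_of, , drop = FALSE]
  }

  list(dW = dW, db = db, dE0 = dE, dQ = dQ,
       rel_idx = unlist(rel_idx, use.names = FALSE),
       rel_grad = do.call(rbind, rel_grad))
}

# rowsum() onto a dense n-row matrix (groups are 1..n positions)
rowsum_into <- function(G, group, n) {
  r <- rowsum(G, group)
  out <- matrix(0, n, ncol(G))
  out[as.integer(rownames(r)), ] <- r
  out
}

# Full forward pass over a batch of pairs with frozen receptive fields.
# Returns encodings, logits and probabilities plus per-side caches.
kgnn_batch_forward <- function(params, sfa, sfb, genes_a, genes_b) {
  Qa <- params$entity_emb[genes_b, , drop = FALSE]   # side a conditioned on partner b
  Qb <- params$entity_emb[genes_a, , drop = FALSE]
  fa <- forward_side(params, sfa, Qa)
  fb <- forward_side(params, sfb, Qb)
  logit <- rowSums(fa$enc * fb$enc)
  list(fa = fa, fb = fb, Qa = Qa, Qb = Qb,
       logit = logit, probability = stats::plogis(logit))
}

# Loss + full analytic gradient for one mini-batch.
# base loss: J(x) = max(x,0) - x*s + log(1 + exp(-|x|)) with x the logit
# (default) or the probability (loss_on = "probability").
kgnn_batch_grad <- function(params, pairs, fields_a, fields_b,
                            alpha = 0, loss_on = "logit") {
  sfa <- stack_fields(fields_a)
  sfb <- stack_fields(fields_b)
  fwd <- kgnn_batch_forward(params, sfa, sfb, pairs$gene_a, pairs$gene_b)
  s <- pairs$label
  x <- if (identical(loss_on, "probability")) fwd$probability else fwd$logit
  base <- pmax(x, 0) - x * s + log1p(exp(-abs(x)))
  dx <- stats::plogis(x) - s
  dlogit <- if (identical(loss_on, "probability"))
    dx * fwd$probability * (1 - fwd$probability) else dx

  dEncA <- fwd$fb$enc * dlogit
  dEncB <- fwd$fa$enc * dlogit
  ba <- backward_side(params, sfa, fwd$fa, fwd$Qa, dEncA)
  bb <- backward_side(params, sfb, fwd$fb, fwd$Qb, dEncB)

  n_ent <- nrow(params$entity_emb)
  ent_idx <- c(unlist(sfa$ent, use.names = FALSE), unlist(sfb$ent, use.names = FALSE),
               pairs$gene_b, pairs$gene_a)
  ent_grad <- rbind(do.call(rbind, ba$dE0), do.call(rbind, bb$dE0), ba$dQ, bb$dQ)
  g_ent <- rowsum_into(ent_grad, ent_idx, n_ent)

  n_rel <- nrow(params$relation_emb)
  g_rel <- rowsum_into(rbind(ba$rel_grad, bb$rel_grad),
                       c(ba$rel_idx, bb$rel_idx), n_rel)

  g_W <- mapply(`+`, ba$dW, bb$dW, SIMPLIFY = FALSE)
  g_b <- mapply(`+`, ba$db, bb$db, SIMPLIFY = FALSE)

  touched_ent <- unique(ent_idx)
  touched_rel <- unique(c(ba$rel_idx, bb$rel_idx))
  penalty <- l2_penalty(params, touched_ent, touched_rel)
  if (alpha != 0) {
    g_ent[touched_ent, ] <- g_ent[touched_ent, ] +
      alpha * params$entity_emb[touched_ent, , drop = FALSE]
    g_rel[touched_rel, ] <- g_rel[touched_rel, ] +
      alpha * params$relation_emb[touched_rel, , drop = FALSE]
    g_W <- lapply(seq_along(g_W), function(l) g_W[[l]] + alpha * params$W[[l]])
  }

  list(loss = sum(base) + alpha * penalty,
       base_loss = base,
       probability = fwd$probability,
       logit = fwd$logit,
       grads = list(entity_emb = g_ent, relation_emb = g_rel, W = g_W, b = g_b))
}

# Forward-only probabilities for a set of pairs with supplied per-gene
# receptive fields (one field per unique gene, reused across pairs).
kgnn_predict_with_fields <- function(params, pairs, fields_by_gene,
                                     chunk = 512L) {
  n <- nrow(pairs)
  probs <- numeric(n)
  logits <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    fa <- fields_by_gene[as.character(pairs$gene_a[idx])]
    fb <- fields_by_gene[as.character(pairs$gene_b[idx])]
    fwd <- kgnn_batch_forward(params, stack_fields(fa), stack_fields(fb),
                              pairs$gene_a[idx], pairs$gene_b[idx])
    probs[idx] <- fwd$probability
    logits[idx] <- fwd$logit
  }
  list(probability = probs, logit = logits)
}

# Draw one receptive field per unique gene (evaluation fields are frozen
# under one seed so metrics are reproducible and comparable across epochs).
build_fields_by_gene <- function(kg, genes, cfg_sampler, seed = NULL) {
  genes <- sort(unique(genes))
  with_seed(seed, {
    out <- lapply(genes, function(g) build_receptive_field(kg, g, cfg_sampler))
    names(out) <- as.character(genes)
    out
  })
}
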