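# Independent reference implementations used as oracles. These are
# deliberately written with scalar loops and naive formulas, sharing no
# code with the package's vectorised paths.

# Nested-loop reference encoder: softmax-weighted aggregation of the
# receptive field conditioned on the partner's raw embedding, H layer
# updates, scalar loops throughout.
oracle_encode <- function(field, partner, params) {
  k <- attr(field, "k"); H <- attr(field, "H"); d <- params$d
  q <- params$entity_emb[partner, ]
  E <- lapply(field$hop_entities, function(idx)
    lapply(idx, function(e) params$entity_emb[e, ]))
  wts <- vector("list", H)
  for (h in seq_len(H)) {
    rel <- field$hop_relations[[h]]
    w <- numeric(length(rel))
    for (p in seq_len(length(rel) %/% k)) {
      sl <- ((p - 1L) * k + 1L):(p * k)
      s <- numeric(k)
      for (j in seq_len(k)) {
        acc <- 0
        for (t in seq_len(d)) acc <- acc + q[t] * params$relation_emb[rel[sl[j]], t]
        s[j] <- acc
      }
      ex <- exp(s - max(s))
      w[sl] <- ex / sum(ex)
    }
    wts[[h]] <- w
  }
  for (l in seq_len(H)) {
    is_last <- l == H
    En <- vector("list", H - l + 1L)
    for (h in seq_len(H - l + 1L)) {
      m <- length(E[[h]])
      En[[h]] <- vector("list", m)
      for (p in seq_len(m)) {
        agg <- numeric(d)
        for (j in seq_len(k)) {
          cidx <- (p - 1L) * k + j
          agg <- agg + wts[[h]][cidx] * E[[h + 1L]][[cidx]]
        }
        z <- numeric(d)
        for (row in seq_len(d)) {
          acc <- params$b[[l]][row]
          for (col in seq_len(d))
            acc <- acc + params$W[[l]][row, col] * (E[[h]][[p]][col] + agg[col])
          z[row] <- acc
        }
        En[[h]][[p]] <- if (!is_last || params$final_activation == "relu")
          pmax(z, 0) else tanh(z)
      }
    }
    E <- En
  }
  E[[1L]][[1L]]
}

# loss of a set of pairs through the oracle encoder (base loss on logits
# plus the sparse L2 penalty computed by direct summation)
oracle_total_loss <- function(batch, params, alpha, fields_a, fields_b) {
  base <- 0
  for (i in seq_len(nrow(batch))) {
    ea <- oracle_encode(fields_a[[i]], batch$gene_b[i], params)
    eb <- oracle_encode(fields_b[[i]], batch$gene_a[i], params)
    x <- sum(ea * eb)
    s <- batch$label[i]
    base <- base + max(x, 0) - x * s + log(1 + exp(-abs(x)))
  }
  ents <- unique(c(unlist(lapply(c(fields_a, fields_b),
                                 function(f) unlist(f$hop_entities))),
                   batch$gene_a, batch$gene_b))
  rels <- unique(unlist(lapply(c(fields_a, fields_b),
                               function(f) unlist(f$hop_relations))))
  pen <- 0
  for (e in ents) pen <- pen + sum(params$entity_emb[e, ]^2)
  for (r in rels) pen <- pen + sum(params$relation_emb[r, ]^2)
  for (l in seq_along(params$W)) pen <- pen + sum(params$W[[l]]^2)
  base + alpha * pen / 2
}

# pairwise-comparison AUC: P(score_pos > score_neg) + 0.5 P(tie)
oracle_auc <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  tot <- 0
  for (p in sp) for (n in sn) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(sp) * length(sn))
}

# average precision for tie-free scores: mean over positives of the
# precision at that positive's rank
oracle_ap <- function(scores, labels) {
  stopifnot(!anyDuplicated(scores))
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  ranks_pos <- which(y == 1)
  mean(vapply(ranks_pos, function(r) sum(y[1:r]) / r, 0))
}
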