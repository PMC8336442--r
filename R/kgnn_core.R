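#' Initialise model parameters
#'
#' Allocates the entity embedding table (`n_entities` x `d`), the relation
#' embedding table (`n_relations` x `d`) and one linear transform
#' (`W`: d x d, `b`: d) per aggregation layer. Matrices are drawn from the
#' Glorot-style scaled uniform `U(-sqrt(6/(fan_in+fan_out)),
#' +sqrt(6/(fan_in+fan_out)))`; biases start at zero.
#'
#' The final-layer activation defaults to `tanh`: with ReLU on every layer
#' the encoded genes would be componentwise non-negative, all pair logits
#' would be >= 0 and the 0.5 decision threshold could never output class 0.
#' `final_activation = "relu"` restores an all-ReLU encoder.
#'
#' @param n_entities,n_relations vocabulary sizes (>= 1)
#' @param d embedding dimension (default 256)
#' @param H number of aggregation layers (default 2); must match the
#'   sampler's hop count
#' @param seed integer seed; identical seeds give bit-identical parameters
#' @param final_activation `"tanh"` (default) or `"relu"`
#' @return object of class `kgnn_params`: list with `entity_emb`,
#'   `relation_emb`, `W` (list of H d x d matrices), `b` (list of H
#'   d-vectors), `d`, `H`, `final_activation`
#' @export
init_params <- function(n_entities, n_relations, d = 256L, H = 2L, seed = NULL,
                        final_activation = c("tanh", "relu")) {
  final_activation <- match.arg(final_activation)
  d <- as.integer(d); H <- as.integer(H)
  if (is.na(d) || d < 1L) abort_config("embedding dimension d must be >= 1")
  if (is.na(H) || H < 1L) abort_config("layer count H must be >= 1")
  if (n_entities < 1L || n_relations < 1L) abort_config("vocabulary sizes must be >= 1")
  with_seed(seed, {
    glorot <- function(nr, nc) {
      lim <- sqrt(6 / (nr + nc))
      matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
    }
    structure(list(entity_emb = glorot(n_entities, d),
                   relation_emb = glorot(n_relations, d),
                   W = lapply(seq_len(H), function(i) glorot(d, d)),
                   b = lapply(seq_len(H), function(i) numeric(d)),
                   d = d, H = H, final_activation = final_activation),
              class = "kgnn_params")
  })
}

#' @export
print.kgnn_params <- function(x, ...) {
  cat(sprintf("<kgnn_params> %d entities, %d relations, d=%d, H=%d, final activation %s\n",
              nrow(x$entity_emb), nrow(x$relation_emb), x$d, x$H, x$final_activation))
  invisible(x)
}

#' Partner-conditioned relation scores
#'
#' The importance of an edge in gene i's receptive field is conditioned on
#' its candidate SL *partner* j: the score of relation r is the inner
#' product of the partner gene's embedding with the relation-type
#' embedding. The same relation can thus matter for one partner and be
#' ignored for another.
#'
#' @param partner_emb numeric vector of length d (the partner gene's raw
#'   entity embedding)
#' @param relation_emb_rows k x d matrix of relation embeddings, one row
#'   per sampled edge
#' @return numeric vector of k raw scores
#' @export
relation_scores <- function(partner_emb, relation_emb_rows) {
  relation_emb_rows <- as_matrix_d(relation_emb_rows, length(partner_emb),
                                   "relation_emb_rows")
  as.vector(relation_emb_rows %*% partner_emb)
}

#' Softmax normalisation of relation scores
#'
#' Max-shifted for numerical stability; the output sums to 1 with every
#' entry in (0, 1].
#'
#' @param scores numeric vector of finite raw scores
#' @return numeric vector of the same length summing to 1
#' @export
normalize_scores <- function(scores) {
  if (length(scores) < 1L) abort_shape("scores must be non-empty")
  if (anyNA(scores) || any(!is.finite(scores))) abort_numeric("scores must be finite")
  e <- exp(scores - max(scores))
  e / sum(e)
}

#' Weighted average of neighbour embeddings
#'
#' @param neighbor_embs k x d matrix
#' @param weights normalised weights of length k (summing to 1)
#' @return numeric vector of length d
#' @export
aggregate_neighborhood <- function(neighbor_embs, weights) {
  if (!is.matrix(neighbor_embs) || nrow(neighbor_embs) != length(weights))
    abort_shape("neighbor_embs must be a k x d matrix matching length(weights)")
  if (abs(sum(weights) - 1) > 1e-6)
    abort_invariant("aggregation weights must sum to 1 (softmax output)")
  as.vector(crossprod(neighbor_embs, weights))
}

#' One aggregation-layer update
#'
#' Combines an entity's own representation with its aggregated
#' neighbourhood: `activation(W (self + agg) + b)`. Hidden layers use
#' ReLU; the last layer uses `final_activation` (tanh by default, see
#' [init_params()]).
#'
#' @param self_emb,agg_emb numeric vectors of length d
#' @param W d x d transform matrix
#' @param b bias vector of length d
#' @param is_last is this the final (hop-0) update?
#' @param final_activation activation used when `is_last`
#' @return numeric vector of length d
#' @export
layer_update <- function(self_emb, agg_emb, W, b, is_last = FALSE,
                         final_activation = "tanh") {
  d <- length(self_emb)
  if (length(agg_emb) != d || !is.matrix(W) || any(dim(W) != d) || length(b) != d)
    abort_shape("layer_update: dimension mismatch")
  z <- as.vector(W %*% (self_emb + agg_emb)) + b
  activate(z, is_last, final_activation)
}

activate <- function(z, is_last, final_activation) {
  if (!is_last || identical(final_activation, "relu")) pmax(z, 0) else tanh(z)
}

as_matrix_d <- function(x, d, what) {
  if (!is.matrix(x)) x <- matrix(x, ncol = d)
  if (ncol(x) != d) abort_shape(sprintf("%s must have %d columns", what, d))
  x
}

#' Encode one gene from its receptive field
#'
#' Runs the full message-passing encoder for a single gene: relation
#' scores conditioned on the partner gene's raw embedding are softmax
#' normalised within each parent's k sampled edges, every entity
#' aggregates its children bottom-up, and H layer updates collapse the
#' field onto the hop-0 gene, whose final vector is returned.
#'
#' This is the transparent per-gene reference path; training uses a
#' mathematically identical batched implementation (asserted by tests).
#'
#' @param field a [build_receptive_field()] result with `H == params$H`
#' @param partner_gene entity index of the candidate SL partner
#' @param params a [init_params()] object
#' @return encoded gene representation, numeric vector of length `params$d`
#' @export
encode_gene <- function(field, partner_gene, params) {
  H <- params$H
  if (attr(field, "H") != H)
    abort_config(sprintf("receptive field has H=%d but params have H=%d",
                         attr(field, "H"), H))
  k <- attr(field, "k")
  d <- params$d
  q <- params$entity_emb[partner_gene, ]

  # per-hop embeddings and per-hop softmax weights (one group of k per parent)
  E <- lapply(field$hop_entities, function(idx)
    params$entity_emb[idx, , drop = FALSE])
  w <- lapply(field$hop_relations, function(ridx) {
    s <- relation_scores(q, params$relation_emb[ridx, , drop = FALSE])
    group_softmax(s, k)
  })

  for (l in seq_len(H)) {
    is_last <- l == H
    E_new <- vector("list", H - l + 1L)
    for (h in seq_len(H - l + 1L)) {      # h is hop index + 1
      agg <- group_weighted_sum(E[[h + 1L]], w[[h]], k)
      X <- E[[h]] + agg
      Z <- X %*% t(params$W[[l]]) + rep(params$b[[l]], each = nrow(X))
      E_new[[h]] <- activate(Z, is_last, params$final_activation)
    }
    E <- E_new
  }
  as.vector(E[[1L]])
}

# softmax within consecutive groups of k; asserts normalisation on exit
group_softmax <- function(s, k) {
  m <- matrix(s, nrow = k)
  m <- exp(sweep(m, 2L, apply(m, 2L, max)))
  m <- sweep(m, 2L, colSums(m), "/")
  w <- as.vector(m)
  check_softmax_groups(w, k)
  w
}

check_softmax_groups <- function(w, k) {
  sums <- colSums(matrix(w, nrow = k))
  if (max(abs(sums - 1)) > 1e-6)
    abort_invariant("softmax weights failed to normalise within a neighbourhood")
  invisible(TRUE)
}

# rows of E summed in consecutive groups of k with elementwise weights w
group_weighted_sum <- function(E, w, k) {
  n <- nrow(E)
  a <- array(E * w, c(k, n %/% k, ncol(E)))
  colSums(a, dims = 1L)
}

#' Score a gene pair
#'
#' The SL score of a pair is the sigmoid of the inner product of the two
#' encoded gene representations; the predicted label applies the 0.5
#' threshold. Symmetric in its arguments.
#'
#' @param enc_a,enc_b encoded gene vectors of equal length
#' @return object of class `pair_score`: list with `logit`, `probability`,
#'   `predicted_label`
#' @export
score_pair <- function(enc_a, enc_b) {
  if (length(enc_a) != length(enc_b)) abort_shape("encoded genes differ in length")
  logit <- sum(enc_a * enc_b)
  p <- stats::plogis(logit)
  structure(list(logit = logit, probability = p,
                 predicted_label = as.integer(p >= 0.5)),
            class = "pair_score")
}

#' @export
print.pair_score <- function(x, ...) {
  cat(sprintf("<pair_score> logit %.4f, probability %.4f, label@0.5 = %d\n",
              x$logit, x$probability, x$predicted_label))
  invisible(x)
}
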