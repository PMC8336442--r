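test_that("init_params is deterministic, Glorot-bounded, with zero biases", {
  p1 <- init_params(10L, 4L, d = 4L, H = 2L, seed = 0L)
  p2 <- init_params(10L, 4L, d = 4L, H = 2L, seed = 0L)
  expect_identical(p1, p2)

  expect_equal(dim(p1$entity_emb), c(10L, 4L))
  expect_true(all(abs(p1$entity_emb) <= sqrt(6 / (10 + 4))))
  expect_true(all(abs(p1$W[[1L]]) <= sqrt(6 / 8)))
  expect_identical(p1$b[[1L]], numeric(4L))
  expect_identical(p1$b[[2L]], numeric(4L))

  expect_error(init_params(10L, 4L, d = 0L), class = "slkgnn_config_error")
  expect_error(init_params(10L, 4L, d = 4L, H = 0L), class = "slkgnn_config_error")
})

test_that("relation_scores computes partner-relation inner products", {
  expect_equal(relation_scores(c(1, 0), rbind(c(2, 5), c(0, 3))), c(2, 0))
  expect_equal(relation_scores(c(0, 0), matrix(rnorm(10), 5, 2)), rep(0, 5))

  set.seed(4)
  q <- rnorm(16); R <- matrix(rnorm(8 * 16), 8, 16)
  loop <- vapply(1:8, function(i) {
    acc <- 0
    for (t in 1:16) acc <- acc + q[t] * R[i, t]
    acc
  }, 0)
  expect_equal(relation_scores(q, R), loop, tolerance = 1e-12)

  expect_error(relation_scores(c(1, 2, 3), matrix(1, 2, 2)),
               class = "slkgnn_shape_error")
})

test_that("normalize_scores is a stable softmax", {
  expect_equal(normalize_scores(c(0, 0, 0, 0)), rep(0.25, 4))
  expect_equal(normalize_scores(c(log(2), 0)), c(2 / 3, 1 / 3))
  big <- normalize_scores(c(1000, 0))
  expect_true(all(is.finite(big)))
  expect_equal(sum(big), 1)
  expect_gt(big[1L], 1 - 1e-10)
  expect_error(normalize_scores(c(NaN, 1)), class = "slkgnn_numeric_error")
})

test_that("aggregate_neighborhood is the weighted average of rows", {
  expect_equal(aggregate_neighborhood(rbind(c(1, 0), c(0, 1)), c(0.5, 0.5)),
               c(0.5, 0.5))
  E <- matrix(rnorm(12), 4, 3)
  w <- c(0, 0, 1, 0)
  expect_equal(aggregate_neighborhood(E, w), E[3L, ])

  set.seed(5)
  w <- normalize_scores(rnorm(4))
  loop <- numeric(3)
  for (i in 1:4) loop <- loop + w[i] * E[i, ]
  expect_equal(aggregate_neighborhood(E, w), loop, tolerance = 1e-12)

  expect_error(aggregate_neighborhood(E, c(0.5, 0.5)), class = "slkgnn_shape_error")
  expect_error(aggregate_neighborhood(E, c(0.4, 0.2, 0.2, 0.1)),
               class = "slkgnn_invariant_error")
})

test_that("layer_update applies W(self + agg) + b with the right activation", {
  I2 <- diag(2)
  expect_equal(layer_update(c(1, -1), c(0, 0), I2, c(0, 0)), c(1, 0))
  b <- c(0.3, -0.7)
  expect_equal(layer_update(c(1, 2), c(3, 4), matrix(0, 2, 2), b), pmax(b, 0))
  expect_equal(layer_update(c(1, -1), c(-1, 1), I2, c(0, 0), is_last = TRUE),
               c(0, 0))   # tanh(0) = 0
  expect_equal(layer_update(c(0.5, 0), c(0, 0), I2, c(0, 0), is_last = TRUE),
               tanh(c(0.5, 0)))
  expect_error(layer_update(c(1, 2), c(1, 2), diag(3), c(0, 0)),
               class = "slkgnn_shape_error")
})

test_that("encode_gene reproduces a hand-walked 2-node example (H=1, k=1)", {
  kg <- tiny_kg()
  g1 <- match("g1", kg$entities$raw_id)
  g2 <- match("g2", kg$entities$raw_id)
  p1 <- match("p1", kg$entities$raw_id)
  params <- init_params(nrow(kg$entities), length(kg$relations), d = 2L, H = 1L,
                        seed = 8L)
  # force the field to the participates edge g2 - p1
  field <- structure(list(hop_entities = list(g2, p1),
                          hop_relations = list(match("participates", kg$relations))),
                     class = "receptive_field", k = 1L, H = 1L, gene = g2)
  enc <- encode_gene(field, g1, params)
  # hand walk: softmax of one score = 1, agg = p1's embedding,
  # update = tanh(W (e_g2 + e_p1) + b)
  expected <- tanh(as.vector(params$W[[1L]] %*%
                               (params$entity_emb[g2, ] + params$entity_emb[p1, ])) +
                     params$b[[1L]])
  expect_equal(enc, expected, tolerance = 1e-12)
})

test_that("zero parameters propagate to a zero encoding", {
  w <- small_world(seed = 23L)
  params <- init_params(nrow(w$kg$entities), length(w$kg$relations),
                        d = 4L, H = 2L, seed = 1L)
  params$entity_emb[] <- 0
  params$relation_emb[] <- 0
  genes <- kg_entities_of_type(w$kg, "gene")
  f <- build_receptive_field(w$kg, genes[1L], sampler_config(3L, 2L, seed = 2L))
  expect_equal(encode_gene(f, genes[2L], params), rep(0, 4L))
})

test_that("encoding is invariant to permuting a parent's sampled children", {
  w <- small_world(seed = 29L)
  genes <- kg_entities_of_type(w$kg, "gene")
  params <- init_params(nrow(w$kg$entities), length(w$kg$relations),
                        d = 4L, H = 2L, seed = 3L)
  f <- build_receptive_field(w$kg, genes[1L], sampler_config(3L, 2L, seed = 4L))
  enc0 <- encode_gene(f, genes[2L], params)
  set.seed(6)
  for (rep in 1:5) {
    g <- f
    # permute hop-1 children together with their relations and subtrees
    perm <- sample(3L)
    g$hop_entities[[2L]] <- f$hop_entities[[2L]][perm]
    g$hop_relations[[1L]] <- f$hop_relations[[1L]][perm]
    blocks <- function(x, p) as.vector(matrix(x, ncol = 3L)[, p])
    g$hop_entities[[3L]] <- blocks(f$hop_entities[[3L]], perm)
    g$hop_relations[[2L]] <- blocks(f$hop_relations[[2L]], perm)
    expect_equal(encode_gene(g, genes[2L], params), enc0, tolerance = 1e-9)
  }
})

test_that("score_pair applies the sigmoid inner product and 0.5 threshold", {
  s <- score_pair(c(0, 0), c(1, 2))
  expect_equal(s$logit, 0)
  expect_equal(s$probability, 0.5)
  expect_equal(s$predicted_label, 1L)   # >= 0.5 rule

  s <- score_pair(c(1, 1), c(1, 1))
  expect_equal(s$logit, 2)
  expect_equal(s$probability, 1 / (1 + exp(-2)))

  a <- rnorm(8); b <- rnorm(8)
  expect_identical(score_pair(a, b), score_pair(b, a))
  expect_error(score_pair(1:3, 1:2), class = "slkgnn_shape_error")
})

test_that("checkpoints round-trip parameters bit-exactly and validate shapes", {
  w <- small_world(seed = 31L)
  params <- init_params(nrow(w$kg$entities), length(w$kg$relations),
                        d = 4L, H = 2L, seed = 5L)
  dir <- withr::local_tempdir()
  cfg <- train_config(k = 3L, d = 4L, H = 2L, seed = 5L)
  save_checkpoint(params, w$kg, dir, cfg = cfg)
  ck <- load_checkpoint(dir, w$kg)
  expect_equal(ck$params$entity_emb, params$entity_emb)
  expect_equal(ck$params$W[[2L]], params$W[[2L]])
  expect_equal(ck$config$k, 3L)

  # vocabulary mismatch is caught
  other <- small_world(n_genes = 12L, seed = 32L)
  expect_error(load_checkpoint(dir, other$kg), class = "slkgnn_integrity_error")
})
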