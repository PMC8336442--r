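write_kg_files <- function(ent, trp, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  ep <- file.path(dir, "entities.tsv")
  tp <- file.path(dir, "triplets.tsv")
  utils::write.table(ent, ep, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(trp, tp, sep = "\t", quote = FALSE, row.names = FALSE)
  list(entities = ep, triplets = tp)
}

test_that("load_kg assigns contiguous indices, drops isolated nodes and symmetrises", {
  p <- write_kg_files(
    data.frame(entity_id = c("g1", "g2", "p1"),
               entity_type = c("gene", "gene", "pathway")),
    data.frame(head_id = "g1", relation = "participates", tail_id = "p1"))
  kg <- suppressMessages(load_kg(p$triplets, p$entities))

  expect_equal(nrow(kg$entities), 2L)             # g2 removed as isolated
  expect_false("g2" %in% kg$entities$raw_id)
  expect_equal(kg$relations, "participates")
  g1 <- match("g1", kg$entities$raw_id)
  p1 <- match("p1", kg$entities$raw_id)
  expect_equal(kg_neighbors(kg, g1), list(entity = p1, relation = 1L))
  expect_equal(kg_neighbors(kg, p1), list(entity = g1, relation = 1L))
})

test_that("load_kg reports format, integrity and empty-input errors", {
  dir <- withr::local_tempdir()
  p <- write_kg_files(
    data.frame(entity_id = c("g1", "gY"), entity_type = c("gene", "gene")),
    data.frame(head_id = "g1", relation = "binds", tail_id = "gX"), dir)
  expect_error(load_kg(p$triplets, p$entities), "gX",
               class = "slkgnn_integrity_error")

  bad <- file.path(dir, "bad.tsv")
  utils::write.table(data.frame(h = "g1", relation = "r", tail_id = "gY"),
                     bad, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_kg(bad, p$entities), "head_id",
               class = "slkgnn_format_error")

  empty <- file.path(dir, "empty.tsv")
  writeLines("head_id\trelation\ttail_id", empty)
  expect_error(load_kg(empty, p$entities), class = "slkgnn_empty_error")
})

test_that("a 24-relation-type fixture yields exactly 24 relation types", {
  rels <- sprintf("rel%02d", 1:24)
  ent <- data.frame(entity_id = c("g1", sprintf("x%02d", 1:24)),
                    entity_type = c("gene", rep("pathway", 24)))
  trp <- data.frame(head_id = "g1", relation = rels,
                    tail_id = sprintf("x%02d", 1:24))
  p <- write_kg_files(ent, trp)
  kg <- suppressMessages(load_kg(p$triplets, p$entities))
  expect_length(kg$relations, 24L)
})

test_that("self-loops are dropped with a warning and duplicates collapsed", {
  ent <- data.frame(entity_id = c("g1", "g2"), entity_type = c("gene", "gene"))
  trp <- data.frame(head_id = c("g1", "g1", "g1"),
                    relation = c("interacts", "interacts", "interacts"),
                    tail_id = c("g1", "g2", "g2"))
  expect_warning(kg <- suppressMessages(knowledge_graph(ent, trp)), "self-loop")
  expect_equal(nrow(kg$triplets), 1L)
})

test_that("write_kg / load_kg round-trips a generated graph", {
  w <- small_world(seed = 11L)
  dir <- withr::local_tempdir()
  tp <- file.path(dir, "t.tsv"); ep <- file.path(dir, "e.tsv")
  write_kg(w$kg, tp, ep)
  kg2 <- suppressMessages(load_kg(tp, ep))
  expect_identical(kg2$entities, w$kg$entities)
  expect_identical(kg2$relations, w$kg$relations)
  # triplet sets identical up to row order
  key <- function(k) sort(paste(k$triplets$head, k$triplets$relation, k$triplets$tail))
  expect_identical(key(kg2), key(w$kg))
})

test_that("neighbour index is symmetric and indices form a bijection", {
  w <- small_world(seed = 21L)
  kg <- w$kg
  n <- nrow(kg$entities)
  expect_identical(sort(unique(c(kg$triplets$head, kg$triplets$tail))),
                   seq_len(n))   # no gaps, all entities touched
  for (i in seq_len(nrow(kg$triplets))) {
    tr <- kg$triplets[i, ]
    nh <- kg_neighbors(kg, tr$head)
    nt <- kg_neighbors(kg, tr$tail)
    expect_true(any(nh$entity == tr$tail & nh$relation == tr$relation))
    expect_true(any(nt$entity == tr$head & nt$relation == tr$relation))
  }
  expect_true(all(kg_degree(kg = kg) >= 1L))
})

test_that("load_sl_pairs deduplicates unordered pairs and drops self-pairs", {
  kg <- tiny_kg()
  dir <- withr::local_tempdir()
  f <- file.path(dir, "pairs.csv")
  writeLines(c("gene_a,gene_b", "g1,g2", "g2,g1", "g1,g2"), f)
  pairs <- load_sl_positives(f, kg)
  expect_equal(nrow(pairs), 1L)
  expect_true(all(pairs$label == 1L))
  expect_lt(pairs$gene_a, pairs$gene_b)

  writeLines(c("gene_a,gene_b", "g1,g1", "g1,g2"), f)
  expect_warning(pairs <- load_sl_positives(f, kg), "self-pair")
  expect_equal(nrow(pairs), 1L)

  writeLines(c("gene_a,gene_b", "g1,p1"), f)
  expect_error(load_sl_positives(f, kg), "p1", class = "slkgnn_type_error")

  writeLines(c("gene_a,gene_b", "g1,gZ"), f)
  expect_error(load_sl_positives(f, kg), "gZ", class = "slkgnn_integrity_error")
})

test_that("sample_negatives is balanced, disjoint from positives and reproducible", {
  set.seed(1)
  universe <- 1:100
  pos <- canonical_pairs(sample(universe, 10), sample(universe, 10))
  pos <- pos[pos$gene_a != pos$gene_b, ][1:8, ]
  pos$label <- 1L
  neg1 <- sample_negatives(pos, universe, seed = 7L)
  neg2 <- sample_negatives(pos, universe, seed = 7L)
  expect_identical(neg1, neg2)
  expect_equal(nrow(neg1), nrow(pos))
  expect_true(all(neg1$label == 0L))
  kp <- pair_key(pos$gene_a, pos$gene_b, 100L)
  kn <- pair_key(neg1$gene_a, neg1$gene_b, 100L)
  expect_length(intersect(kp, kn), 0L)
  expect_false(anyDuplicated(kn) > 0L)
  # different seeds give different draws
  expect_false(identical(neg1, sample_negatives(pos, universe, seed = 8L)))
})

test_that("sample_negatives raises a capacity error when no unknown pairs remain", {
  pos <- data.frame(gene_a = c(1L, 1L, 2L), gene_b = c(2L, 3L, 3L), label = 1L)
  expect_error(sample_negatives(pos, 1:3, seed = 1L),
               class = "slkgnn_capacity_error")
})

test_that("split_dataset uses floor-based sizes with the remainder in test", {
  mk <- function(n) data.frame(gene_a = seq_len(n), gene_b = seq_len(n) + n,
                               label = rep_len(c(0L, 1L), n))
  d100 <- suppressMessages(split_dataset(mk(100), c(0.8, 0.1, 0.1), seed = 4L))
  expect_equal(as.vector(table(d100$split)), c(80L, 10L, 10L))
  d101 <- suppressMessages(split_dataset(mk(101), c(0.8, 0.1, 0.1), seed = 4L))
  expect_equal(as.vector(table(d101$split)), c(80L, 10L, 11L))

  again <- suppressMessages(split_dataset(mk(100), c(0.8, 0.1, 0.1), seed = 4L))
  expect_identical(again$split, d100$split)
  expect_identical(again$pairs, d100$pairs)

  expect_error(split_dataset(mk(100), c(1, 0, 0), seed = 1L),
               class = "slkgnn_config_error")
  expect_error(split_dataset(mk(100), c(0.5, 0.2, 0.2), seed = 1L),
               class = "slkgnn_config_error")
})
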