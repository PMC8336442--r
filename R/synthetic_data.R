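#' Specification of a synthetic SL corpus
#'
#' Describes a schema-faithful synthetic world in which SL labels are
#' driven by *shared latent factors*: each gene participates in a few
#' mechanism-like entities (biological processes), and a gene pair is
#' synthetic-lethal with high probability when the two genes share at
#' least one factor. Decoy entities (compounds, diseases) and decoy
#' relation types are wired to genes at comparable density but carry no
#' label information, so they exercise the relation-weighting machinery
#' without rewarding it. Factor popularity is skewed (Zipf-like) to mimic
#' the hub-degree heterogeneity of real biomedical knowledge graphs.
#'
#' The defaults (300 genes, 30 factors, 2 factors per gene, 200
#' distractors, 6 relation types, 3000 balanced pairs, p(SL | shared
#' factor) = 0.9 vs 0.02 otherwise) give a corpus where factor sharing is
#' strongly informative but not deterministic, at desk-test scale.
#'
#' @param n_genes number of gene entities
#' @param n_factors number of latent mechanism entities (>= 2)
#' @param n_distractor_entities number of decoy entities
#' @param factors_per_gene factors drawn (without replacement) per gene
#' @param n_relation_types total relation types: one gene-participates-
#'   factor type plus decoys (>= 2)
#' @param p_pos_shared P(SL = 1) for pairs sharing >= 1 factor
#' @param p_pos_unshared P(SL = 1) for pairs sharing none
#' @param n_pairs total labelled pairs (balanced; must be even)
#' @param seed integer seed
#' @return list of class `synthetic_spec`
#' @export
synthetic_spec <- function(n_genes = 300L, n_factors = 30L,
                           n_distractor_entities = 200L,
                           factors_per_gene = 2L, n_relation_types = 6L,
                           p_pos_shared = 0.9, p_pos_unshared = 0.02,
                           n_pairs = 3000L, seed = 0L) {
  if (n_factors < 2L) abort_config("n_factors must be >= 2")
  if (factors_per_gene < 1L || factors_per_gene > n_factors)
    abort_config("factors_per_gene must be in 1..n_factors")
  if (!(p_pos_unshared >= 0 && p_pos_unshared < p_pos_shared && p_pos_shared <= 1))
    abort_config("need 0 <= p_pos_unshared < p_pos_shared <= 1")
  if (n_relation_types < 2L) abort_config("n_relation_types must be >= 2")
  if (n_pairs %% 2L != 0L) abort_config("n_pairs must be even (balanced corpus)")
  structure(list(n_genes = as.integer(n_genes), n_factors = as.integer(n_factors),
                 n_distractor_entities = as.integer(n_distractor_entities),
                 factors_per_gene = as.integer(factors_per_gene),
                 n_relation_types = as.integer(n_relation_types),
                 p_pos_shared = p_pos_shared, p_pos_unshared = p_pos_unshared,
                 n_pairs = as.integer(n_pairs), seed = seed),
            class = "synthetic_spec")
}

decoy_relation_names <- function(n) {
  pool <- c("binds", "associates", "expresses", "upregulates", "downregulates",
            "resembles", "treats", "palliates", "localizes", "covaries")
  if (n > length(pool)) abort_config(sprintf("at most %d relation types supported",
                                             length(pool) + 1L))
  pool[seq_len(n)]
}

decoy_entity_types <- c("compound", "disease", "anatomy")

#' Generate a synthetic knowledge graph with planted gene-factor structure
#'
#' Every gene is linked to `factors_per_gene` factors via the
#' `participates` relation; factors are drawn with Zipf-skewed popularity
#' so some factors are hubs. Each distractor entity is wired to 1 +
#' Poisson(2) random genes through a random decoy relation type. The
#' result satisfies every knowledge-graph invariant (no isolated nodes,
#' symmetric neighbour index, contiguous indices).
#'
#' @param spec a [synthetic_spec()]
#' @return list with `kg` (a [knowledge_graph()]) and `assignment` (named
#'   list: for each gene raw id, the integer factor ids it participates in)
#' @export
generate_kg <- function(spec) {
  with_seed(spec$seed, {
    gene_ids <- sprintf("g%04d", seq_len(spec$n_genes))
    factor_ids <- sprintf("bp%03d", seq_len(spec$n_factors))
    dis_ids <- if (spec$n_distractor_entities > 0L)
      sprintf("dx%04d", seq_len(spec$n_distractor_entities)) else character(0)

    zipf <- 1 / seq_len(spec$n_factors)
    assignment <- lapply(seq_len(spec$n_genes), function(i)
      sort(sample.int(spec$n_factors, spec$factors_per_gene, prob = zipf)))
    names(assignment) <- gene_ids

    gf <- data.frame(
      head_id = rep(gene_ids, each = spec$factors_per_gene),
      relation = "participates",
      tail_id = factor_ids[unlist(assignment, use.names = FALSE)])

    decoys <- decoy_relation_names(spec$n_relation_types - 1L)
    dd <- NULL
    if (spec$n_distractor_entities > 0L) {
      deg <- 1L + stats::rpois(spec$n_distractor_entities, 2)
      dd <- data.frame(
        head_id = rep(dis_ids, deg),
        relation = decoys[sample.int(length(decoys), sum(deg), replace = TRUE)],
        tail_id = gene_ids[sample.int(spec$n_genes, sum(deg), replace = TRUE)])
      dd <- dd[!duplicated(dd), , drop = FALSE]
    }

    ent <- data.frame(
      entity_id = c(gene_ids, factor_ids, dis_ids),
      entity_type = c(rep("gene", spec$n_genes),
                      rep("biological_process", spec$n_factors),
                      decoy_entity_types[1L + (seq_len(spec$n_distractor_entities) - 1L) %%
                                           length(decoy_entity_types)]))

    kg <- suppressMessages(knowledge_graph(ent, rbind(gf, dd)))
    # factors never drawn under the skew are removed as isolated; drop them
    # from the assignment view too (cannot happen for genes, which always
    # carry their participates edges)
    kept <- factor_ids[factor_ids %in% kg$entities$raw_id]
    assignment <- lapply(assignment, function(f) f[factor_ids[f] %in% kept])
    list(kg = kg, assignment = assignment)
  })
}

shares_factor <- function(assignment, id_a, id_b) {
  vapply(seq_along(id_a), function(i)
    length(intersect(assignment[[id_a[i]]], assignment[[id_b[i]]])) > 0L,
    logical(1))
}

#' Plant SL labels driven by factor sharing
#'
#' Samples candidate unordered gene pairs uniformly and labels each
#' positive with probability `p_pos_shared` when the genes share a factor
#' and `p_pos_unshared` otherwise, then keeps exactly `n_pairs / 2`
#' positives and negatives (rejection sampling) and splits 8:1:1.
#'
#' @param kg the [generate_kg()] graph (supplies gene entity indices)
#' @param assignment the gene-to-factor map from [generate_kg()]
#' @param spec the same [synthetic_spec()]
#' @param seed integer seed (labelling and splitting; defaults to
#'   `spec$seed + 1`)
#' @return an `sl_dataset` (see [split_dataset()]) with balanced labels
#' @export
plant_sl_labels <- function(kg, assignment, spec, seed = NULL) {
  seed <- seed %||% (spec$seed + 1L)
  genes <- kg_entities_of_type(kg, "gene")
  ids <- kg$entities$raw_id
  n_half <- spec$n_pairs %/% 2L
  with_seed(seed, {
    pos <- neg <- list()
    n_pos <- n_neg <- 0L
    seen <- numeric(0)
    drawn <- 0L
    limit <- 100L * spec$n_pairs
    while ((n_pos < n_half || n_neg < n_half) && drawn < limit) {
      m <- 4L * spec$n_pairs
      drawn <- drawn + m
      a <- genes[sample.int(length(genes), m, replace = TRUE)]
      b <- genes[sample.int(length(genes), m, replace = TRUE)]
      ok <- a != b
      a <- a[ok]; b <- b[ok]
      key <- pair_key(a, b, nrow(kg$entities))
      keep <- !(key %in% seen) & !duplicated(key)
      a <- a[keep]; b <- b[keep]
      seen <- c(seen, key[keep])
      sh <- shares_factor(assignment, ids[a], ids[b])
      p <- ifelse(sh, spec$p_pos_shared, spec$p_pos_unshared)
      lab <- as.integer(stats::runif(length(p)) < p)
      df <- canonical_pairs(a, b)
      df$label <- lab
      pos[[length(pos) + 1L]] <- df[df$label == 1L, , drop = FALSE]
      neg[[length(neg) + 1L]] <- df[df$label == 0L, , drop = FALSE]
      n_pos <- n_pos + sum(lab == 1L)
      n_neg <- n_neg + sum(lab == 0L)
    }
    if (n_pos < n_half || n_neg < n_half)
      abort_capacity(paste0(
        "could not reach the requested pair counts within 100x oversampling; ",
        "increase n_genes or lower n_pairs"))
    pairs <- rbind(utils::head(do.call(rbind, pos), n_half),
                   utils::head(do.call(rbind, neg), n_half))
    rownames(pairs) <- NULL
    suppressMessages(split_dataset(pairs, c(0.8, 0.1, 0.1),
                                   seed = sample.int(2^30, 1L)))
  })
}

#' Degree-preserving knowledge-graph edge shuffle (ablation control)
#'
#' Permutes the tail endpoints of the triplets uniformly *within each
#' relation type*, preserving the graph size, every node's degree and the
#' per-type edge counts while destroying the gene-factor semantics that
#' carry the planted SL signal. Training on the shuffled graph isolates
#' how much predictive performance comes from knowledge-graph content
#' rather than from SL-label memorisation.
#'
#' Permutations that would create self-loops or duplicate triplets are
#' locally re-drawn (the single-triplet degenerate case is returned
#' unchanged).
#'
#' @param kg a [knowledge_graph()]
#' @param seed integer seed
#' @return a new [knowledge_graph()] with identical entities and relation
#'   types
#' @export
shuffle_kg_edges <- function(kg, seed = NULL) {
  tri <- kg$triplets
  with_seed(seed, {
    for (r in seq_along(kg$relations)) {
      rows <- which(tri$relation == r)
      if (length(rows) < 2L) next
      tails <- tri$tail[rows][sample.int(length(rows))]
      for (attempt in seq_len(50L)) {
        key <- (tri$head[rows] - 1) * as.double(nrow(kg$entities)) + tails
        bad <- which(tri$head[rows] == tails | duplicated(key))
        if (length(bad) == 0L) break
        # reshuffle the offending tails together with as many random others
        mix <- unique(c(bad, sample.int(length(rows), min(length(rows), 2L * length(bad)))))
        tails[mix] <- tails[mix][sample.int(length(mix))]
      }
      ok <- tri$head[rows] != tails
      tri$tail[rows[ok]] <- tails[ok]   # leave any stubborn self-loop edges intact
    }
    ids <- kg$entities$raw_id
    ent <- data.frame(entity_id = ids, entity_type = kg$entities$etype)
    suppressMessages(knowledge_graph(
      ent,
      data.frame(head_id = ids[tri$head],
                 relation = kg$relations[tri$relation],
                 tail_id = ids[tri$tail])))
  })
}

#' Write a synthetic corpus to disk
#'
#' Emits the three standard interchange files (KG triplets TSV, entity
#' TSV, labelled pairs CSV) plus a JSON manifest recording the spec and
#' seed.
#'
#' @param spec a [synthetic_spec()]
#' @param dir output directory (created if needed)
#' @return invisibly, a list with the generated `kg`, `dataset`,
#'   `assignment` and the file `paths`
#' @export
simulate_corpus <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_kg(spec)
  data <- plant_sl_labels(gen$kg, gen$assignment, spec)
  paths <- list(triplets = file.path(dir, "kg_triplets.tsv"),
                entities = file.path(dir, "kg_entities.tsv"),
                pairs = file.path(dir, "sl_pairs.csv"),
                manifest = file.path(dir, "manifest.json"))
  write_kg(gen$kg, paths$triplets, paths$entities)
  ids <- gen$kg$entities$raw_id
  utils::write.csv(data.frame(gene_a = ids[data$pairs$gene_a],
                              gene_b = ids[data$pairs$gene_b],
                              label = data$pairs$label),
                   paths$pairs, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(generator = "slkgnn::simulate_corpus",
                            spec = unclass(spec)),
                       paths$manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(kg = gen$kg, dataset = data, assignment = gen$assignment,
                 paths = paths))
}
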