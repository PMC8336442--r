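#' Heterogeneous knowledge graphs for synthetic-lethality prediction
#'
#' A `knowledge_graph` holds typed entities, typed directed triplets
#' (head, relation, tail) and an undirected neighbour index used for
#' receptive-field sampling. Entities and relation types carry contiguous
#' 1-based internal indices assigned deterministically (identifiers sorted
#' in the C locale), so that checkpoints are reproducible across sessions.
#'
#' Traversal is undirected: for every triplet `(h, r, t)` the neighbour
#' index records `t` (with relation `r`) among the neighbours of `h` *and*
#' `h` among the neighbours of `t`. In biomedical knowledge graphs genes
#' are predominantly tail entities (e.g. anatomy-expresses-gene), so a
#' directed-only traversal would orphan most genes. No inverse-relation
#' types are introduced.
#'
#' After construction every entity has degree >= 1: entities that appear in
#' no triplet are dropped. Duplicate triplets are collapsed to one and
#' self-loop triplets are rejected by default (the aggregation layer already
#' injects a self term).
#'
#' @param entities data.frame with character columns `entity_id` and
#'   `entity_type`.
#' @param triplets data.frame with character columns `head_id`, `relation`
#'   and `tail_id`, all ids present in `entities`.
#' @param allow_self_loops keep triplets with `head_id == tail_id` instead
#'   of dropping them.
#' @return An object of class `knowledge_graph`: a list with elements
#'   `entities` (data.frame `raw_id`, `etype`; row i is entity index i),
#'   `relations` (character vector; position is the relation index) and
#'   `triplets` (data.frame of integer indices `head`, `relation`, `tail`).
#'   The neighbour index is stored in compressed sparse form and accessed
#'   with [kg_neighbors()].
#' @seealso [load_kg()] to read the TSV interchange format, [write_kg()],
#'   [kg_neighbors()]
#' @export
knowledge_graph <- function(entities, triplets, allow_self_loops = FALSE) {
  ent <- normalize_cols(entities, list(entity_id = c("entity_id", "raw_id"),
                                       entity_type = c("entity_type", "etype")),
                        "entity table")
  trp <- normalize_cols(triplets, list(head_id = c("head_id", "head"),
                                       relation = c("relation", "relation_name"),
                                       tail_id = c("tail_id", "tail")),
                        "triplet table")
  if (nrow(ent) == 0L) abort_empty("entity table is empty")
  if (nrow(trp) == 0L) abort_empty("triplet table is empty")
  if (anyDuplicated(ent$entity_id))
    abort_format(sprintf("duplicate entity id '%s' in entity table",
                         ent$entity_id[duplicated(ent$entity_id)][1L]))

  known <- ent$entity_id
  bad <- setdiff(unique(c(trp$head_id, trp$tail_id)), known)
  if (length(bad))
    abort_integrity(sprintf("triplet references unknown entity id '%s'", bad[1L]))

  if (!allow_self_loops) {
    loops <- trp$head_id == trp$tail_id
    if (any(loops)) {
      warning(sprintf("dropped %d self-loop triplet(s)", sum(loops)), call. = FALSE)
      trp <- trp[!loops, , drop = FALSE]
      if (nrow(trp) == 0L) abort_empty("no triplets remain after self-loop removal")
    }
  }

  key <- paste(trp$head_id, trp$relation, trp$tail_id, sep = "\r")
  if (anyDuplicated(key)) {
    message(sprintf("collapsed %d duplicate triplet(s)", sum(duplicated(key))))
    trp <- trp[!duplicated(key), , drop = FALSE]
  }

  used <- unique(c(trp$head_id, trp$tail_id))
  n_iso <- sum(!(ent$entity_id %in% used))
  if (n_iso > 0L) {
    message(sprintf("removed %d isolated entit%s", n_iso, if (n_iso == 1L) "y" else "ies"))
    ent <- ent[ent$entity_id %in% used, , drop = FALSE]
  }

  raw_id <- sort(ent$entity_id, method = "radix")
  etype <- ent$entity_type[match(raw_id, ent$entity_id)]
  relations <- sort(unique(trp$relation), method = "radix")

  tri <- data.frame(head = match(trp$head_id, raw_id),
                    relation = match(trp$relation, relations),
                    tail = match(trp$tail_id, raw_id))

  kg <- structure(list(entities = data.frame(raw_id = raw_id, etype = etype,
                                             stringsAsFactors = FALSE),
                       relations = relations,
                       triplets = tri),
                  class = "knowledge_graph")
  kg$adj <- build_adjacency(tri, nrow(kg$entities))
  kg
}

# Undirected adjacency in compressed sparse row layout:
# neighbours of entity e are nbr[(ptr[e]+1):ptr[e+1]] with relations rel[...].
build_adjacency <- function(tri, n_entities) {
  node <- c(tri$head, tri$tail)
  nbr <- c(tri$tail, tri$head)
  rel <- c(tri$relation, tri$relation)
  ord <- order(node, method = "radix")
  deg <- tabulate(node, nbins = n_entities)
  list(ptr = c(0L, cumsum(deg)), nbr = nbr[ord], rel = rel[ord])
}

normalize_cols <- function(df, wanted, what) {
  out <- list()
  for (target in names(wanted)) {
    hit <- intersect(wanted[[target]], names(df))
    if (length(hit) == 0L)
      abort_format(sprintf("%s is missing required column '%s'", what, target))
    out[[target]] <- as.character(df[[hit[1L]]])
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' @export
print.knowledge_graph <- function(x, ...) {
  cat(sprintf("<knowledge_graph> %d entities (%d types), %d relation types, %d triplets\n",
              nrow(x$entities), length(unique(x$entities$etype)),
              length(x$relations), nrow(x$triplets)))
  invisible(x)
}

#' Neighbours of an entity
#'
#' Returns the undirected neighbour list of one entity: every entity
#' reachable over a triplet touching `entity`, paired with the relation
#' type on that edge.
#'
#' @param kg a [knowledge_graph()]
#' @param entity internal entity index (1-based)
#' @return list with integer vectors `entity` and `relation`
#' @export
kg_neighbors <- function(kg, entity) {
  ptr <- kg$adj$ptr
  idx <- seq.int(ptr[entity] + 1L, length.out = ptr[entity + 1L] - ptr[entity])
  list(entity = kg$adj$nbr[idx], relation = kg$adj$rel[idx])
}

kg_degree <- function(kg, entity = NULL) {
  d <- diff(kg$adj$ptr)
  if (is.null(entity)) d else d[entity]
}

#' Entity indices of a given type
#' @inheritParams kg_neighbors
#' @param etype entity type name, e.g. `"gene"`
#' @return integer vector of entity indices
#' @export
kg_entities_of_type <- function(kg, etype) which(kg$entities$etype == etype)

#' Read a knowledge graph from TSV files
#'
#' The interchange format is two UTF-8 TSV files: a triplet file with
#' header `head_id<TAB>relation<TAB>tail_id` (one triplet per line; the
#' relation column may also be named `relation_name`) and an entity file
#' with header `entity_id<TAB>entity_type`. Every id referenced by a
#' triplet must appear in the entity file.
#'
#' @param triplet_path path to the triplet TSV
#' @param entity_path path to the entity TSV
#' @param allow_self_loops passed to [knowledge_graph()]
#' @return a [knowledge_graph()]
#' @export
load_kg <- function(triplet_path, entity_path, allow_self_loops = FALSE) {
  trp <- read_tsv_checked(triplet_path, "triplet file")
  ent <- read_tsv_checked(entity_path, "entity file")
  knowledge_graph(ent, trp, allow_self_loops = allow_self_loops)
}

read_tsv_checked <- function(path, what) {
  if (!file.exists(path)) abort_format(sprintf("%s '%s' does not exist", what, path))
  df <- tryCatch(
    utils::read.delim(path, sep = "\t", quote = "", colClasses = "character",
                      check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) abort_empty(sprintf("%s '%s' is empty or unreadable: %s",
                                            what, path, conditionMessage(e))))
  if (nrow(df) == 0L) abort_empty(sprintf("%s '%s' has no rows", what, path))
  df
}

#' Write a knowledge graph to the TSV interchange format
#'
#' Triplets are written in canonical order (sorted by head id, relation,
#' tail id in the C locale) so that output is byte-stable; entities are
#' written in index order. `write_kg()` followed by [load_kg()] reproduces
#' the graph exactly.
#'
#' @inheritParams kg_neighbors
#' @param triplet_path,entity_path output file paths
#' @return `kg`, invisibly
#' @export
write_kg <- function(kg, triplet_path, entity_path) {
  ids <- kg$entities$raw_id
  tri <- data.frame(head_id = ids[kg$triplets$head],
                    relation = kg$relations[kg$triplets$relation],
                    tail_id = ids[kg$triplets$tail],
                    stringsAsFactors = FALSE)
  tri <- tri[order(tri$head_id, tri$relation, tri$tail_id, method = "radix"), ]
  utils::write.table(tri, triplet_path, sep = "\t", quote = FALSE, row.names = FALSE)
  ent <- data.frame(entity_id = ids, entity_type = kg$entities$etype)
  utils::write.table(ent, entity_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(kg)
}

# ---- SL pair corpus ---------------------------------------------------------

canonical_pairs <- function(gene_a, gene_b) {
  data.frame(gene_a = pmin(gene_a, gene_b), gene_b = pmax(gene_a, gene_b))
}

pair_key <- function(gene_a, gene_b, n) {
  (pmin(gene_a, gene_b) - 1) * as.double(n) + pmax(gene_a, gene_b)
}

#' Load labelled or positives-only SL pairs
#'
#' Reads a CSV with header `gene_a,gene_b[,label]`. Ids are resolved
#' against the knowledge graph and must name gene-type entities. When the
#' label column is absent every row is a positive. Pairs are stored
#' unordered (`gene_a < gene_b`); duplicate unordered pairs are collapsed
#' and self-pairs dropped with a warning.
#'
#' @param path CSV path
#' @param kg a [knowledge_graph()]
#' @return data.frame with integer columns `gene_a`, `gene_b`, `label`
#' @export
load_sl_pairs <- function(path, kg) {
  if (!file.exists(path)) abort_format(sprintf("pair file '%s' does not exist", path))
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (nrow(df) == 0L) abort_empty(sprintf("pair file '%s' has no rows", path))
  df <- normalize_cols_optional(df)
  a <- match(df$gene_a, kg$entities$raw_id)
  b <- match(df$gene_b, kg$entities$raw_id)
  if (anyNA(a) || anyNA(b)) {
    missing_id <- c(df$gene_a[is.na(a)], df$gene_b[is.na(b)])[1L]
    abort_integrity(sprintf("SL pair references id '%s' absent from the knowledge graph",
                            missing_id))
  }
  et <- kg$entities$etype
  non_gene <- c(df$gene_a[et[a] != "gene"], df$gene_b[et[b] != "gene"])
  if (length(non_gene))
    abort_type(sprintf("SL pair references non-gene entity '%s'", non_gene[1L]))

  label <- as.integer(df$label)
  if (any(!label %in% c(0L, 1L))) abort_format("pair labels must be 0 or 1")
  self <- a == b
  if (any(self)) {
    warning(sprintf("dropped %d self-pair(s)", sum(self)), call. = FALSE)
    a <- a[!self]; b <- b[!self]; label <- label[!self]
  }
  if (length(a) == 0L) abort_empty("no pairs remain after self-pair removal")
  out <- canonical_pairs(a, b)
  out$label <- label
  key <- pair_key(out$gene_a, out$gene_b, nrow(kg$entities))
  dup <- duplicated(key)
  if (any(dup)) out <- out[!dup, , drop = FALSE]
  rownames(out) <- NULL
  out
}

normalize_cols_optional <- function(df) {
  out <- normalize_cols(df, list(gene_a = c("gene_a", "gene_a_id"),
                                 gene_b = c("gene_b", "gene_b_id")),
                        "pair file")
  out$label <- if ("label" %in% names(df)) df[["label"]] else "1"
  out
}

#' Load positive SL pairs
#'
#' Convenience wrapper around [load_sl_pairs()] that keeps only label-1
#' rows (all rows when the file carries no label column).
#'
#' @inheritParams load_sl_pairs
#' @return data.frame `gene_a`, `gene_b`, `label` with all labels 1
#' @export
load_sl_positives <- function(path, kg) {
  df <- load_sl_pairs(path, kg)
  df <- df[df$label == 1L, , drop = FALSE]
  if (nrow(df) == 0L) abort_empty("no positive pairs in file")
  rownames(df) <- NULL
  df
}

#' Sample balanced negative pairs
#'
#' Known SL databases record far fewer negatives than positives, so a
#' balanced corpus is built by drawing unknown gene pairs uniformly at
#' random: exactly one label-0 pair per positive, sampled without
#' replacement from the unordered pairs over `universe` that are not in
#' `positives`.
#'
#' @param positives data.frame `gene_a`, `gene_b` (label-1 pairs)
#' @param universe integer vector of candidate gene entity indices
#' @param seed integer seed; identical seeds give identical draws
#' @return data.frame `gene_a`, `gene_b`, `label` with all labels 0
#' @export
sample_negatives <- function(positives, universe, seed = NULL) {
  universe <- sort(unique(as.integer(universe)))
  n_gene <- length(universe)
  if (n_gene < 2L) abort_capacity("need at least two genes to sample negative pairs")
  n_pos <- nrow(positives)
  n_all <- n_gene * (n_gene - 1) / 2
  if (n_all - n_pos < n_pos)
    abort_capacity(sprintf(
      "cannot draw %d negatives: only %.0f unknown unordered pairs available",
      n_pos, n_all - n_pos))
  m <- max(universe)
  taken <- pair_key(positives$gene_a, positives$gene_b, m)
  with_seed(seed, {
    acc_a <- integer(0); acc_b <- integer(0)
    while (length(acc_a) < n_pos) {
      draw <- max(1024L, 2L * (n_pos - length(acc_a)))
      a <- universe[sample.int(n_gene, draw, replace = TRUE)]
      b <- universe[sample.int(n_gene, draw, replace = TRUE)]
      ok <- a != b
      a <- a[ok]; b <- b[ok]
      key <- pair_key(a, b, m)
      keep <- !(key %in% taken) & !duplicated(key)
      a <- a[keep]; b <- b[keep]; key <- key[keep]
      acc_a <- c(acc_a, pmin(a, b)); acc_b <- c(acc_b, pmax(a, b))
      taken <- c(taken, key)
    }
    data.frame(gene_a = acc_a[seq_len(n_pos)], gene_b = acc_b[seq_len(n_pos)],
               label = 0L)
  })
}

#' Split an SL pair corpus into train/validation/test
#'
#' Pairs are randomly permuted under `seed` and assigned contiguously by
#' the requested fractions; split sizes are `floor(ratio * n)` for train
#' and validation with the remainder going to test. The per-split label
#' balance is reported (not enforced).
#'
#' @param pairs data.frame `gene_a`, `gene_b`, `label`
#' @param ratio length-3 numeric, positive, summing to 1 (train, valid, test)
#' @param seed integer seed
#' @return an `sl_dataset`: list with `pairs` (the permuted data.frame),
#'   `split` (factor with levels train/valid/test) and `gene_universe`
#' @export
split_dataset <- function(pairs, ratio = c(0.8, 0.1, 0.1), seed = NULL) {
  if (length(ratio) != 3L || any(ratio <= 0))
    abort_config("split ratio must be three positive fractions")
  if (abs(sum(ratio) - 1) > 1e-8) abort_config("split ratio must sum to 1")
  n <- nrow(pairs)
  if (n < 10L) abort_config("need at least 10 pairs to split")
  key <- pair_key(pairs$gene_a, pairs$gene_b, max(pairs$gene_b))
  if (anyDuplicated(key)) abort_config("duplicate unordered pairs in corpus")
  perm <- with_seed(seed, sample.int(n))
  pairs <- pairs[perm, , drop = FALSE]
  rownames(pairs) <- NULL
  n_train <- floor(ratio[1L] * n)
  n_valid <- floor(ratio[2L] * n)
  split <- factor(rep(c("train", "valid", "test"),
                      c(n_train, n_valid, n - n_train - n_valid)),
                  levels = c("train", "valid", "test"))
  bal <- vapply(levels(split), function(s) mean(pairs$label[split == s]), 0)
  message(sprintf("split %d/%d/%d; positive fraction train %.3f valid %.3f test %.3f",
                  n_train, n_valid, n - n_train - n_valid, bal[1L], bal[2L], bal[3L]))
  structure(list(pairs = pairs, split = split,
                 gene_universe = sort(unique(c(pairs$gene_a, pairs$gene_b)))),
            class = "sl_dataset")
}

#' @export
print.sl_dataset <- function(x, ...) {
  cat(sprintf("<sl_dataset> %d pairs (%d positive) over %d genes; split %s\n",
              nrow(x$pairs), sum(x$pairs$label), length(x$gene_universe),
              paste(table(x$split), collapse = "/")))
  invisible(x)
}

dataset_split <- function(data, which) {
  data$pairs[data$split == which, , drop = FALSE]
}
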