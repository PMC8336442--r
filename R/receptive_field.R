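#' Sampler configuration for receptive fields
#'
#' Receptive fields are built by sampling a fixed number `k` of neighbours
#' per entity, repeated for `H` hops, so hop `h` holds exactly `k^h`
#' entities regardless of true node degree. Low-degree nodes are sampled
#' with duplicates; high-degree hubs are subsampled. The defaults
#' (`k = 64`, `H = 2`) are the settings at which the model performs best
#' on the full-scale SL corpus; scale them down for small graphs.
#'
#' @param k neighbour sample size per hop (>= 1)
#' @param H number of hops (>= 1)
#' @param seed optional integer seed used by [build_receptive_field()]
#' @return list of class `sampler_config`
#' @export
sampler_config <- function(k = 64L, H = 2L, seed = NULL) {
  k <- as.integer(k); H <- as.integer(H)
  if (is.na(k) || k < 1L) abort_config("k must be a positive integer")
  if (is.na(H) || H < 1L) abort_config("H must be a positive integer")
  structure(list(k = k, H = H, seed = seed), class = "sampler_config")
}

#' Sample k incident edges of an entity
#'
#' Draws exactly `k` (neighbour, relation) pairs uniformly *with
#' replacement* from the undirected neighbour list of `entity`. A node
#' with fewer than `k` neighbours therefore contributes duplicates; a hub
#' is subsampled. Uses the current RNG stream.
#'
#' @param kg a [knowledge_graph()]
#' @param entity entity index with degree >= 1
#' @param k number of draws
#' @return list with integer vectors `entity` (length k) and `relation`
#'   (length k); every pair is a true incident edge
#' @export
sample_neighbors <- function(kg, entity, k) {
  ptr <- kg$adj$ptr
  deg <- ptr[entity + 1L] - ptr[entity]
  if (deg < 1L)
    abort_invariant(sprintf("entity %d has degree 0; isolated nodes must be removed",
                            entity))
  pos <- ptr[entity] + sample.int(deg, k, replace = TRUE)
  list(entity = kg$adj$nbr[pos], relation = kg$adj$rel[pos])
}

# Vectorised hop expansion: one uniform draw per (parent, slot) pair.
# parents is an integer vector; returns k draws per parent, parent-major.
sample_hop <- function(kg, parents, k) {
  ptr <- kg$adj$ptr
  m <- length(parents)
  rep_par <- rep(parents, each = k)
  deg <- ptr[rep_par + 1L] - ptr[rep_par]
  if (any(deg < 1L))
    abort_invariant("encountered degree-0 entity during sampling")
  pos <- ptr[rep_par] + floor(stats::runif(m * k) * deg) + 1L
  # guard the measure-zero case runif == 1 exactly
  pos <- pmin(pos, ptr[rep_par + 1L])
  list(entity = kg$adj$nbr[pos], relation = kg$adj$rel[pos])
}

#' Build the multi-hop receptive field of a gene
#'
#' Hop 0 is the seed gene alone; hop `h+1` is produced by sampling `k`
#' neighbours of every hop-`h` entity (in order), so hop `h` has length
#' `k^h`. The entity at position `i` of hop `h+1` was sampled from parent
#' `ceiling(i / k)` of hop `h`, and `hop_relations[[h+1]][i]` is the
#' relation type on that edge. Cycles are allowed: the seed gene may
#' reappear in deeper hops.
#'
#' @param kg a [knowledge_graph()]
#' @param gene seed gene entity index
#' @param cfg a [sampler_config()]; when `cfg$seed` is non-NULL the draw is
#'   made under that seed without disturbing the caller's RNG stream
#' @return object of class `receptive_field`: list with `hop_entities`
#'   (list of H+1 integer vectors, hop h at position h+1) and
#'   `hop_relations` (list of H integer vectors), plus attributes `k`,
#'   `H`, `gene`
#' @export
build_receptive_field <- function(kg, gene, cfg) {
  with_seed(cfg$seed, {
    hop_entities <- vector("list", cfg$H + 1L)
    hop_relations <- vector("list", cfg$H)
    hop_entities[[1L]] <- as.integer(gene)
    for (h in seq_len(cfg$H)) {
      drawn <- sample_hop(kg, hop_entities[[h]], cfg$k)
      hop_entities[[h + 1L]] <- drawn$entity
      hop_relations[[h]] <- drawn$relation
    }
    structure(list(hop_entities = hop_entities, hop_relations = hop_relations),
              class = "receptive_field", k = cfg$k, H = cfg$H, gene = as.integer(gene))
  })
}

#' @export
print.receptive_field <- function(x, ...) {
  cat(sprintf("<receptive_field> gene %d, k=%d, H=%d; hop sizes %s\n",
              attr(x, "gene"), attr(x, "k"), attr(x, "H"),
              paste(lengths(x$hop_entities), collapse = ", ")))
  invisible(x)
}

#' Dump a receptive field as an edge-list TSV for inspection
#'
#' @param field a [build_receptive_field()] result
#' @param kg the knowledge graph it was sampled from
#' @param path output TSV path (`hop`, `parent_id`, `relation`, `child_id`)
#' @return the data.frame written, invisibly
#' @export
dump_receptive_field <- function(field, kg, path) {
  k <- attr(field, "k")
  rows <- do.call(rbind, lapply(seq_along(field$hop_relations), function(h) {
    child <- field$hop_entities[[h + 1L]]
    parent <- field$hop_entities[[h]][((seq_along(child) - 1L) %/% k) + 1L]
    data.frame(hop = h,
               parent_id = kg$entities$raw_id[parent],
               relation = kg$relations[field$hop_relations[[h]]],
               child_id = kg$entities$raw_id[child])
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rows)
}

# Stack per-pair receptive fields into batch-major flat index vectors:
# element block p of hop h holds pair p's k^h entities. Used by the
# batched forward/backward pass.
stack_fields <- function(fields) {
  H <- attr(fields[[1L]], "H")
  list(
    ent = lapply(seq_len(H + 1L), function(h)
      unlist(lapply(fields, function(f) f$hop_entities[[h]]), use.names = FALSE)),
    rel = lapply(seq_len(H), function(h)
      unlist(lapply(fields, function(f) f$hop_relations[[h]]), use.names = FALSE)),
    B = length(fields), k = attr(fields[[1L]], "k"), H = H)
}
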