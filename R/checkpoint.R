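# Checkpoint format: one little-endian float64 binary file per parameter
# tensor plus a JSON sidecar recording shapes, hyper-parameters and the
# entity/relation vocabularies. Loading validates every shape against the
# sidecar.

#' Save model parameters to a checkpoint directory
#'
#' @param params a [init_params()] object
#' @param kg the [knowledge_graph()] the model was trained on (vocabularies
#'   are stored so a checkpoint can be validated against a reloaded graph)
#' @param dir checkpoint directory (created if needed)
#' @param cfg optional [train_config()] stored alongside for provenance
#' @return `dir`, invisibly
#' @export
save_checkpoint <- function(params, kg, dir, cfg = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tensors <- checkpoint_tensors(params)
  for (nm in names(tensors)) {
    con <- file(file.path(dir, paste0(nm, ".bin")), "wb")
    writeBin(as.vector(tensors[[nm]]), con, size = 8L, endian = "little")
    close(con)
  }
  sidecar <- list(
    format = "slkgnn-checkpoint-v1",
    d = params$d, H = params$H, final_activation = params$final_activation,
    shapes = lapply(tensors, function(x) dim(x) %||% length(x)),
    entity_vocab = kg$entities$raw_id,
    relation_vocab = kg$relations,
    config = if (!is.null(cfg)) unclass(cfg) else NULL)
  jsonlite::write_json(sidecar, file.path(dir, "checkpoint.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

checkpoint_tensors <- function(params) {
  out <- list(entity_emb = params$entity_emb, relation_emb = params$relation_emb)
  for (l in seq_len(params$H)) {
    out[[sprintf("W%d", l)]] <- params$W[[l]]
    out[[sprintf("b%d", l)]] <- params$b[[l]]
  }
  out
}

#' Load model parameters from a checkpoint directory
#'
#' @param dir directory written by [save_checkpoint()]
#' @param kg optional [knowledge_graph()]; when given, its vocabularies
#'   must match the checkpoint exactly
#' @return list with `params` (a `kgnn_params`), `config` (the stored
#'   training configuration, or NULL) and the stored vocabularies
#' @export
load_checkpoint <- function(dir, kg = NULL) {
  side_path <- file.path(dir, "checkpoint.json")
  if (!file.exists(side_path))
    abort_format(sprintf("'%s' is not a checkpoint directory (no checkpoint.json)", dir))
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  if (!identical(side$format, "slkgnn-checkpoint-v1"))
    abort_format("unrecognised checkpoint format")
  read_tensor <- function(nm) {
    shape <- side$shapes[[nm]]
    path <- file.path(dir, paste0(nm, ".bin"))
    if (!file.exists(path)) abort_format(sprintf("checkpoint tensor '%s' missing", nm))
    n <- prod(shape)
    con <- file(path, "rb")
    on.exit(close(con))
    x <- readBin(con, "double", n = n + 1L, size = 8L, endian = "little")
    if (length(x) != n)
      abort_shape(sprintf("tensor '%s' has %d values, expected %d", nm, length(x), n))
    if (length(shape) == 2L) matrix(x, shape[1L], shape[2L]) else x
  }
  H <- side$H
  params <- structure(list(
    entity_emb = read_tensor("entity_emb"),
    relation_emb = read_tensor("relation_emb"),
    W = lapply(seq_len(H), function(l) read_tensor(sprintf("W%d", l))),
    b = lapply(seq_len(H), function(l) read_tensor(sprintf("b%d", l))),
    d = side$d, H = H, final_activation = side$final_activation),
    class = "kgnn_params")
  if (!is.null(kg)) {
    if (!identical(kg$entities$raw_id, side$entity_vocab) ||
        !identical(kg$relations, side$relation_vocab))
      abort_integrity("knowledge graph vocabularies do not match the checkpoint")
  }
  cfg <- side$config
  if (!is.null(cfg)) {
    cfg <- do.call(train_config, cfg[setdiff(names(cfg), character(0))])
  }
  list(params = params, config = cfg,
       entity_vocab = side$entity_vocab, relation_vocab = side$relation_vocab)
}
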