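# Fixtures are built programmatically; nothing is read from disk except
# files the tests themselves write to tempdir().

# internal helpers exercised directly by the tests
pair_key <- slkgnn:::pair_key
canonical_pairs <- slkgnn:::canonical_pairs
kg_degree <- slkgnn:::kg_degree
stack_fields <- slkgnn:::stack_fields
group_softmax <- slkgnn:::group_softmax
kgnn_batch_forward <- slkgnn:::kgnn_batch_forward
kgnn_batch_grad <- slkgnn:::kgnn_batch_grad
adam_init <- slkgnn:::adam_init
adam_step <- slkgnn:::adam_step
build_fields_by_gene <- slkgnn:::build_fields_by_gene
shares_factor_raw <- slkgnn:::shares_factor

# minimal hand-made KG: two genes, one pathway, one compound
#   g1 -participates- p1, g2 -participates- p1, c1 -binds- g1
tiny_kg <- function() {
  ent <- data.frame(entity_id = c("g1", "g2", "p1", "c1"),
                    entity_type = c("gene", "gene", "pathway", "compound"))
  trp <- data.frame(head_id = c("g1", "g2", "c1"),
                    relation = c("participates", "participates", "binds"),
                    tail_id = c("p1", "p1", "g1"))
  suppressMessages(knowledge_graph(ent, trp))
}

# path graph g - a - b - c (single relation type), for k = 1 walks
line_kg <- function() {
  ent <- data.frame(entity_id = c("g", "a", "b", "c"),
                    entity_type = c("gene", "pathway", "pathway", "pathway"))
  trp <- data.frame(head_id = c("g", "a", "b"),
                    relation = "linked",
                    tail_id = c("a", "b", "c"))
  suppressMessages(knowledge_graph(ent, trp))
}

# small synthetic world for model tests: 10 genes by default
small_world <- function(n_genes = 10L, n_factors = 3L, n_distractors = 5L,
                        n_pairs = 20L, seed = 5L) {
  spec <- synthetic_spec(n_genes = n_genes, n_factors = n_factors,
                         n_distractor_entities = n_distractors,
                         n_pairs = n_pairs, seed = seed)
  gen <- generate_kg(spec)
  list(spec = spec, kg = gen$kg, assignment = gen$assignment)
}

# medium corpus for cheap end-to-end training tests
training_world <- function(seed = 3L, n_pairs = 400L) {
  spec <- synthetic_spec(n_genes = 60L, n_factors = 8L,
                         n_distractor_entities = 40L,
                         n_pairs = n_pairs, seed = seed)
  gen <- generate_kg(spec)
  data <- suppressMessages(plant_sl_labels(gen$kg, gen$assignment, spec))
  list(spec = spec, kg = gen$kg, assignment = gen$assignment, data = data)
}

random_fields_and_params <- function(kg, k, H, d, seed) {
  set.seed(seed)
  params <- init_params(nrow(kg$entities), length(kg$relations), d = d, H = H)
  genes <- kg_entities_of_type(kg, "gene")
  list(params = params, genes = genes, sampler = sampler_config(k, H))
}

# gene-factor sharing recomputed from a (possibly shuffled) graph's
# participates edges
shares_from_kg <- function(kg, gene_a, gene_b) {
  r_part <- match("participates", kg$relations)
  fac <- function(g) {
    nb <- kg_neighbors(kg, g)
    sort(unique(nb$entity[nb$relation == r_part]))
  }
  fac_list <- lapply(seq_len(nrow(kg$entities)), fac)
  vapply(seq_along(gene_a), function(i)
    length(intersect(fac_list[[gene_a[i]]], fac_list[[gene_b[i]]])) > 0L,
    logical(1))
}

# discrete mutual information (nats) of two binary vectors
binary_mi <- function(x, y) {
  tab <- table(factor(x, c(FALSE, TRUE)), factor(y, c(0, 1))) / length(x)
  px <- rowSums(tab); py <- colSums(tab)
  mi <- 0
  for (i in 1:2) for (j in 1:2)
    if (tab[i, j] > 0) mi <- mi + tab[i, j] * log(tab[i, j] / (px[i] * py[j]))
  mi
}
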