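---
title: "Predicting synthetic lethality by knowledge-graph message passing"
author: "slkgnn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting synthetic lethality by knowledge-graph message passing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slkgnn)
```

## The problem and the model

Synthetic lethality (SL) — two genes whose joint loss kills a cell while
either single loss is tolerated — is a prime source of selective cancer
targets. Many SL pairs are not independent observations: they share
mechanisms such as DNA-repair processes or common pathways. `slkgnn`
models this directly by embedding the genes in a heterogeneous
*knowledge graph* (KG) `G = (V_e, V_r)` of typed entities and typed
triplets `(h, r, t)`, and learning gene representations by message
passing over that graph, supervised only by labelled SL pairs.

The model has three stages.

**1. Gene-specific receptive field.** Node degrees in biomedical KGs
span several orders of magnitude, so neighbourhoods are equalised by
sampling: every entity draws exactly `k` of its neighbours uniformly
*with replacement*, and the process repeats for `H` hops, giving hop
sizes `1, k, k^2, ..., k^H`. A node with fewer than `k` neighbours
contributes duplicates; a hub is subsampled. Undirected traversal is
used (relation types preserved): in schemas of this kind genes are
predominantly *tail* entities (e.g. anatomy-expresses-gene), and a
directed-only walk would leave most genes without outgoing edges.

**2. Partner-conditioned weighted aggregation.** For the candidate pair
`(i, j)`, edges inside gene `i`'s field are scored by the relation's
relevance *to the partner*: `ω = <e_j, r>`, the inner product of the
partner gene's embedding with the relation-type embedding,
softmax-normalised within each entity's `k` sampled edges. Each entity
then updates bottom-up through

```
e[h+1] = phi( W (e[h] + sum_softmax(ω) * e'[h]) + b )
```

for `H` layers; the hop-0 output is the gene representation `ê_i`.
The same machinery, with the roles of `i` and `j` exchanged, yields
`ê_j`.

**3. Decoder and loss.** The pair probability is
`ŝ = sigmoid(<ê_i, ê_j>)`, classified at 0.5. Training minimises the
summed stable cross-entropy on logits,
`J(x) = max(x, 0) − x·s + log(1 + exp(−|x|))`, plus `α` times an L2
penalty: half the squared norm of the entity- and relation-embedding
rows touched by the batch and of all layer transforms. Optimisation is
mini-batch Adam with early stopping on validation AUC (parameters of the
best epoch are restored).

## Tunable parameters

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `k` | 64 | neighbours sampled per entity per hop; the full-scale sweet spot on dense KGs. On sparse synthetic graphs (gene degree ~4) `k = 8` already covers every neighbour with duplicates. |
| `d` | 256 | embedding dimension; 32 suffices for the 30-factor synthetic world. |
| `H` | 2 | hops; 1 reaches a gene's factors, 2 additionally reaches co-member genes. |
| `learning_rate` | 0.002 | Adam step size. |
| `l2_alpha` | 0.0039 | L2 weight; balances fit against embedding-norm growth. |
| `batch_size` | 256 | unspecified upstream; conventional default, configurable. |
| `patience` | 10 | epochs without validation-AUC improvement before stopping. |
| `final_activation` | `tanh` | see "Numerical choices". |

All randomness flows from explicit integer seeds (`train_config(seed=)`,
`sampler_config(seed=)`, `synthetic_spec(seed=)`); identical seeds give
bit-identical training histories in single-threaded mode.

## The synthetic world

`generate_kg()` plants a known mechanism: every gene participates in
`factors_per_gene = 2` of `n_factors = 30` latent biological-process
entities (Zipf-skewed popularity, producing hub heterogeneity), and 200
decoy entities of other types attach to random genes through five decoy
relation types at comparable density. `plant_sl_labels()` samples
unordered gene pairs and labels them SL with probability 0.9 when the
genes share a factor and 0.02 otherwise, then balances to 1500/1500 and
splits 8:1:1. With 300 genes these defaults make factor sharing strongly
informative (a "share a factor" oracle classifier reaches test AUC ≈
0.95) while each gene appears in only ~16 training pairs, keeping the KG
signal — not label memorisation — the decisive route to held-out
accuracy.

The signal is placed *only* in the KG. `shuffle_kg_edges()` permutes
tail endpoints within each relation type, preserving graph size, node
degrees and per-type edge counts while destroying gene–factor semantics;
training on the shuffled graph therefore bounds how far a model can get
from SL-label topology alone. On planted data the intact-KG model beats
its shuffled control by ≈ 0.07–0.10 AUC (the test suite requires ≥ 0.05,
seed-averaged). Note the shuffled arm does *not* fall to chance: SL
labels are assortative by factor group, so the training pairs themselves
carry recoverable structure — the same reason SL-graph-only baselines
are competitive on real corpora.

What the generator does **not** emulate: real ontology semantics, the
24-relation catalogue of real SL KGs, realistic degree distributions
beyond a one-parameter skew, or noise in the SL labels themselves. A
green test certifies that the implementation recovers a planted
multi-hop relational signal and that its advantage disappears under the
shuffle control — not that the model attains any particular accuracy on
a real corpus.

## Numerical choices

* **Loss input.** The stable cross-entropy form is algebraically the
  binary cross-entropy *on logits*; the raw inner product is therefore
  fed to the loss by default. Reading the decoder output (the sigmoid
  probability) into the same formula is exposed via
  `train_config(loss_on = "probability")` but is not the default.
* **Final activation.** With ReLU on every layer, encoded genes are
  componentwise non-negative, so every pair logit is ≥ 0, every
  probability ≥ 0.5, and the 0.5 threshold can never produce class 0.
  The final layer therefore uses `tanh` by default;
  `final_activation = "relu"` restores the uniform reading.
* **Partner conditioning** uses the partner's *raw* embedding row, not
  its encoded output — conditioning on the encoding would make each
  encoding depend on the other, a circular definition.
* **Per-layer transforms.** Each hop has its own `(W, b)` (standard
  practice); Glorot-uniform initialisation, zero biases.
* **L2 reading.** The penalty is a uniform sum of *squared* L2 norms
  (the conventional smooth weight-decay form) with a 1/2 factor; only
  embedding rows touched by the current batch decay per step, so the
  effective `α` does not scale with vocabulary size. All layer `W`
  matrices are always included; biases never.
* **Adam** uses the standard constants (β₁ = 0.9, β₂ = 0.999, ε = 1e-8)
  and dense updates (zero gradients outside touched rows), matching
  mainstream-framework semantics.
* **Resampling schedule.** Training receptive fields are re-drawn fresh
  every batch (stochastic regularisation); evaluation fields are drawn
  once per run under a fixed seed so metrics are comparable across
  epochs and bit-reproducible.
* **Softmax** is max-shifted; an always-on assertion verifies each
  neighbourhood's weights sum to 1 within 1e-6 at every aggregation
  site.
* **Negative sampling** draws unknown pairs uniformly without
  replacement, once, globally, before splitting — the corpus is one
  fixed balanced set partitioned 8:1:1 (floor-based sizes, remainder to
  test).
* **Degenerate inputs.** Isolated KG entities are removed at load;
  duplicate triplets collapse to one; self-loop triplets are dropped by
  default (the layer update already injects a self term); self SL pairs
  are dropped with a warning; single-class evaluation sets raise a
  named undefined-metric error rather than returning NaN.

## Design decisions taken where the design was open

* Sampling is uniform **with replacement for all degrees** (one code
  path; the aggregation is an expectation either way), not just for
  low-degree nodes.
* The seed gene may reappear in its own deeper hops; cycles are not
  filtered.
* Early stopping monitors validation AUC with patience 10 and restores
  the best epoch.
* Training-time resampling per batch is a choice, not an upstream
  requirement; frozen-field training is available by passing prebuilt
  fields to the internal step function.
* The backward pass is hand-derived (no autodiff framework exists in
  this environment) and is validated by finite differences (relative
  error ≤ 1e-4 on random coordinates) and by a scalar nested-loop
  reference implementation agreeing to 1e-9.

## Known limitations

* Pure-R execution: fine for desk-scale corpora (thousands of pairs,
  hundreds of entities; a full synthetic run trains in under a minute),
  but a 2M-edge production KG would need larger `k`, `d` and batch
  throughput than this reference implementation targets.
* No attention beyond inner-product relation scoring; no
  relation-specific transform matrices; no k-fold cross-validation
  driver (single 8:1:1 split only).
* The evaluation receptive fields are one Monte-Carlo draw; metrics
  carry sampling noise of a few thousandths of AUC across evaluation
  seeds.

## A minimal run

```{r example, eval = FALSE}
spec <- synthetic_spec(n_genes = 100, n_factors = 10,
                       n_distractor_entities = 60, n_pairs = 800, seed = 42)
gen  <- generate_kg(spec)
data <- plant_sl_labels(gen$kg, gen$assignment, spec)
cfg  <- train_config(k = 8, d = 32, H = 2, batch_size = 128,
                     max_epochs = 15, patience = 5, seed = 42)
fit  <- train_model(data, gen$kg, cfg)
fit
evaluate(fit$params, data$pairs[data$split == "test", ], gen$kg, cfg,
         eval_seed = 7)
run_ablation(data, gen$kg, cfg, ablation_seed = 99)
```
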