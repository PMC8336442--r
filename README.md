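# slkgnn

Synthetic lethality (SL) is a gene-pair relationship in which simultaneous
loss of two genes kills a cell while loss of either alone is tolerated —
a central route to selective anti-cancer targets (inactivate the partner
of a gene the tumour has already lost). Wet-lab SL screens are expensive
and noisy, and most computational predictors treat SL pairs as
independent samples, ignoring the shared biology (pathways, biological
processes, complexes) that underlies many pairs.

`slkgnn` predicts SL gene pairs by message passing over a heterogeneous
biomedical **knowledge graph** (KG): typed entities (genes, biological
processes, compounds, diseases, ...) connected by typed triplets
*(head, relation, tail)*. Shared mechanisms enter the model as graph
structure instead of hand-engineered features. The package is for
computational biologists who want a self-contained, CPU-only, fully
reproducible implementation of this model class — including a synthetic
benchmark generator, so the entire pipeline runs and is tested without
any external download.

## The model

For a candidate pair (*i*, *j*), each gene gets a fixed-width receptive
field sampled from the KG: hop 0 is the gene, and each entity draws *k*
neighbours uniformly **with replacement** (duplicates for low-degree
nodes, subsampling for hubs), repeated for *H* hops, so hop *h* holds
exactly *k*<sup>*h*</sup> entities.

Edges in gene *i*'s field are weighted by how much their relation type
matters *to the partner j*: the score of an edge with relation *r* is
the inner product ω = ⟨**e**<sub>j</sub>, **r**⟩ of the partner's
embedding with the relation-type embedding, softmax-normalised over each
entity's *k* sampled edges. Every entity *e* then aggregates its
neighbourhood and updates through

&nbsp;&nbsp;&nbsp;&nbsp;**e**<sup>[h+1]</sup> = φ( **W** ( **e**<sup>[h]</sup> + Σ ω̃ **e′**<sup>[h]</sup> ) + **b** ),

with ReLU on hidden layers (tanh on the final one, see the vignette).
After *H* updates the hop-0 vector **ê**<sub>i</sub> is the gene's
representation, and the pair score is

&nbsp;&nbsp;&nbsp;&nbsp;ŝ<sub>ij</sub> = σ( ⟨**ê**<sub>i</sub>, **ê**<sub>j</sub>⟩ ),

classified at threshold 0.5. Training minimises the summed logit
cross-entropy plus an L2 penalty (weight α) over the touched embedding
rows and all transform weights, with Adam (lr 0.002, α 0.0039 by
default), early stopping on validation AUC, and AUC / AUPR / F1
reporting. Because no autodiff framework is available in this R stack,
the backward pass is derived analytically and verified against central
finite differences in the test suite.

## Worked example

Simulate a corpus in which SL labels are planted through shared latent
factors (genes participating in a common biological process are
synthetic-lethal with probability 0.9, others with 0.02), train, and ask
whether the knowledge graph — not label memorisation — drives the
predictions:

```r
library(slkgnn)

spec <- synthetic_spec(n_genes = 100, n_factors = 10, n_distractor_entities = 60,
                       n_pairs = 800, seed = 42)
gen  <- generate_kg(spec)
gen$kg
#> <knowledge_graph> 170 entities (5 types), 6 relation types, 369 triplets

data <- plant_sl_labels(gen$kg, gen$assignment, spec)
data
#> <sl_dataset> 800 pairs (400 positive) over 100 genes; split 640/80/80

cfg <- train_config(k = 8, d = 32, H = 2, batch_size = 128,
                    max_epochs = 15, patience = 5, seed = 42)
fit <- train_model(data, gen$kg, cfg)
fit
#> <kgnn_fit> 15 epochs trained, best epoch 13
#>   train loss 0.3091  AUC 0.9470  AUPR 0.9497  F1 0.8597
#>   valid loss 0.4936  AUC 0.8441  AUPR 0.8727  F1 0.7500
#>   test  loss 0.5202  AUC 0.8434  AUPR 0.8266  F1 0.6944

run_ablation(data, gen$kg, cfg, ablation_seed = 99)
#> <ablation_report> intact test AUC 0.8434 vs shuffled 0.7602 (delta +0.0831)
```

The held-out test AUC of 0.84 shows the model recovers the planted
mechanism signal on this small corpus (larger corpora score higher; the
test suite requires seed-averaged AUC ≥ 0.85 at the default 300-gene
scale). The ablation trains the identical model on a degree-preserving
edge shuffle of the KG: the +0.08 AUC drop attributes that margin to
knowledge-graph *content*, since graph size, degrees and per-relation
edge counts are all preserved.

A command-line wrapper ships at `inst/cli/slkgnn`
(`simulate` / `train` / `evaluate` / `predict` / `ablate`); see
`system.file("cli", "slkgnn", package = "slkgnn")`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the pipeline from scratch at the given seed — simulates the
default synthetic corpus, trains on the intact and the shuffled
knowledge graph, and evaluates both on the held-out test split — and
writes the JSON report to `--out`.

## Documentation

The methods vignette (`vignettes/slkgnn-methods.Rmd`) describes the
model and its assumptions, every tunable parameter, what the synthetic
generator does and does not emulate, and the numerical design choices.
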