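# nutriwalk

Radiotherapy response in rectal cancer varies widely between patients, and
part of that variability traces to molecular programs — notably lipid
metabolism — that bioactive molecules in everyday foods can modulate.
`nutriwalk` implements a genomic-driven pipeline that screens the space of
food molecules for potential radioresponse modulators and then rewrites
recipes to concentrate them, for computational biologists studying
network-based nutrition interventions.

## The model

The pipeline works on a multiscale interactome: an undirected heterogeneous
graph `G = (V, E)` whose `N` protein nodes and `M` biological-function
nodes are joined by protein–protein, protein–function and function–function
edges (unit weights). An entity — the resistance phenotype, a drug, a
disease, or a food molecule — is a binary seed vector `p ∈ {0,1}^N` over
the proteins it dysregulates or targets. A biased random walk with restarts
diffuses each seed over the graph: the diffusion profile `s` solves

    s = r · p̂ + (1 − r) · W · s

where `W` is the column-stochastic transition matrix, `p̂` the seed
indicator normalized to sum one, and `r = 0.64` the restart probability.
`s` records how often the walker visits every protein and function, i.e.
the entity's network-wide effect.

Raw profile similarity is a blunt ranking signal, so a multilayer
perceptron is trained to embed profiles into a metric space using the
triplet loss

    L = max(0, d(f(s_disease), f(s_drug+)) − d(f(s_disease), f(s_drug−)) + m)

over (disease, treating drug, non-treating drug) triples from a
drug–disease gold standard, with 5-fold cross-validation by disease,
one sampled positive and negative per disease per epoch, and the Adam
optimizer (at most 100 epochs). Held-out AUROC against the model-free
profile-correlation baseline quantifies the gain. Food molecules are then
ranked by embedding distance to the phenotype; a curated direction list
(assembled by literature review, consumed as data) keeps molecules with the
desired modulation direction, and the survivors roll up to the ingredients
that contain them.

The recipe module scores each recipe by its enrichment — the number of
distinct predicted modulators across its ingredients — and substitutes
ingredients using occurrence-level context embeddings: a candidate's
substitute score counts how often it appears among the 200 nearest
neighbours of the query ingredient's occurrences (kept if the score exceeds
100 and a tenth of the ingredient's top score), filtered to candidates with
strictly more modulators, under no-reuse/no-duplicate constraints, the 14
canonical food allergens and 1–5 patient preference scores.

Because the full external inputs (the 27k-node interactome, drug
indication databases, food composition tables, recipe corpora and
language-model embeddings) are not redistributable, the package ships
seeded desk-scale generators for all of them with planted signal, so every
stage's recovery behaviour is testable offline.

## Worked example

```r
library(nutriwalk)

cfg   <- simulation_config(rng_seed = 7L)
graph <- generate_interactome(cfg)
graph
#> interactome_graph: 500 nodes (350 proteins, 150 functions), 1936 edges
#>   function-function: 164
#>   protein-function: 690
#>   protein-protein: 1082

W   <- build_transition_matrix(graph)
sim <- generate_benchmark(graph, cfg)
profiles <- propagate_batch(c(list(sim$seeds$phenotype), sim$seeds$diseases,
                              sim$seeds$drugs, sim$seeds$molecules), W)

cv <- train_embedding_model(profiles, sim$benchmark,
                            config = list(layers = c(128L, 64L), seed = 7L))
cv
#> embedding_cv: 5 folds, mean AUROC 0.798 (baseline 0.703)
```

The learned metric ranks drugs for held-out diseases at AUROC 0.798 where
raw profile correlation reaches 0.703 — the metric-learning gain the
pipeline is built around. Ranking food molecules against the phenotype and
filtering by curated direction recovers the planted modulators:

```r
food    <- generate_food_world(cfg, sim$modulator_ids)
ranking <- rank_food_molecules("phenotype", names(sim$seeds$molecules),
                               profiles, cv$models[[1]], k = 30L)
modulators <- apply_direction_filter(ranking, food$curated, "positive")
head(modulators, 3)
#>   molecule_id distance
#> 1 molecule007 10.94478
#> 2 molecule003 11.22171
#> 3 molecule005 12.49742

tops <- ingredients_by_modulator_count(modulators$molecule_id,
                                       food$composition)
head(tops, 3)
#>      ingredient n_modulators
#> 1 ingredient_06            4
#> 2 ingredient_19            4
#> 3 ingredient_22            4
```

Finally, a recipe is rewritten through the substitution table (here at the
desk-scale thresholds) and its enrichment score rises from 4 to 7 distinct
modulators:

```r
counts <- setNames(tops$n_modulators, tops$ingredient)
subst  <- filter_substitutes_by_modulators(
  build_substitution_table(food$embeddings, k = 5, min_score = 3), counts)
out <- mutate_recipe(food$recipes[[1]], subst, rng_seed = 7L,
                     modulators = modulators$molecule_id,
                     composition = food$composition)
```

A command-line front end wrapping the same functions (subcommands
`simulate`, `propagate`, `train`, `rank`, `substitutions`, `optimize`)
is installed under `inst/cli/nutriwalk.R`.

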