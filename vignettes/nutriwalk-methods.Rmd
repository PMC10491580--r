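---
title: "Methods: network propagation, metric learning and recipe optimization in nutriwalk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network propagation, metric learning and recipe optimization in nutriwalk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its methods: the models and
their assumptions, the parameters that matter, what the synthetic-data
generators emulate (and what they do not), and the numerical and design
choices made where the design was genuinely open. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## 1. The multiscale interactome and the walker

The core object is an undirected heterogeneous graph whose nodes are
proteins and biological functions, with three edge classes:
protein–protein (physical interaction), protein–function (a protein
affecting a function) and function–function (the hierarchy of function
terms). All edges carry unit weight by default; per-edge-type weights are
accepted but deliberately not optimized — fixed weights move the modelling
burden onto the learned metric, which is the package's central design
commitment.

Conventions worth stating explicitly:

* **Node ordering.** Proteins sorted lexicographically, then functions
  sorted lexicographically. Seed vectors index the protein block;
  transition matrices and profiles use the full ordering. The ordering is
  asserted stable across load → matrix → profile in the tests.
* **Undirectedness.** The function hierarchy is traversed bidirectionally
  like every other edge class: the walk is defined over one undirected
  graph, and nothing in the edge files carries a reliable direction after
  canonicalization. (Edge files are canonicalized with lexicographically
  ordered endpoints, duplicates collapsed — weights not summed — and
  self-loops dropped.)
* **Dangling nodes** (degree zero after canonicalization) receive a
  uniform transition column. This keeps the matrix column-stochastic
  without deleting nodes that seed vectors may legitimately reference.
* **Identifier matching is exact-string and case-preserving.** Silent
  case-folding merges distinct gene symbols; unmapped identifiers are
  counted and reported instead.

The diffusion profile of a seed vector solves
`s = r p̂ + (1 − r) W s` with `p̂` uniform over the seed set (the standard
random-walk-with-restarts convention; configurable in principle but not
exposed until needed). We solve it by power iteration on sparse
matrix–vector products, stopping when the L1 change drops below `tol`
(default `1e-10`, far below any tolerance used in a test) or at `max_iter`
(default 10,000; at `r = 0.64` the iteration contracts by factor 0.36 per
sweep, so convergence takes ~25 sweeps). Non-convergence flags the result
and warns rather than raising: a partially converged profile is still
informative, and batch callers should not lose 400 finished profiles to
one pathological seed. The dense linear solve `(I − (1−r)W)s = r p̂` is
reserved for the test oracle.

The restart probability defaults to `r = 0.64`, treated as a fixed
constant of the method. The calibration recipe sometimes quoted for this
value (propagating at a zero restart probability and rescaling by the mean
maximum propagated value) is not well defined as stated — a restart
probability of zero has no seed mass to rescale — so the package
implements only the constant, and exposes it as an argument everywhere.

## 2. Metric learning over diffusion profiles

Raw diffusion profiles concentrate their mass near the seeds and on
well-connected regions, and their plain correlation mixes signal the task
cares about with mass it does not. The package therefore trains a
multilayer perceptron to embed profiles into a space where Euclidean
distance reflects treatment relationships, using the triplet hinge loss
`max(0, d_ap − d_an + margin)` over (disease, treating drug, non-treating
drug) triples.

Design choices, all exposed in the training config:

* **Preprocessing**: `log(x + 1e-12)` then per-feature standardization.
  Diffusion mass spans orders of magnitude; the log makes low-mass
  function nodes commensurate with high-mass seed neighbourhoods.
  Statistics are fitted on the training fold's diseases plus all drugs
  only, then applied everywhere — held-out diseases never influence the
  scaling.
* **Folds are split by disease** (drugs shared across folds). Evaluation
  ranks drugs per disease, so the disease axis is where leakage would
  matter.
* **Sampling**: per training disease per epoch, one uniformly sampled
  positive and one uniformly sampled negative drug; unlabelled pairs count
  as negative; a disease's own positives are the only exclusions. All
  triplets of an epoch form one batch; gradients average over the batch.
* **Architecture**: ReLU hidden layers, linear embedding output, He
  initialization, Adam updates. The package default is input → 512 → 256
  with margin 1 and learning rate 1e-3. The tests and the acceptance
  script use 128 → 64 at the 500-node desk scale — at that input width the
  wider net buys nothing but time, and the suite's runtime budget is
  better spent on seeds; this is recorded here as the package's scale
  choice, and both choices are plain config entries.
* **Distance**: Euclidean in embedding space; Pearson correlation of raw
  profiles for the model-free baseline. Which space the final molecule
  ranking uses is logged on the ranking object (`embedding` when a model
  is supplied, `raw_profile` correlation distance otherwise).
* **Evaluation**: AUROC (ties one half, computed by midranks) pooled over
  the held-out diseases' pairs against all non-positive drugs, with a
  per-disease macro average alongside. The baseline is computed on the
  same held-out split inside the same fold loop, so the comparison shares
  every split decision.
* **Training length**: at most 100 epochs, no early stopping — with one
  triplet per disease per epoch the batch count is small enough that
  stopping heuristics add variance rather than protection.

Models serialize to a text directory (architecture JSON, weights/biases
and preprocessing statistics as TSV at 17 significant digits, which
round-trips IEEE doubles exactly).

## 3. Ranking, direction filtering, explanation

Molecules are ranked by ascending distance to the phenotype (top-k,
default 100), ties broken lexicographically by molecule id — every
tie-break in the package is deterministic lexicographic, for
reproducibility. Diffusion proximity is unsigned, so a curated direction
list (a CSV of molecule, direction, evidence — produced by literature
review, never automated) filters the ranking to the desired modulation
direction; molecules absent from the list are dropped and logged.
Surviving modulators roll up to ingredients by distinct-molecule count.
`explain_association()` returns the induced subgraph over both seed sets
plus the `q` nodes maximizing `min(profile_mol, profile_phen)` — the
co-visited backbone — with shortest paths between the seed sets annotated,
or a `no_path` flag when the seed sets are disconnected.

## 4. Ingredient lexicon and recipe optimization

Ingredient names are lowercased, whitespace-collapsed and de-pluralized
token-wise. The de-pluralization rule is centralized and deliberately
simple: `-oes` plurals lose `es` (potatoes → potato), otherwise a trailing
`s` is stripped unless the token ends in `ss` (swiss, glass) or has at
most two characters. Two normalized names match when they share the first
two words, the last two words, the first word, or the last word; the
relation is not transitive, so connected components of the match graph
define canonical ingredient identities (the component's lexicographically
smallest member names it). "Spaces removed" is implemented as whitespace
collapsing, not concatenation — concatenation would destroy the
word-position matching rule.

Substitute discovery: for every occurrence of an ingredient, its `k = 200`
nearest occurrence vectors by Euclidean distance are found **excluding
occurrences of the same ingredient** (a self-neighbour can never be a
substitute and would otherwise dominate every tally); a candidate's
substitute score is the number of neighbour slots it fills across all of
the query's occurrences; candidates survive with score > 100 and score >
1/10 of the ingredient's top score. The search is a joint search over all
occurrences, blockwise exact distances — no approximate index, since
exactness is what the brute-force oracle test checks. The desk-scale tests
run the same code at k = 5, min_score = 3 (scaled roughly with
occurrences-per-ingredient × k / ingredient count).

Recipe mutation walks ingredients in order and substitutes each by one
uniformly sampled candidate from its modulator-filtered list, under three
constraints: a substitute is never reused within a recipe, a substitute
may not already be in the recipe — read strictly: neither in the current
state nor among the original ingredients, so a substitution never
reintroduces what another substitution removed — and, when the modulator
set and composition are supplied, a sampled substitution that would
strictly lower the recipe's enrichment score is rejected. The last guard
exists because per-ingredient modulator counts do not compose: replacing
an ingredient whose sole modulator is unique to it with a higher-count
candidate whose modulators the recipe already contains can lower the
distinct-molecule union even though the per-ingredient filter passed. The
guard makes mutation monotone in the quantity the pipeline actually
optimizes.

The enrichment score itself counts **distinct modulator molecules** in the
union of the recipe's ingredients' compositions; the alternative reading
(number of modulator-carrying ingredients) is available via a mode flag.

Allergy handling: ingredients carrying any of the patient's allergens
(from the 14 canonical allergen labels) are substituted by their
highest-scoring non-allergenic candidate, deterministically; recipes where
some allergenic ingredient has no safe candidate are removed, so surviving
recipes contain zero allergenic ingredients. Preference optimization
applies a substitution iff the patient strictly prefers the candidate and
enrichment does not fall, or enrichment strictly rises and the preference
does not fall — both deltas evaluated at recipe level, candidates tried in
substitute-score order, first admissible taken. Unrated ingredients take
the neutral preference 3, which is what makes the two clauses well defined
for foods the patient never scored.

## 5. What the synthetic generators emulate

All generators are pure functions of a `simulation_config` (identical
configs give byte-identical outputs, which the tests assert on the written
files). The desk-scale defaults — 350 proteins + 150 functions in 10
communities, 60 diseases, 300 drugs, 100 food molecules, positive-pair
community overlap 0.8, 40 ingredients × 20 occurrence embeddings in 5
culinary clusters, 30 recipes — are the package's chosen study conditions
for a single-CPU test run.

* **Interactome**: stochastic-block protein layer (dense within
  communities, sparse across), a rooted random recursive tree plus
  ancestor→descendant shortcuts for the function hierarchy (a single-root
  DAG in parent→child orientation), community-biased protein–function
  links, bridges added if disconnected.
* **Benchmark**: each disease seeds proteins of one community; each
  positive drug targets the disease's community with probability
  `positive_overlap`, otherwise a uniformly random drug — at overlap 0
  positives are exchangeable with negatives, giving the null
  configuration used to check that the trained AUROC sits at chance.
* **Off-target nuisance**: every disease, drug and molecule additionally
  seeds 4–8 proteins from one of three shared "frequent-hitter" pools,
  emulating promiscuous off-target binding and generic stress-response
  co-dysregulation. This matters: without a structured confounder, raw
  profile correlation is already essentially optimal on a planted
  community benchmark and metric learning has nothing to add. The
  frequent-hitter mass inflates raw similarity between unrelated entities
  while remaining a low-dimensional, learnable nuisance that supervision
  projects out — which is precisely the regime in which the learned
  metric separates from the baseline (the acceptance suite measures
  both).
* **Food world**: modulator molecules (the ones targeting the phenotype's
  community) are planted into a known enriched ingredient subset;
  occurrence embeddings are Gaussian around per-cluster centers (sd 2)
  with within-cluster spread 0.5, so substitution candidates stay within
  culinary clusters as the spread shrinks; recipes sample ingredients
  within one cluster; allergens are drawn from the 14 canonical labels;
  the curated list marks planted modulators positive.

What the generators do **not** emulate: scale-free degree tails, realistic
FoodDB/STITCH marginal statistics, correlated target overlap between
specific drug pairs, multi-cluster recipes, or textual ingredient-name
noise. Passing tests therefore demonstrate that each stage recovers the
structure it is designed to recover under controlled conditions — not
performance on the real external datasets, whose headline numbers require
the full-size inputs.

## 6. Degenerate inputs and numerical corner cases

* Empty edge files are legal (a layer may be absent); an empty seed set,
  a zero-length ingredient list, or an all-one-class label vector raise
  immediate validation errors.
* Zero-variance profiles score 0 in the correlation baseline, with a
  warning, rather than propagating NaN.
* Triplet gradients guard zero distances with an epsilon before
  normalizing difference vectors.
* Distance computations clamp negative squared distances (round-off from
  the quadratic expansion) at zero; KNN ties break on occurrence index,
  making tallies reproducible.
* A disease whose positives exhaust the drug universe is skipped in
  sampling with a warning; a fold with no evaluable disease aborts before
  training.

## 7. Problem sizes used by the test suite

The suite runs the full pipeline at the desk-scale defaults across three
simulation seeds and four restart probabilities, 100 random small graphs
(≤ 200 nodes) against the dense-solve oracle, 1000 random vectors against
the pair-counting AUROC oracle, an exact brute-force check of the
substitution table on the 800-occurrence fixture, and 1000 seeded recipe
mutations. These sizes were chosen so the complete suite runs in a few
minutes on one CPU while every property is still measured on the same
code paths the package exposes.
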