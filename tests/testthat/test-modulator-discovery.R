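# Fixture: profiles for a phenotype and molecules, correlation space.
ranking_fixture <- function(n_mol = 20L, seed = 1L) {
  set.seed(seed)
  P <- matrix(abs(rnorm((n_mol + 1) * 30)), n_mol + 1, 30)
  P <- P / rowSums(P)
  rownames(P) <- c("phenotype", sprintf("mol%02d", seq_len(n_mol)))
  P["mol07", ] <- P["phenotype", ]  # planted perfect match
  P
}

test_that("a molecule with the phenotype's profile ranks first", {
  P <- ranking_fixture()
  rk <- rank_food_molecules("phenotype", rownames(P)[-1], P, k = 5L)
  expect_equal(rk$molecule_id[1], "mol07")
  expect_equal(rk$distance[1], 0, tolerance = 1e-12)
  expect_identical(attr(rk, "ranking_space"), "raw_profile")
})

test_that("k equal to the molecule count returns the full ordering, and the
           ranking equals a brute-force sort of pairwise distances", {
  P <- ranking_fixture(100L, seed = 9L)
  mols <- rownames(P)[-1]
  rk <- rank_food_molecules("phenotype", mols, P, k = 100L)
  expect_equal(nrow(rk), 100L)
  d <- vapply(mols, function(m) 1 - cor(P["phenotype", ], P[m, ]),
              numeric(1))
  expect_identical(rk$molecule_id, mols[order(d, mols)])
  expect_true(all(diff(rk$distance) >= 0))
  expect_error(rank_food_molecules("phenotype", mols, P, k = 0L),
               "positive")
  expect_error(rank_food_molecules("phenotype", mols, P, k = 101L),
               "exceeds")
})

test_that("direction filtering keeps a rank-preserving subsequence", {
  P <- ranking_fixture(100L, seed = 2L)
  mols <- rownames(P)[-1]
  rk <- rank_food_molecules("phenotype", mols, P, k = 100L)
  # mark exactly 33 molecules as the kept direction
  curated <- data.frame(molecule_id = mols, direction = "negative")
  curated$direction[1:33] <- "positive"
  kept <- apply_direction_filter(rk, curated, keep = "positive")
  expect_equal(nrow(kept), 33L)
  expect_identical(kept$molecule_id,
                   rk$molecule_id[rk$molecule_id %in% mols[1:33]])
  # empty curated list leaves nothing, with a warning
  expect_warning(
    none <- apply_direction_filter(
      rk, data.frame(molecule_id = character(0),
                     direction = character(0)), "positive"),
    "no molecules")
  expect_equal(nrow(none), 0L)
})

test_that("filtering commutes with ranking (order preservation)", {
  P <- ranking_fixture(40L, seed = 3L)
  mols <- rownames(P)[-1]
  curated <- data.frame(molecule_id = mols,
                        direction = rep_len(c("positive", "negative"), 40L))
  pos_mols <- curated$molecule_id[curated$direction == "positive"]
  rank_then_filter <- apply_direction_filter(
    rank_food_molecules("phenotype", mols, P, k = 40L), curated, "positive")
  filter_then_rank <- rank_food_molecules("phenotype", pos_mols, P,
                                          k = length(pos_mols))
  expect_identical(rank_then_filter$molecule_id,
                   filter_then_rank$molecule_id)
})

test_that("ingredient rollup counts distinct modulators, beetroot-style", {
  comp <- data.frame(
    ingredient = c("beetroot", "beetroot", "beetroot", "spinach",
                   "new potato", "kale", "kale", "beetroot"),
    molecule_id = c("kaempferol", "syringic acid", "sucrose", "kaempferol",
                    "starch", "kaempferol", "quercetin", "kaempferol"))
  modulators <- c("kaempferol", "syringic acid", "quercetin")
  out <- ingredients_by_modulator_count(modulators, comp)
  expect_equal(out$n_modulators[out$ingredient == "beetroot"], 2L)
  expect_equal(out$n_modulators[out$ingredient == "new potato"], 0L)
  expect_equal(out$ingredient[nrow(out)], "new potato") # none -> last
  expect_equal(out$ingredient[1], "beetroot")
  # permutation invariance in table row order
  out2 <- ingredients_by_modulator_count(modulators,
                                         comp[sample(nrow(comp)), ])
  expect_identical(out2, out)
})

test_that("molecules seeded inside the phenotype community outrank others", {
  cfg <- simulation_config(n_proteins = 150L, n_functions = 60L,
                           community_count = 5L, n_food_molecules = 30L,
                           n_modulator_molecules = 10L,
                           targets_per_entity = 4L,
                           offtarget_min = 1L, offtarget_max = 2L,
                           offtarget_pool_size = 6L,
                           rng_seed = 21L)
  g <- generate_interactome(cfg)
  W <- build_transition_matrix(g)
  ranks_in <- c()
  ranks_out <- c()
  for (rep_seed in 1:20) {
    cfg$rng_seed <- 100L + rep_seed
    bench <- generate_benchmark(g, cfg)
    profiles <- propagate_batch(c(list(bench$seeds$phenotype),
                                  bench$seeds$molecules), W)
    rk <- rank_food_molecules("phenotype", names(bench$seeds$molecules),
                              profiles, k = 30L)
    pos <- match(bench$modulator_ids, rk$molecule_id)
    neg <- match(setdiff(rk$molecule_id, bench$modulator_ids),
                 rk$molecule_id)
    ranks_in <- c(ranks_in, pos)
    ranks_out <- c(ranks_out, neg)
  }
  expect_lt(median(ranks_in), median(ranks_out))
})

test_that("explain_association surfaces connecting paths and bridges", {
  # molecule targets p3; phenotype gene p1; p1-p2-p3 path plus a bridging
  # function f1 linked to both sides
  g <- write_graph_fixture(c("p1\tp2", "p2\tp3"),
                           c("p1\tf1", "p3\tf1"), c("f1\tf2"))
  W <- build_transition_matrix(g)
  mol <- make_seed_vector("p3", g, "mol", "molecule")
  phe <- make_seed_vector("p1", g, "phe", "phenotype")
  pm <- diffusion_profile(mol, W)
  pp <- diffusion_profile(phe, W)
  ex <- explain_association(mol, phe, g, pm, pp, q = 2L)
  expect_false(ex$no_path)
  expect_true("p3" %in% ex$paths[["p3"]] && "p1" %in% ex$paths[["p3"]])
  # the bridging function is among the top co-visited nodes
  expect_true("f1" %in% ex$nodes$node_id[ex$nodes$role == "co_visited"])
  # identical seed sets: subnetwork is seeds plus top-q co-visited
  ex2 <- explain_association(phe, phe, g, pp, pp, q = 2L)
  expect_true(all(c("p1") %in% ex2$nodes$node_id))
  expect_equal(sum(ex2$nodes$role == "shared_seed"), 1L)
  # disconnected seed sets flag no_path
  g2 <- write_graph_fixture(c("p1\tp2", "p3\tp4"))
  W2 <- build_transition_matrix(g2)
  m2 <- make_seed_vector("p3", g2, "m2", "molecule")
  h2 <- make_seed_vector("p1", g2, "h2", "phenotype")
  ex3 <- explain_association(m2, h2, g2, diffusion_profile(m2, W2),
                             diffusion_profile(h2, W2), q = 1L)
  expect_true(ex3$no_path)
})
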