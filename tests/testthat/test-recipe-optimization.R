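# Hand-built Fig-4-style fixture: a substitution table and composition in
# which new-potato-like and kale-like ingredients have strictly better
# substitutes (beetroot-like, spinach-like).
fig4_fixture <- function() {
  table <- structure(list(
    new_potato = data.frame(candidate_id = c("beetroot", "parsnip"),
                            score = c(150L, 120L)),
    kale = data.frame(candidate_id = c("spinach", "cabbage"),
                      score = c(140L, 110L)),
    beetroot = data.frame(candidate_id = character(0), score = integer(0)),
    spinach = data.frame(candidate_id = character(0), score = integer(0)),
    parsnip = data.frame(candidate_id = character(0), score = integer(0)),
    cabbage = data.frame(candidate_id = character(0), score = integer(0))),
    class = "substitution_table")
  composition <- data.frame(
    ingredient = c("beetroot", "beetroot", "spinach", "spinach",
                   "new_potato", "kale", "parsnip", "cabbage"),
    molecule_id = c("kaempferol", "syringic_acid", "kaempferol",
                    "alpha_lipoic_acid", "starch", "chlorophyll",
                    "sugar", "fiber"))
  modulators <- c("kaempferol", "syringic_acid", "alpha_lipoic_acid")
  list(table = table, composition = composition, modulators = modulators)
}

test_that("enrichment counts distinct modulator molecules in the union", {
  fx <- fig4_fixture()
  r <- recipe("r1", ingredients = "beetroot")
  expect_equal(enrichment_score(r, fx$modulators, fx$composition), 2L)
  # two ingredients sharing one modulator: counted once
  r <- recipe("r2", ingredients = c("beetroot", "spinach"))
  expect_equal(enrichment_score(r, fx$modulators, fx$composition), 3L)
  expect_equal(enrichment_score(r, character(0), fx$composition), 0L)
  expect_equal(
    enrichment_score(r, fx$modulators, fx$composition,
                     mode = "ingredient_count"), 2L)
  expect_warning(
    enrichment_score(recipe("r3", ingredients = "dragonfruit"),
                     fx$modulators, fx$composition, warn_unresolved = TRUE),
    "dragonfruit")
})

test_that("modulator filtering keeps strictly better candidates only", {
  fx <- fig4_fixture()
  counts <- setNames(c(0L, 0L, 2L, 2L, 0L, 0L),
                     c("new_potato", "kale", "beetroot", "spinach",
                       "parsnip", "cabbage"))
  ft <- filter_substitutes_by_modulators(fx$table, counts)
  expect_equal(ft$new_potato$candidate_id, "beetroot")
  expect_equal(ft$kale$candidate_id, "spinach")
  # equal counts are dropped (strict inequality)
  counts["parsnip"] <- 0L
  counts["new_potato"] <- 2L
  ft2 <- filter_substitutes_by_modulators(fx$table, counts)
  expect_equal(nrow(ft2$new_potato), 0L)
  # empty candidate lists stay empty
  expect_equal(nrow(ft$beetroot), 0L)
})

test_that("the Fig-4-style recipe mutates potatoes to beetroot, kale to
           spinach", {
  fx <- fig4_fixture()
  counts <- setNames(c(0L, 0L, 2L, 2L, 0L, 0L),
                     c("new_potato", "kale", "beetroot", "spinach",
                       "parsnip", "cabbage"))
  ft <- filter_substitutes_by_modulators(fx$table, counts)
  r <- recipe("korma", ingredients = c("new_potato", "kale"))
  out <- mutate_recipe(r, ft, rng_seed = 1L)
  expect_equal(out$ingredients, c("beetroot", "spinach"))
  # empty substitution lists leave the recipe unchanged
  empty <- structure(list(), class = "substitution_table")
  expect_equal(mutate_recipe(r, empty, rng_seed = 1L)$ingredients,
               r$ingredients)
})

test_that("a substitute is never reused and never duplicates the recipe", {
  # two slots whose only candidate is the same ingredient: exactly the
  # first slot is substituted, across seeds
  table <- structure(list(
    a = data.frame(candidate_id = "x", score = 200L),
    b = data.frame(candidate_id = "x", score = 200L),
    x = data.frame(candidate_id = character(0), score = integer(0))),
    class = "substitution_table")
  r <- recipe("r", ingredients = c("a", "b"))
  for (seed in 1:20) {
    out <- mutate_recipe(r, table, rng_seed = seed)
    expect_equal(out$ingredients, c("x", "b"))
  }
  # a candidate already present in the recipe is not allowed
  r2 <- recipe("r2", ingredients = c("a", "x"))
  for (seed in 1:10)
    expect_equal(mutate_recipe(r2, table, rng_seed = seed)$ingredients,
                 c("a", "x"))
})

test_that("mutation is reproducible under a fixed seed", {
  fx <- fig4_fixture()
  r <- recipe("r", ingredients = c("new_potato", "kale"))
  o1 <- mutate_recipe(r, fx$table, rng_seed = 11L)
  o2 <- mutate_recipe(r, fx$table, rng_seed = 11L)
  expect_identical(o1$ingredients, o2$ingredients)
})

test_that("allergy constraints substitute or remove, leaving safe recipes", {
  fx <- fig4_fixture()
  db <- data.frame(ingredient = c("new_potato", "beetroot"),
                   allergen = c("celery", "celery"))
  ctx <- dietary_context(allergies = "celery", allergen_db = db)
  # new_potato is allergenic; parsnip is its safe candidate
  out <- apply_allergy_constraints(
    list(recipe("r", ingredients = c("new_potato", "kale"))), ctx, fx$table)
  expect_length(out, 1L)
  expect_equal(out[[1]]$ingredients, c("parsnip", "kale"))
  # all candidates allergenic -> recipe removed
  db2 <- data.frame(ingredient = c("new_potato", "beetroot", "parsnip"),
                    allergen = "celery")
  ctx2 <- dietary_context(allergies = "celery", allergen_db = db2)
  out2 <- apply_allergy_constraints(
    list(recipe("r", ingredients = c("new_potato", "kale"))), ctx2,
    fx$table)
  expect_length(out2, 0L)
  # empty allergy list is the identity
  rs <- list(recipe("r", ingredients = "new_potato"))
  ctx3 <- dietary_context(allergen_db = db)
  expect_identical(apply_allergy_constraints(rs, ctx3, fx$table), rs)
  expect_error(dietary_context(allergies = "pollen"), "allergen")
})

test_that("preference optimization applies only Pareto-improving swaps", {
  fx <- fig4_fixture()
  counts_ctx <- function(prefs) dietary_context(
    preferences = prefs,
    allergen_db = data.frame(ingredient = character(0),
                             allergen = character(0)))
  r <- recipe("r", ingredients = "new_potato")
  # higher preference, equal modulator gain impossible here (beetroot adds
  # 2), so test pure preference with a no-modulator candidate: parsnip
  ctx <- counts_ctx(c(parsnip = 5, new_potato = 2, beetroot = 1))
  out <- optimize_with_preferences(r, ctx, fx$table, fx$modulators,
                                   fx$composition)
  expect_equal(out$ingredients, "parsnip")  # pref up, enrichment equal
  # more modulators but lower preference: blocked
  ctx <- counts_ctx(c(beetroot = 1, new_potato = 4, parsnip = 1))
  out <- optimize_with_preferences(r, ctx, fx$table, fx$modulators,
                                   fx$composition)
  expect_equal(out$ingredients, "new_potato")
  # more modulators, equal (neutral) preference: substituted
  ctx <- counts_ctx(numeric(0))
  out <- optimize_with_preferences(r, ctx, fx$table, fx$modulators,
                                   fx$composition)
  expect_equal(out$ingredients, "beetroot")
})

test_that("ingredient embedding averages equal direct arithmetic", {
  v <- matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE)
  emb <- occurrence_embeddings(c("o1", "o2"), c("a", "a"), v)
  expect_equal(unname(average_ingredient_embeddings(emb)["a", ]),
               c(2, 3))
  emb <- occurrence_embeddings(c("o1", "o2"), c("a", "a"),
                               rbind(c(1, -2), c(-1, 2)))
  expect_equal(unname(average_ingredient_embeddings(emb)["a", ]), c(0, 0))
  set.seed(8)
  V <- matrix(rnorm(100), 10, 10)
  emb <- occurrence_embeddings(sprintf("o%d", 1:10), rep("z", 10), V)
  expect_equal(unname(average_ingredient_embeddings(emb)["z", ]),
               colSums(V) / 10)
})

test_that("substitution tables match the brute-force tally on a small
           clustered fixture", {
  cfg <- simulation_config(n_ingredients = 12L,
                           occurrences_per_ingredient = 6L,
                           n_culinary_clusters = 3L, embedding_dim = 4L,
                           cluster_spread = 0.8, rng_seed = 17L)
  food <- generate_food_world(cfg)
  got <- build_substitution_table(food$embeddings, k = 4L, min_score = 2,
                                  max_ratio = 0.1)
  want <- oracle_substitution_table(food$embeddings, k = 4L, min_score = 2,
                                    max_ratio = 0.1)
  expect_equal(unclass(got), want)
  # raising min_score beyond any tally empties every candidate list
  high <- build_substitution_table(food$embeddings, k = 4L,
                                   min_score = 1e6, max_ratio = 0.1)
  expect_true(all(vapply(high, nrow, integer(1)) == 0L))
})

test_that("recipes round-trip through Recipe1M-style JSON", {
  rs <- list(recipe("r1", "Test soup", c("a", "b"), c("step 1", "step 2")),
             recipe("r2", ingredients = "c"))
  path <- tempfile(fileext = ".json")
  write_recipes_json(rs, path)
  rs2 <- read_recipes_json(path)
  expect_equal(rs2[[1]]$ingredients, c("a", "b"))
  expect_equal(rs2[[1]]$title, "Test soup")
  expect_equal(rs2[[2]]$recipe_id, "r2")
  expect_error(recipe("bad", ingredients = character(0)), "ingredient")
})
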