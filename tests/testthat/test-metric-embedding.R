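# Shared scaled-down planted benchmark for the training-behaviour tests.
small_bench_env <- new.env()
small_benchmark <- function() {
  if (!is.null(small_bench_env$data)) return(small_bench_env$data)
  cfg <- simulation_config(n_proteins = 120L, n_functions = 60L,
                           community_count = 6L, n_diseases = 18L,
                           n_drugs = 60L, targets_per_entity = 4L,
                           offtarget_pool_size = 8L,
                           offtarget_min = 2L, offtarget_max = 4L,
                           rng_seed = 7L)
  g <- generate_interactome(cfg)
  W <- build_transition_matrix(g)
  bench <- generate_benchmark(g, cfg)
  profiles <- propagate_batch(c(bench$seeds$diseases, bench$seeds$drugs), W)
  small_bench_env$data <- list(bench = bench$benchmark, profiles = profiles)
  small_bench_env$data
}

test_that("triplet loss is the hinge on the distance gap", {
  expect_equal(triplet_loss(0, 0, margin = 1), 1)
  expect_equal(triplet_loss(0, 2, margin = 1), 0)
  expect_equal(triplet_loss(0.2, 0.9, margin = 1), 0.3)
  expect_equal(triplet_loss(c(0, 0.2), c(2, 0.9), 1), c(0, 0.3))
  expect_error(triplet_loss(-0.1, 1, 1), "non-negative")
  expect_error(triplet_loss(1, 1, 0), "margin")
})

test_that("triplet sampling is uniform, reproducible and skips dead ends", {
  b1 <- association_benchmark(
    data.frame(disease_id = "d1", drug_id = "r1"),
    diseases = "d1", drugs = c("r1", "r2"))
  tri <- sample_triplets(b1, rng_seed = 1L)
  expect_equal(tri$positive_id, "r1")
  expect_equal(tri$negative_id, "r2")
  # determinism
  b2 <- association_benchmark(
    data.frame(disease_id = rep("d1", 2), drug_id = c("r1", "r2")),
    drugs = sprintf("r%d", 1:6))
  expect_identical(sample_triplets(b2, rng_seed = 42L, epochs = 20L),
                   sample_triplets(b2, rng_seed = 42L, epochs = 20L))
  # two positives drawn ~50/50 over many epochs
  tri <- sample_triplets(b2, rng_seed = 7L, epochs = 10000L)
  frac <- mean(tri$positive_id == "r1")
  expect_gt(frac, 0.48)
  expect_lt(frac, 0.52)
  # a disease whose positives exhaust the drugs cannot yield a negative
  b3 <- suppressWarnings(association_benchmark(
    data.frame(disease_id = c("d1", "d1", "d2"),
               drug_id = c("r1", "r2", "r1")),
    drugs = c("r1", "r2")))
  expect_warning(tri <- sample_triplets(b3, rng_seed = 1L), "skipped")
  expect_equal(tri$disease_id, "d2")
})

test_that("auroc matches exhaustive pair counting, including ties", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auroc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_equal(auroc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)), 0.75)
  expect_error(auroc(1:3, c(1, 1, 1)), "negative")
  set.seed(123)
  for (i in 1:200) {
    n <- sample(2:100, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE) # force ties
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    expect_equal(auroc(scores, labels), oracle_auroc_pairs(scores, labels))
  }
})

test_that("score_pairs reproduces a by-hand forward pass on a toy model", {
  # 2 inputs -> 2 hidden (ReLU) -> 1 output, fixed weights
  params <- list(W = list(matrix(c(1, 0, -1, 1), 2, 2),
                          matrix(c(1, 2), 2, 1)),
                 b = list(c(0, 0.5), 1))
  preproc <- list(mean = c(0, 0), sd = c(1, 1), eps = 0)
  model <- nutriwalk:::new_embedding_model(params, 2L, c(2L, 1L), 1,
                                           preproc, 1L, c("n1", "n2"))
  # identity preprocessing needs exp() inputs since embed applies log(x)
  X <- exp(matrix(c(1, 2, 0.5, -0.5), 2, 2, byrow = TRUE,
                  dimnames = list(c("e1", "e2"), c("n1", "n2"))))
  # hand computation: h = relu(x %*% W1 + b1); out = h %*% W2 + b2
  h1 <- pmax(c(1 * 1 + 2 * 0, 1 * -1 + 2 * 1 + 0.5), 0)   # (1, 1.5)
  o1 <- h1[1] * 1 + h1[2] * 2 + 1                          # 5
  h2 <- pmax(c(0.5, -1 + 0.5), 0)                          # (0.5, 0)
  o2 <- h2[1] * 1 + 0 * 2 + 1                              # 1.5
  E <- embed_profiles(model, X)
  expect_equal(unname(E[, 1]), c(o1, o2))
  S <- score_pairs(model, X[1, , drop = FALSE], X)
  expect_equal(unname(S[1, ]), -abs(c(o1 - o1, o1 - o2)))
  # identical profiles take the maximal score in the row
  expect_equal(unname(which.max(S[1, ])), 1L)
  # column permutation permutes scores identically
  S2 <- score_pairs(model, X[1, , drop = FALSE], X[2:1, ])
  expect_equal(unname(S2[1, ]), unname(S[1, 2:1]))
  expect_error(score_pairs(model, X[, 1, drop = FALSE], X), "dimension")
})

test_that("baseline ranking is model-free profile correlation", {
  set.seed(5)
  drugs <- matrix(rnorm(50), 5, 10,
                  dimnames = list(sprintf("r%d", 1:5), NULL))
  disease <- drugs[3, ] # identical to one drug
  sc <- baseline_rank(disease, drugs)
  expect_equal(names(which.max(sc)), "r3")
  expect_equal(unname(sc["r3"]), 1)
  flat <- matrix(1, 1, 10, dimnames = list("flat", NULL))
  expect_warning(sc0 <- baseline_rank(disease, flat), "variance")
  expect_equal(unname(sc0), 0)
})

test_that("an untrained model still evaluates with AUROC in [0, 1]", {
  d <- small_benchmark()
  cv <- train_embedding_model(d$profiles, d$bench,
                              config = list(max_epochs = 0L,
                                            layers = c(32L, 16L),
                                            seed = 1L))
  expect_true(all(cv$metrics$auroc >= 0 & cv$metrics$auroc <= 1))
  expect_true(all(is.na(cv$metrics$loss_first)))
})

test_that("training reduces the epoch loss and recovers planted signal", {
  d <- small_benchmark()
  cv <- train_embedding_model(d$profiles, d$bench,
                              config = list(layers = c(64L, 32L),
                                            seed = 7L))
  expect_lt(mean(cv$metrics$loss_last), mean(cv$metrics$loss_first))
  # well above chance on the planted benchmark (the full-scale comparison
  # against the baseline lives in the acceptance suite)
  expect_gt(mean(cv$metrics$auroc), 0.6)
})

test_that("embedding models round-trip through the text serialization", {
  d <- small_benchmark()
  cv <- train_embedding_model(d$profiles, d$bench,
                              config = list(max_epochs = 5L,
                                            layers = c(24L, 8L), seed = 3L))
  model <- cv$models[[1]]
  E1 <- embed_profiles(model, d$profiles)
  dir <- tempfile()
  save_embedding_model(model, dir)
  model2 <- load_embedding_model(dir)
  E2 <- embed_profiles(model2, d$profiles)
  expect_equal(E2, E1, tolerance = 1e-12)
  expect_identical(model2$layers, model$layers)
})

test_that("benchmark TSV round-trips entity universes", {
  b <- association_benchmark(
    data.frame(disease_id = c("d1", "d2"), drug_id = c("r1", "r1")),
    diseases = c("d1", "d2", "d3"), drugs = c("r1", "r2"))
  path <- tempfile(fileext = ".tsv")
  write_benchmark(b, path)
  b2 <- read_benchmark(path)
  expect_identical(b2$diseases, b$diseases)
  expect_identical(b2$drugs, b$drugs)
  expect_identical(b2$positive_pairs, b$positive_pairs)
})
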