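#' @title Triplet-loss metric learning over diffusion profiles
#'
#' @description
#' Diffusion profiles place every drug, disease and food molecule in the
#' same node space, but raw profile similarity is a blunt ranking signal.
#' A multilayer perceptron is therefore trained to embed profiles into a
#' metric space in which diseases sit close to the drugs known to treat
#' them and far from drugs with no known benefit, by minimising the triplet
#' hinge loss `max(0, d(anchor, positive) - d(anchor, negative) + margin)`
#' over sampled (disease, treating drug, non-treating drug) triples.
#' Cross-validated AUROC on held-out diseases measures the gain over the
#' model-free profile-correlation baseline.
#'
#' @name metric_embedding
NULL

#' Triplet hinge loss
#'
#' @param d_ap distance(s) anchor-positive, non-negative.
#' @param d_an distance(s) anchor-negative, non-negative.
#' @param margin positive margin.
#' @return `max(0, d_ap - d_an + margin)`, vectorized.
#' @examples
#' triplet_loss(0.2, 0.9, margin = 1) # 0.3
#' @export
triplet_loss <- function(d_ap, d_an, margin = 1) {
  if (any(d_ap < 0) || any(d_an < 0)) stopf("distances must be non-negative")
  if (margin <= 0) stopf("margin must be positive")
  pmax(d_ap - d_an + margin, 0)
}

#' Construct a labelled drug-disease association benchmark
#'
#' Positive pairs are known treatment relationships; every other
#' (disease, drug) combination is treated as unlabelled-negative.
#'
#' @param positive_pairs data.frame with columns `disease_id`, `drug_id`.
#' @param diseases,drugs entity universes; default to the ids appearing in
#'   `positive_pairs` but should normally be supplied so that
#'   never-positive drugs are part of the negative pool.
#' @return an `association_benchmark`.
#' @export
association_benchmark <- function(positive_pairs, diseases = NULL,
                                  drugs = NULL) {
  stopifnot(all(c("disease_id", "drug_id") %in% names(positive_pairs)))
  positive_pairs$disease_id <- as.character(positive_pairs$disease_id)
  positive_pairs$drug_id <- as.character(positive_pairs$drug_id)
  positive_pairs <- unique(positive_pairs[c("disease_id", "drug_id")])
  diseases <- sort(unique(c(diseases %||% character(0),
                            positive_pairs$disease_id)))
  drugs <- sort(unique(c(drugs %||% character(0), positive_pairs$drug_id)))
  bad_d <- setdiff(positive_pairs$disease_id, diseases)
  bad_r <- setdiff(positive_pairs$drug_id, drugs)
  if (length(bad_d) || length(bad_r))
    stopf("positive pairs reference unknown entities: %s",
          paste(c(bad_d, bad_r), collapse = ", "))
  n_pos <- table(factor(positive_pairs$disease_id, levels = diseases))
  saturated <- names(n_pos)[n_pos >= length(drugs)]
  if (length(saturated) > 0L)
    warnf("disease(s) with no negative candidates: %s",
          paste(saturated, collapse = ", "))
  structure(list(diseases = diseases, drugs = drugs,
                 positive_pairs = positive_pairs),
            class = "association_benchmark")
}

#' @export
print.association_benchmark <- function(x, ...) {
  cat(sprintf(
    "association_benchmark: %d diseases, %d drugs, %d positive pairs\n",
    length(x$diseases), length(x$drugs), nrow(x$positive_pairs)))
  invisible(x)
}

positives_of <- function(benchmark, disease) {
  benchmark$positive_pairs$drug_id[
    benchmark$positive_pairs$disease_id == disease]
}

#' Write / read a benchmark as TSV
#'
#' Columns `disease_id`, `drug_id`, `label`. Positive pairs carry label 1;
#' entities appearing in no positive pair are declared with a `.`
#' placeholder partner and label 0 so the entity universes round-trip.
#'
#' @param benchmark an `association_benchmark`.
#' @param path TSV path.
#' @export
write_benchmark <- function(benchmark, path) {
  pos <- data.frame(disease_id = benchmark$positive_pairs$disease_id,
                    drug_id = benchmark$positive_pairs$drug_id, label = 1L,
                    stringsAsFactors = FALSE)
  lone_dis <- setdiff(benchmark$diseases, pos$disease_id)
  lone_drug <- setdiff(benchmark$drugs, pos$drug_id)
  extra <- rbind(
    if (length(lone_dis)) data.frame(disease_id = lone_dis, drug_id = ".",
                                     label = 0L, stringsAsFactors = FALSE),
    if (length(lone_drug)) data.frame(disease_id = ".", drug_id = lone_drug,
                                      label = 0L, stringsAsFactors = FALSE))
  utils::write.table(rbind(pos, extra), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_benchmark
#' @export
read_benchmark <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "integer"))
  pos <- df[df$label == 1L, , drop = FALSE]
  association_benchmark(pos,
                        diseases = setdiff(df$disease_id, "."),
                        drugs = setdiff(df$drug_id, "."))
}

#' Sample training triplets from a benchmark
#'
#' Per disease and per epoch, one positive drug and one negative drug are
#' drawn uniformly; diseases with no positive or no negative candidate are
#' skipped with a warning. Fully reproducible under `rng_seed`.
#'
#' @param benchmark an `association_benchmark`.
#' @param rng_seed integer seed; `NULL` uses the current RNG stream.
#' @param epochs how many epochs' worth of triplets to emit.
#' @param diseases optionally restrict to this disease subset.
#' @return data.frame with columns `epoch`, `disease_id`, `positive_id`,
#'   `negative_id`.
#' @export
sample_triplets <- function(benchmark, rng_seed = NULL, epochs = 1L,
                            diseases = NULL) {
  run <- function() {
    diseases <- diseases %||% benchmark$diseases
    skipped <- character(0)
    rows <- vector("list", epochs)
    for (e in seq_len(epochs)) {
      out <- lapply(diseases, function(d) {
        pos <- positives_of(benchmark, d)
        neg <- setdiff(benchmark$drugs, pos)
        if (length(pos) == 0L || length(neg) == 0L) {
          skipped <<- union(skipped, d)
          return(NULL)
        }
        data.frame(epoch = e, disease_id = d,
                   positive_id = pos[sample.int(length(pos), 1L)],
                   negative_id = neg[sample.int(length(neg), 1L)],
                   stringsAsFactors = FALSE)
      })
      rows[[e]] <- do.call(rbind, out)
    }
    if (length(skipped) > 0L)
      warnf("skipped disease(s) without a positive/negative candidate: %s",
            paste(skipped, collapse = ", "))
    do.call(rbind, rows)
  }
  if (is.null(rng_seed)) run() else with_seed(rng_seed, run())
}

#' Area under the ROC curve
#'
#' Probability that a randomly chosen positive outranks a randomly chosen
#' negative, with ties counted one half; computed via the rank-sum identity
#' with midranks.
#'
#' @param scores numeric vector.
#' @param labels binary vector (0/1 or logical) of the same length.
#' @return AUROC in \[0, 1\].
#' @examples
#' auroc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)) # 0.75
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels))
    stopf("scores and labels must have equal length")
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stopf("auroc needs at least one positive and one negative label")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# -- preprocessing -----------------------------------------------------------

# Diffusion mass spans orders of magnitude, so profiles are log-transformed
# and standardized per feature; statistics are fitted on training entities
# only and reapplied everywhere.
fit_preproc <- function(X, eps = 1e-12) {
  L <- log(X + eps)
  mu <- colMeans(L)
  sd <- apply(L, 2, stats::sd)
  sd[sd < 1e-8] <- 1
  list(mean = mu, sd = sd, eps = eps)
}

apply_preproc <- function(preproc, X) {
  L <- log(X + preproc$eps)
  sweep(sweep(L, 2, preproc$mean, "-"), 2, preproc$sd, "/")
}

# -- the trained model object ------------------------------------------------

new_embedding_model <- function(params, input_dim, layers, margin, preproc,
                                seed, feature_names) {
  structure(list(params = params, input_dim = input_dim, layers = layers,
                 margin = margin, metric = "euclidean", preproc = preproc,
                 seed = seed, feature_names = feature_names),
            class = "embedding_model")
}

#' @export
print.embedding_model <- function(x, ...) {
  cat(sprintf(
    "embedding_model: %d -> %s (ReLU hidden, %s metric, margin %.2g)\n",
    x$input_dim, paste(x$layers, collapse = " -> "), x$metric, x$margin))
  invisible(x)
}

#' Embed raw diffusion profiles with a trained model
#'
#' Applies the model's stored preprocessing (log transform + per-feature
#' standardization fitted on its training fold) and the forward pass.
#'
#' @param model an `embedding_model`.
#' @param profiles matrix, rows = entities, columns = interactome nodes.
#' @return embedding matrix (rows = entities).
#' @export
embed_profiles <- function(model, profiles) {
  if (ncol(profiles) != model$input_dim)
    stopf("profile dimension %d does not match model input %d",
          ncol(profiles), model$input_dim)
  X <- apply_preproc(model$preproc, profiles)
  out <- mlp_forward(model$params, X)
  rownames(out) <- rownames(profiles)
  out
}

#' Score disease-drug pairs with a trained embedding model
#'
#' @param model an `embedding_model` (or an initialized, untrained one).
#' @param disease_profiles,drug_profiles raw profile matrices.
#' @return score matrix (diseases x drugs); score = negative embedding
#'   distance, higher is better.
#' @export
score_pairs <- function(model, disease_profiles, drug_profiles) {
  ed <- embed_profiles(model, disease_profiles)
  er <- embed_profiles(model, drug_profiles)
  -cross_dist(ed, er)
}

#' Model-free baseline ranking from raw diffusion profiles
#'
#' Scores each drug by the Pearson correlation between its raw diffusion
#' profile and the disease's; consumes no trained weights. A zero-variance
#' profile yields score 0 with a warning.
#'
#' @param disease_profile numeric vector (one profile).
#' @param drug_profiles matrix, one row per drug.
#' @return named numeric score vector (higher = better).
#' @export
baseline_rank <- function(disease_profile, drug_profiles) {
  if (stats::sd(disease_profile) == 0) {
    warnf("zero-variance disease profile; baseline scores set to 0")
    return(stats::setNames(numeric(nrow(drug_profiles)),
                           rownames(drug_profiles)))
  }
  sds <- apply(drug_profiles, 1, stats::sd)
  scores <- numeric(nrow(drug_profiles))
  ok <- sds > 0
  if (any(!ok)) warnf("zero-variance drug profile(s); scores set to 0")
  if (any(ok))
    scores[ok] <- as.numeric(stats::cor(disease_profile,
                                        t(drug_profiles[ok, , drop = FALSE])))
  stats::setNames(scores, rownames(drug_profiles))
}

# Pooled evaluation over a disease subset: every (disease, drug) pair with
# drug in the full universe, labelled by the positive set.
pooled_auroc <- function(score_matrix, benchmark, diseases) {
  scores <- numeric(0)
  labels <- integer(0)
  per_disease <- numeric(0)
  for (d in diseases) {
    pos <- positives_of(benchmark, d)
    s <- score_matrix[d, benchmark$drugs]
    l <- as.integer(benchmark$drugs %in% pos)
    if (sum(l) == 0L || sum(l) == length(l)) next
    scores <- c(scores, s)
    labels <- c(labels, l)
    per_disease <- c(per_disease, auroc(s, l))
  }
  if (length(per_disease) == 0L)
    stopf("no evaluable disease in this subset")
  list(pooled = auroc(scores, labels), macro = mean(per_disease),
       n_diseases = length(per_disease))
}

#' Train triplet-loss embedding models under disease-level cross-validation
#'
#' Diseases are split into `folds` groups (drugs are shared across folds,
#' since evaluation ranks drugs per disease). Within each fold the MLP is
#' trained on triplets sampled from the training diseases — one positive and
#' one negative drug per disease per epoch — using the Adam update rule, and
#' evaluated on the held-out diseases: pooled AUROC against all non-positive
#' drugs, plus a per-disease macro average and the model-free
#' profile-correlation baseline on the same held-out split.
#'
#' @param profiles matrix of raw diffusion profiles, rows named by entity
#'   id; must cover every benchmark disease and drug.
#' @param benchmark an `association_benchmark`.
#' @param config list of training settings; see Details.
#' @details Config entries (with defaults): `folds` (5), `max_epochs` (100),
#'   `margin` (1), `lr` (1e-3), `layers` (c(512, 256)), `seed` (1),
#'   `preprocess` (TRUE — log + per-feature standardization fitted on the
#'   training fold's diseases plus all drugs).
#' @return an `embedding_cv`: list with `models` (one `embedding_model` per
#'   fold), `metrics` (data.frame: fold, auroc, macro_auroc, baseline_auroc,
#'   baseline_macro, loss_first, loss_last), `fold_assignment`, `config`.
#' @export
train_embedding_model <- function(profiles, benchmark, config = list()) {
  cfg <- utils::modifyList(
    list(folds = 5L, max_epochs = 100L, margin = 1, lr = 1e-3,
         layers = c(512L, 256L), seed = 1L, preprocess = TRUE), config)
  entities <- c(benchmark$diseases, benchmark$drugs)
  missing <- setdiff(entities, rownames(profiles))
  if (length(missing) > 0L)
    stopf("benchmark entity(ies) missing a profile row: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  evaluable <- vapply(benchmark$diseases, function(d) {
    np <- length(positives_of(benchmark, d))
    np >= 1L && np < length(benchmark$drugs)
  }, logical(1))
  fold_assignment <- with_seed(cfg$seed, {
    ord <- sample(benchmark$diseases)
    folds_shuffled <- rep_len(seq_len(cfg$folds), length(ord))
    stats::setNames(folds_shuffled[match(benchmark$diseases, ord)],
                    benchmark$diseases)
  })
  for (f in seq_len(cfg$folds)) {
    held <- names(fold_assignment)[fold_assignment == f]
    if (!any(evaluable[held]))
      stopf("fold %d contains no evaluable disease", f)
  }
  drug_X <- profiles[benchmark$drugs, , drop = FALSE]
  models <- vector("list", cfg$folds)
  metrics <- vector("list", cfg$folds)
  for (f in seq_len(cfg$folds)) {
    held <- names(fold_assignment)[fold_assignment == f]
    train_d <- setdiff(benchmark$diseases, held)
    pp <- if (isTRUE(cfg$preprocess)) {
      fit_preproc(profiles[c(train_d, benchmark$drugs), , drop = FALSE])
    } else {
      list(mean = rep(0, ncol(profiles)), sd = rep(1, ncol(profiles)),
           eps = 1e-12)
    }
    X <- apply_preproc(pp, profiles[entities, , drop = FALSE])
    rownames(X) <- entities
    params <- mlp_init(ncol(X), cfg$layers, seed = cfg$seed * 1000L + f)
    opt <- adam_init(params)
    losses <- numeric(cfg$max_epochs)
    with_seed(cfg$seed * 100000L + f, {
      for (ep in seq_len(cfg$max_epochs)) {
        tri <- suppressWarnings(
          sample_triplets(benchmark, diseases = train_d))
        step <- triplet_batch_step(params,
                                   X[tri$disease_id, , drop = FALSE],
                                   X[tri$positive_id, , drop = FALSE],
                                   X[tri$negative_id, , drop = FALSE],
                                   cfg$margin)
        upd <- adam_step(params, step$grads, opt, lr = cfg$lr)
        params <- upd$params
        opt <- upd$state
        losses[ep] <- step$loss
      }
    })
    model <- new_embedding_model(params, ncol(X), cfg$layers, cfg$margin,
                                 pp, cfg$seed, colnames(profiles))
    sc <- score_pairs(model, profiles[held, , drop = FALSE], drug_X)
    rownames(sc) <- held
    colnames(sc) <- benchmark$drugs
    ev <- pooled_auroc(sc, benchmark, held[evaluable[held]])
    base_sc <- t(vapply(held, function(d)
      suppressWarnings(baseline_rank(profiles[d, ], drug_X)),
      numeric(nrow(drug_X))))
    colnames(base_sc) <- benchmark$drugs
    bev <- pooled_auroc(base_sc, benchmark, held[evaluable[held]])
    models[[f]] <- model
    metrics[[f]] <- data.frame(
      fold = f, auroc = ev$pooled, macro_auroc = ev$macro,
      baseline_auroc = bev$pooled, baseline_macro = bev$macro,
      loss_first = if (cfg$max_epochs >= 1L) losses[1] else NA_real_,
      loss_last = if (cfg$max_epochs >= 1L) losses[cfg$max_epochs]
        else NA_real_,
      n_eval_diseases = ev$n_diseases)
  }
  structure(list(models = models, metrics = do.call(rbind, metrics),
                 fold_assignment = fold_assignment, config = cfg),
            class = "embedding_cv")
}

#' @export
print.embedding_cv <- function(x, ...) {
  cat(sprintf("embedding_cv: %d folds, mean AUROC %.3f (baseline %.3f)\n",
              nrow(x$metrics), mean(x$metrics$auroc),
              mean(x$metrics$baseline_auroc)))
  invisible(x)
}

# -- serialization -----------------------------------------------------------

#' Save / load a trained embedding model as a text directory
#'
#' Architecture and metadata go to `architecture.json`; weight matrices,
#' biases and preprocessing statistics to TSV files at 17 significant
#' digits, which round-trips IEEE doubles exactly.
#'
#' @param model an `embedding_model`.
#' @param dir target directory.
#' @export
save_embedding_model <- function(model, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta <- list(input_dim = model$input_dim, layers = model$layers,
               margin = model$margin, metric = model$metric,
               seed = model$seed, n_layers = length(model$params$W),
               eps = model$preproc$eps)
  jsonlite::write_json(meta, file.path(dir, "architecture.json"),
                       auto_unbox = TRUE, digits = NA)
  num_tsv <- function(x, path) {
    utils::write.table(format(as.data.frame(x), digits = 17, trim = TRUE,
                              scientific = TRUE),
                       path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  for (i in seq_along(model$params$W)) {
    num_tsv(model$params$W[[i]], file.path(dir, sprintf("W%d.tsv", i)))
    num_tsv(matrix(model$params$b[[i]], nrow = 1),
            file.path(dir, sprintf("b%d.tsv", i)))
  }
  num_tsv(rbind(model$preproc$mean, model$preproc$sd),
          file.path(dir, "preproc.tsv"))
  writeLines(model$feature_names, file.path(dir, "features.txt"))
  invisible(dir)
}

#' @rdname save_embedding_model
#' @export
load_embedding_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "architecture.json"),
                              simplifyVector = TRUE)
  read_num <- function(path) as.matrix(utils::read.table(path, sep = "\t"))
  W <- list(); b <- list()
  for (i in seq_len(meta$n_layers)) {
    W[[i]] <- unname(read_num(file.path(dir, sprintf("W%d.tsv", i))))
    b[[i]] <- as.numeric(read_num(file.path(dir, sprintf("b%d.tsv", i))))
  }
  pp <- read_num(file.path(dir, "preproc.tsv"))
  new_embedding_model(list(W = W, b = b), meta$input_dim, meta$layers,
                      meta$margin,
                      list(mean = as.numeric(pp[1, ]),
                           sd = as.numeric(pp[2, ]), eps = meta$eps),
                      meta$seed,
                      readLines(file.path(dir, "features.txt")))
}
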