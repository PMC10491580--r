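#' @title Recipe enrichment scoring and constrained ingredient substitution
#'
#' @description
#' Recipes are scored by how many distinct predicted modulator molecules
#' their ingredients contain (the enrichment score), and optimized by
#' substituting ingredients for candidates that appear in similar cooking
#' contexts. Substitute candidates come from occurrence-level context
#' embeddings: for every occurrence of an ingredient, its nearest
#' neighbouring occurrences are found, and a candidate's substitute score is
#' the number of neighbour slots it fills across all of the query
#' ingredient's occurrences — frequent co-context implies culinary
#' interchangeability. Substitutions are then constrained by modulator
#' content, allergies and patient preferences.
#'
#' @name recipe_optimization
NULL

#' The 14 canonical food allergen labels
#'
#' The major allergen categories that dietary contexts and allergen
#' databases may reference.
#' @export
ALLERGENS14 <- c("celery", "crustaceans", "eggs", "fish", "gluten", "lupin",
                 "milk", "molluscs", "mustard", "nuts", "peanuts", "sesame",
                 "soya", "sulphites")

#' Construct a recipe
#'
#' @param recipe_id identifier.
#' @param title display title.
#' @param ingredients character vector of canonical ingredient ids (at least
#'   one).
#' @param instructions character vector of instruction steps.
#' @return a `recipe`.
#' @export
recipe <- function(recipe_id, title = recipe_id, ingredients,
                   instructions = character(0)) {
  if (length(ingredients) == 0L) stopf("a recipe needs >= 1 ingredient")
  structure(list(recipe_id = recipe_id, title = title,
                 ingredients = as.character(ingredients),
                 instructions = as.character(instructions)),
            class = "recipe")
}

#' @export
print.recipe <- function(x, ...) {
  cat(sprintf("recipe '%s' (%s): %s\n", x$recipe_id, x$title,
              paste(x$ingredients, collapse = ", ")))
  invisible(x)
}

#' Read / write recipes as Recipe1M-style JSON
#'
#' An array of objects `{id, title, ingredients: [strings],
#' instructions: [strings]}`.
#'
#' @param path JSON file path.
#' @param recipes list of `recipe` objects.
#' @export
read_recipes_json <- function(path) {
  arr <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(arr, function(r)
    recipe(r$id, r$title %||% r$id,
           vapply(r$ingredients, as.character, character(1)),
           vapply(r$instructions %||% list(), as.character, character(1))))
}

#' @rdname read_recipes_json
#' @export
write_recipes_json <- function(recipes, path) {
  arr <- lapply(recipes, function(r)
    list(id = r$recipe_id, title = r$title,
         ingredients = as.list(r$ingredients),
         instructions = as.list(r$instructions)))
  jsonlite::write_json(arr, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# enrichment over a plain vector of canonical ids
enrichment_of_ids <- function(ids, modulators, composition) {
  comp <- composition[composition$ingredient %in% ids &
                        composition$molecule_id %in% modulators, ,
                      drop = FALSE]
  length(unique(comp$molecule_id))
}

#' Enrichment score of a recipe
#'
#' Number of distinct modulator molecules present in the union of the
#' recipe ingredients' compositions. The alternative reading — the number of
#' ingredients containing at least one modulator — is available via `mode`.
#'
#' @param recipe a `recipe` (canonical ingredient ids).
#' @param modulators character vector of modulator molecule ids.
#' @param composition data.frame (`ingredient`, `molecule_id`).
#' @param mode `"distinct_molecules"` (default) or `"ingredient_count"`.
#' @param warn_unresolved warn about ingredients absent from the
#'   composition table (they contribute zero).
#' @return integer score.
#' @export
enrichment_score <- function(recipe, modulators, composition,
                             mode = c("distinct_molecules",
                                      "ingredient_count"),
                             warn_unresolved = FALSE) {
  mode <- match.arg(mode)
  unresolved <- setdiff(recipe$ingredients, composition$ingredient)
  if (warn_unresolved && length(unresolved) > 0L)
    warnf("ingredient(s) absent from composition table (count 0): %s",
          paste(unresolved, collapse = ", "))
  if (mode == "distinct_molecules")
    return(enrichment_of_ids(recipe$ingredients, modulators, composition))
  comp <- composition[composition$molecule_id %in% modulators, ,
                      drop = FALSE]
  sum(unique(recipe$ingredients) %in% comp$ingredient)
}

#' Construct occurrence embeddings
#'
#' Context-dependent vectors, one per appearance of an ingredient in
#' cooking instructions.
#'
#' @param occurrence_id,canonical_id character vectors, one entry per
#'   occurrence.
#' @param vectors numeric matrix, one row per occurrence (default
#'   dimension 768 in the upstream corpus; any fixed dimension >= 2 works).
#' @return an `occurrence_embeddings`.
#' @export
occurrence_embeddings <- function(occurrence_id, canonical_id, vectors) {
  vectors <- as.matrix(vectors)
  if (length(occurrence_id) != nrow(vectors) ||
      length(canonical_id) != nrow(vectors))
    stopf("occurrence ids, canonical ids and vector rows must align")
  if (ncol(vectors) < 2L) stopf("embedding dimension must be >= 2")
  rownames(vectors) <- occurrence_id
  structure(list(ids = data.frame(occurrence_id = as.character(occurrence_id),
                                  canonical_id = as.character(canonical_id),
                                  stringsAsFactors = FALSE),
                 vectors = vectors),
            class = "occurrence_embeddings")
}

#' @export
print.occurrence_embeddings <- function(x, ...) {
  cat(sprintf("occurrence_embeddings: %d occurrences, %d ingredients, dim %d\n",
              nrow(x$vectors), length(unique(x$ids$canonical_id)),
              ncol(x$vectors)))
  invisible(x)
}

#' Read / write occurrence embeddings as TSV
#'
#' Columns: `occurrence_id`, `canonical_id`, then the embedding dimensions.
#'
#' @param emb an `occurrence_embeddings`.
#' @param path TSV path.
#' @export
write_embeddings <- function(emb, path) {
  df <- data.frame(emb$ids, emb$vectors, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  occurrence_embeddings(df$occurrence_id, df$canonical_id,
                        as.matrix(df[, -(1:2), drop = FALSE]))
}

#' Average occurrence embeddings per ingredient
#'
#' @param emb an `occurrence_embeddings`.
#' @return matrix, one row per canonical id (arithmetic mean of its
#'   occurrence vectors), rows sorted by id.
#' @export
average_ingredient_embeddings <- function(emb) {
  sums <- rowsum(emb$vectors, emb$ids$canonical_id)
  counts <- as.integer(table(emb$ids$canonical_id)[rownames(sums)])
  sums / counts
}

#' Build the ingredient substitution table from occurrence embeddings
#'
#' For every occurrence of an ingredient, its `k` nearest occurrence vectors
#' (Euclidean; occurrences of the same ingredient excluded — a self-match
#' can never be a substitute) are found, and each candidate ingredient's
#' substitute score is the number of neighbour slots it fills across all of
#' the query ingredient's occurrences. Candidates are kept when their score
#' exceeds `min_score` AND exceeds `max_ratio` times the highest score for
#' that query ingredient.
#'
#' @param emb an `occurrence_embeddings`.
#' @param k neighbours per occurrence (default 200).
#' @param min_score absolute score threshold (strict; default 100).
#' @param max_ratio fraction of the per-ingredient top score (strict;
#'   default 0.1).
#' @param block_size rows per distance block (memory knob).
#' @return a `substitution_table`: named list, per canonical id a data.frame
#'   (`candidate_id`, `score`) sorted by descending score then id.
#' @export
build_substitution_table <- function(emb, k = 200L, min_score = 100,
                                     max_ratio = 0.1, block_size = 512L) {
  if (k < 1L) stopf("k must be >= 1")
  X <- emb$vectors
  ids <- emb$ids$canonical_id
  n <- nrow(X)
  if (n < k + 1L)
    warnf("only %d occurrences for k = %d: using all eligible neighbours",
          n, k)
  tallies <- new.env(parent = emptyenv())
  for (ing in unique(ids)) assign(ing, integer(0), envir = tallies)
  for (start in seq(1L, n, by = block_size)) {
    rows <- start:min(start + block_size - 1L, n)
    D <- cross_dist(X[rows, , drop = FALSE], X)
    for (bi in seq_along(rows)) {
      i <- rows[bi]
      d <- D[bi, ]
      d[ids == ids[i]] <- Inf      # exclude self + same-ingredient
      eligible <- which(is.finite(d))
      if (length(eligible) == 0L) next
      kk <- min(k, length(eligible))
      nn <- order(d, seq_len(n))[seq_len(kk)]
      hits <- ids[nn]
      cur <- get(ids[i], envir = tallies)
      tab <- table(hits)
      for (nm in names(tab)) {
        prev <- if (nm %in% names(cur)) cur[[nm]] else 0L
        cur[nm] <- prev + as.integer(tab[[nm]])
      }
      assign(ids[i], cur, envir = tallies)
    }
  }
  out <- lapply(sort(unique(ids)), function(ing) {
    scores <- get(ing, envir = tallies)
    if (length(scores) == 0L)
      return(data.frame(candidate_id = character(0), score = integer(0),
                        stringsAsFactors = FALSE))
    keep <- scores > min_score & scores > max_ratio * max(scores)
    scores <- scores[keep]
    df <- data.frame(candidate_id = names(scores),
                     score = as.integer(scores), stringsAsFactors = FALSE)
    df <- df[order(-df$score, df$candidate_id), , drop = FALSE]
    rownames(df) <- NULL
    df
  })
  names(out) <- sort(unique(ids))
  structure(out, class = "substitution_table")
}

#' @export
print.substitution_table <- function(x, ...) {
  n_cand <- vapply(x, nrow, integer(1))
  cat(sprintf("substitution_table: %d ingredients, %d with candidates (median %d)\n",
              length(x), sum(n_cand > 0),
              as.integer(stats::median(n_cand))))
  invisible(x)
}

#' Keep only substitutes with strictly more modulator molecules
#'
#' @param table a `substitution_table`.
#' @param modulator_counts named integer vector, canonical id ->
#'   distinct-modulator count (ids absent default to 0), e.g. from
#'   [ingredients_by_modulator_count()].
#' @return the filtered `substitution_table`.
#' @export
filter_substitutes_by_modulators <- function(table, modulator_counts) {
  cnt <- function(id) {
    v <- modulator_counts[id]
    ifelse(is.na(v), 0L, as.integer(v))
  }
  out <- lapply(names(table), function(key) {
    df <- table[[key]]
    df[cnt(df$candidate_id) > cnt(key), , drop = FALSE]
  })
  names(out) <- names(table)
  structure(out, class = "substitution_table")
}

# candidates for slot `id` given recipe state: drop candidates already used
# as substitutes and candidates present in the recipe, where "present"
# covers both the current state and the original ingredient list (a
# substitution never reintroduces an ingredient the recipe started with)
eligible_candidates <- function(table, id, exclude) {
  df <- table[[id]]
  if (is.null(df) || nrow(df) == 0L)
    return(data.frame(candidate_id = character(0), score = integer(0),
                      stringsAsFactors = FALSE))
  df[!(df$candidate_id %in% exclude), , drop = FALSE]
}

#' Randomly mutate a recipe through its substitution table
#'
#' Walks the ingredients in recipe order and substitutes each by one
#' uniformly sampled candidate from its (modulator-filtered) list, under two
#' constraints: the same substitute is never used for two different
#' ingredients, and a substitute already present in the recipe is not
#' allowed. An ingredient with no surviving candidate is left unchanged.
#' When `modulators` and `composition` are supplied, a sampled substitution
#' that would strictly decrease the recipe's enrichment score is also
#' rejected, keeping the mutation monotone in enrichment.
#'
#' @param recipe a `recipe`.
#' @param table a `substitution_table` (normally modulator-filtered).
#' @param rng_seed integer seed; `NULL` uses the current stream.
#' @param modulators,composition optional; enable the enrichment guard.
#' @return the mutated `recipe`, with a `substitutions` attribute
#'   (data.frame `from`, `to`).
#' @export
mutate_recipe <- function(recipe, table, rng_seed = NULL,
                          modulators = NULL, composition = NULL) {
  run <- function() {
    ids <- recipe$ingredients
    orig <- ids
    used <- character(0)
    subs <- list()
    for (j in seq_along(ids)) {
      cand <- eligible_candidates(table, ids[j], c(orig, ids, used))
      if (is.null(cand) || nrow(cand) == 0L) next
      pick <- cand$candidate_id[sample.int(nrow(cand), 1L)]
      if (!is.null(modulators) && !is.null(composition)) {
        before <- enrichment_of_ids(ids, modulators, composition)
        trial <- ids
        trial[j] <- pick
        if (enrichment_of_ids(trial, modulators, composition) < before)
          next
      }
      subs[[length(subs) + 1L]] <- data.frame(from = ids[j], to = pick,
                                              stringsAsFactors = FALSE)
      ids[j] <- pick
      used <- c(used, pick)
    }
    out <- recipe
    out$ingredients <- ids
    attr(out, "substitutions") <- if (length(subs)) do.call(rbind, subs)
      else data.frame(from = character(0), to = character(0))
    out
  }
  if (is.null(rng_seed)) run() else with_seed(rng_seed, run())
}

#' Construct a dietary context
#'
#' @param allergies subset of [ALLERGENS14].
#' @param preferences named numeric vector, canonical id -> 1..5 liking
#'   score (1 strong dislike, 5 strong like); unrated ingredients default to
#'   the neutral 3.
#' @param allergen_db data.frame (`ingredient`, `allergen`) listing which of
#'   the 14 allergens each ingredient carries; ingredients absent from the
#'   table are allergen-free.
#' @return a `dietary_context`.
#' @export
dietary_context <- function(allergies = character(0),
                            preferences = numeric(0),
                            allergen_db = data.frame(
                              ingredient = character(0),
                              allergen = character(0))) {
  bad <- setdiff(allergies, ALLERGENS14)
  if (length(bad) > 0L)
    stopf("unknown allergen label(s): %s (must be among the 14 canonical labels)",
          paste(bad, collapse = ", "))
  if (length(preferences) > 0L &&
      (any(preferences < 1) || any(preferences > 5)))
    stopf("preference scores must lie in 1..5")
  stopifnot(all(c("ingredient", "allergen") %in% names(allergen_db)))
  bad_db <- setdiff(allergen_db$allergen, ALLERGENS14)
  if (length(bad_db) > 0L)
    stopf("allergen_db contains unknown label(s): %s",
          paste(bad_db, collapse = ", "))
  structure(list(allergies = allergies, preferences = preferences,
                 allergen_db = allergen_db),
            class = "dietary_context")
}

allergens_of <- function(ctx, id) {
  ctx$allergen_db$allergen[ctx$allergen_db$ingredient == id]
}

is_allergenic <- function(ctx, id) {
  length(intersect(allergens_of(ctx, id), ctx$allergies)) > 0L
}

preference_of <- function(ctx, id) {
  v <- ctx$preferences[id]
  ifelse(is.na(v), 3, as.numeric(v))
}

#' Remove or repair recipes that violate a patient's allergies
#'
#' Every ingredient carrying one of the patient's allergens is substituted
#' by its highest-scoring non-allergenic candidate (subject to the usual
#' no-reuse / not-already-present constraints); recipes in which some
#' allergenic ingredient has no safe candidate are removed. The returned
#' recipes contain zero allergenic ingredients.
#'
#' @param recipes list of `recipe`s.
#' @param ctx a `dietary_context`.
#' @param table a `substitution_table`.
#' @return the filtered/repaired list of `recipe`s.
#' @export
apply_allergy_constraints <- function(recipes, ctx, table) {
  if (length(ctx$allergies) == 0L) return(recipes)
  out <- list()
  for (r in recipes) {
    ids <- r$ingredients
    orig <- ids
    used <- character(0)
    ok <- TRUE
    for (j in seq_along(ids)) {
      if (!is_allergenic(ctx, ids[j])) next
      cand <- eligible_candidates(table, ids[j],
                                  setdiff(c(orig, ids, used), ids[j]))
      if (!is.null(cand) && nrow(cand) > 0L) {
        safe <- !vapply(cand$candidate_id, is_allergenic, logical(1),
                        ctx = ctx)
        cand <- cand[safe, , drop = FALSE]
      }
      if (is.null(cand) || nrow(cand) == 0L) {
        ok <- FALSE
        break
      }
      pick <- cand$candidate_id[1L]   # highest score, deterministic
      ids[j] <- pick
      used <- c(used, pick)
    }
    if (ok) {
      r$ingredients <- ids
      out[[length(out) + 1L]] <- r
    }
  }
  out
}

#' Optimize a recipe for modulator content and patient preferences
#'
#' Walks the ingredients in order; a substitution is applied iff the patient
#' strictly prefers the new ingredient while the recipe's enrichment score
#' does not decrease, or the enrichment score strictly increases while the
#' preference does not decrease. Candidates are tried in substitute-score
#' order and the first admissible one is taken; the mutation constraints
#' (no substitute reuse, none already present) still hold.
#'
#' @param recipe a `recipe`.
#' @param ctx a `dietary_context` (preferences default to neutral 3).
#' @param table a `substitution_table`.
#' @param modulators modulator molecule ids.
#' @param composition data.frame (`ingredient`, `molecule_id`).
#' @return the optimized `recipe` with a `substitutions` attribute.
#' @export
optimize_with_preferences <- function(recipe, ctx, table, modulators,
                                      composition) {
  ids <- recipe$ingredients
  orig <- ids
  used <- character(0)
  subs <- list()
  for (j in seq_along(ids)) {
    cand <- eligible_candidates(table, ids[j], c(orig, ids, used))
    if (is.null(cand) || nrow(cand) == 0L) next
    before <- enrichment_of_ids(ids, modulators, composition)
    pref_old <- preference_of(ctx, ids[j])
    for (ci in seq_len(nrow(cand))) {
      pick <- cand$candidate_id[ci]
      trial <- ids
      trial[j] <- pick
      d_enrich <- enrichment_of_ids(trial, modulators, composition) - before
      d_pref <- preference_of(ctx, pick) - pref_old
      if ((d_pref > 0 && d_enrich >= 0) || (d_enrich > 0 && d_pref >= 0)) {
        subs[[length(subs) + 1L]] <- data.frame(from = ids[j], to = pick,
                                                stringsAsFactors = FALSE)
        ids <- trial
        used <- c(used, pick)
        break
      }
    }
  }
  out <- recipe
  out$ingredients <- ids
  attr(out, "substitutions") <- if (length(subs)) do.call(rbind, subs)
    else data.frame(from = character(0), to = character(0))
  out
}

#' Read a food composition, curated-direction or allergen CSV
#'
#' `read_composition()` expects columns `ingredient`, `molecule_id`;
#' `read_curated_directions()` expects `molecule_id`, `direction`, optional
#' `evidence`; `read_allergen_db()` expects `ingredient`, `allergen`.
#'
#' @param path CSV path.
#' @export
read_composition <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("ingredient", "molecule_id") %in% names(df)))
  unique(df[c("ingredient", "molecule_id")])
}

#' @rdname read_composition
#' @export
read_curated_directions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("molecule_id", "direction") %in% names(df)))
  df
}

#' @rdname read_composition
#' @export
read_allergen_db <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("ingredient", "allergen") %in% names(df)))
  df
}
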