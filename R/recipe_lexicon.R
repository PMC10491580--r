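#' @title Ingredient normalization and lexicon matching
#'
#' @description
#' Ingredient names arriving from recipe corpora and from the food
#' composition table are free text; before any scoring they are normalized
#' (lowercased, whitespace collapsed, plurals stripped) and matched into a
#' shared lexicon. Two names match when they share their first two or last
#' two words, or the same word in first or last position — so "king oyster
#' mushroom" and "dried porcini mushroom" resolve to the same ingredient.
#' The match relation is not transitive, so its connected components define
#' the canonical ingredient identities.
#'
#' @name recipe_lexicon
NULL

# Pluralization rule, centralized: "-oes" plurals lose "es"
# (potatoes -> potato, tomatoes -> tomato); otherwise a trailing "s" is
# stripped unless the token ends in "ss" (glass, swiss) or is at most 2
# characters long.
depluralize <- function(token) {
  oes <- endsWith(token, "oes") & nchar(token) > 3
  token[oes] <- substr(token[oes], 1, nchar(token[oes]) - 2)
  strip <- endsWith(token, "s") & !endsWith(token, "ss") & nchar(token) > 2
  token[strip] <- substr(token[strip], 1, nchar(token[strip]) - 1)
  token
}

#' Normalize a raw ingredient name
#'
#' Lowercases, collapses runs of whitespace, trims, and de-pluralizes each
#' token: "-oes" plurals lose "es" (potatoes, tomatoes); otherwise a
#' trailing "s" is stripped unless the token ends in "ss" or has at most
#' two characters.
#'
#' @param raw non-empty ingredient string.
#' @return an `ingredient`: list with `raw_name`, `tokens` and `normalized`
#'   (tokens joined by single spaces).
#' @examples
#' normalize_ingredient("New  Potatoes")$tokens # "new" "potato"
#' @export
normalize_ingredient <- function(raw) {
  if (length(raw) != 1L || is.na(raw) || !nzchar(trimws(raw)))
    stopf("ingredient name must be a non-empty string")
  tokens <- strsplit(trimws(tolower(raw)), "\\s+")[[1]]
  tokens <- depluralize(tokens)
  structure(list(raw_name = raw, tokens = tokens,
                 normalized = paste(tokens, collapse = " ")),
            class = "ingredient")
}

#' Do two normalized ingredient names refer to the same ingredient?
#'
#' True when the names share the first two words, the last two words, the
#' first word, or the last word. Single-token names participate through the
#' single-token clauses.
#'
#' @param a,b `ingredient` objects from [normalize_ingredient()].
#' @return logical.
#' @export
match_ingredients <- function(a, b) {
  ta <- a$tokens
  tb <- b$tokens
  first_two <- length(ta) >= 2 && length(tb) >= 2 &&
    all(ta[1:2] == tb[1:2])
  last_two <- length(ta) >= 2 && length(tb) >= 2 &&
    all(utils::tail(ta, 2) == utils::tail(tb, 2))
  first_one <- ta[1] == tb[1]
  last_one <- ta[length(ta)] == tb[length(tb)]
  first_two || last_two || first_one || last_one
}

#' Build an ingredient lexicon from raw names
#'
#' Normalizes every name and partitions the unique normalized forms into
#' connected components of the match relation (the relation itself is not
#' transitive; taking components closes it into an equivalence). Each
#' component receives one canonical id: its lexicographically smallest
#' member with spaces replaced by underscores.
#'
#' @param names character vector of raw ingredient names.
#' @return an `ingredient_lexicon`: list with `table` (data.frame:
#'   `raw_name`, `normalized`, `canonical_id`) and `components` (named list
#'   canonical_id -> member normalized names).
#' @export
build_lexicon <- function(names) {
  ings <- lapply(names, normalize_ingredient)
  normalized <- vapply(ings, `[[`, character(1), "normalized")
  uniq <- sort(unique(normalized))
  uings <- lapply(uniq, normalize_ingredient)
  n <- length(uniq)
  from <- integer(0); to <- integer(0)
  if (n >= 2) {
    # first/last token index prunes the quadratic scan: only pairs sharing
    # a positional token can match
    firsts <- vapply(uings, function(x) x$tokens[1], character(1))
    lasts <- vapply(uings, function(x) x$tokens[length(x$tokens)],
                    character(1))
    cand <- unique(rbind(
      do.call(rbind, lapply(split(seq_len(n), firsts),
                            function(ix) if (length(ix) > 1)
                              t(utils::combn(ix, 2)))),
      do.call(rbind, lapply(split(seq_len(n), lasts),
                            function(ix) if (length(ix) > 1)
                              t(utils::combn(ix, 2))))))
    if (!is.null(cand) && nrow(cand) > 0) {
      keep <- vapply(seq_len(nrow(cand)), function(r)
        match_ingredients(uings[[cand[r, 1]]], uings[[cand[r, 2]]]),
        logical(1))
      from <- cand[keep, 1]
      to <- cand[keep, 2]
    }
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to), directed = FALSE,
    vertices = data.frame(name = as.character(seq_len(n))))
  comp <- igraph::components(g)$membership[as.character(seq_len(n))]
  canon_of_comp <- vapply(split(uniq, comp), function(members)
    gsub(" ", "_", min(members)), character(1))
  canonical <- canon_of_comp[as.character(comp)]
  tab <- data.frame(raw_name = names, normalized = normalized,
                    canonical_id = canonical[match(normalized, uniq)],
                    stringsAsFactors = FALSE)
  structure(list(table = tab, components = split(uniq, canonical)),
            class = "ingredient_lexicon")
}

#' @export
print.ingredient_lexicon <- function(x, ...) {
  cat(sprintf("ingredient_lexicon: %d names -> %d canonical ingredients\n",
              nrow(x$table), length(unique(x$table$canonical_id))))
  invisible(x)
}

#' Resolve a raw name against a lexicon
#'
#' Exact normalized lookup first; otherwise the first lexicon entry the name
#' matches under [match_ingredients()]; `NA` when nothing matches.
#'
#' @param lexicon an `ingredient_lexicon`.
#' @param raw raw ingredient name.
#' @return canonical id or `NA_character_`.
#' @export
resolve_ingredient <- function(lexicon, raw) {
  ing <- normalize_ingredient(raw)
  hit <- match(ing$normalized, lexicon$table$normalized)
  if (!is.na(hit)) return(lexicon$table$canonical_id[hit])
  uniq <- unique(lexicon$table[c("normalized", "canonical_id")])
  for (i in seq_len(nrow(uniq))) {
    if (match_ingredients(ing, normalize_ingredient(uniq$normalized[i])))
      return(uniq$canonical_id[i])
  }
  NA_character_
}
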