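#' @title Ranking food molecules against the phenotype
#'
#' @description
#' Food molecules whose network-wide effect resembles the radioresistance
#' phenotype's are candidate radioresponse modulators. Molecules are ranked
#' by distance to the phenotype either in the learned embedding space or
#' directly between raw diffusion profiles (correlation distance). Because
#' diffusion proximity carries no sign, a curated direction list — assembled
#' by literature review, never automated — filters the top candidates down
#' to modulators acting in the desired direction, which are then rolled up
#' to the ingredients that contain them.
#'
#' @name modulator_discovery
NULL

#' Rank food molecules by proximity to the phenotype
#'
#' @param phenotype_id entity id of the phenotype row in `profiles`.
#' @param molecule_ids molecule entity ids (rows of `profiles`).
#' @param profiles raw diffusion-profile matrix covering phenotype and
#'   molecules.
#' @param model optional trained `embedding_model`; when supplied, distance
#'   is Euclidean in embedding space, otherwise correlation distance
#'   (1 - Pearson) between raw profiles.
#' @param k how many top molecules to keep (default 100).
#' @return a `molecule_ranking`: data.frame (`molecule_id`, `distance`)
#'   sorted by ascending distance, ties broken lexicographically, with
#'   attributes `phenotype_id` and `ranking_space`.
#' @export
rank_food_molecules <- function(phenotype_id, molecule_ids, profiles,
                                model = NULL, k = 100L) {
  if (k <= 0) stopf("k must be positive")
  molecule_ids <- unique(as.character(molecule_ids))
  if (k > length(molecule_ids))
    stopf("k (%d) exceeds the number of molecules (%d)", k,
          length(molecule_ids))
  missing <- setdiff(c(phenotype_id, molecule_ids), rownames(profiles))
  if (length(missing) > 0L)
    stopf("missing profile row(s): %s", paste(missing, collapse = ", "))
  if (!is.null(model)) {
    space <- "embedding"
    E <- embed_profiles(model, profiles[c(phenotype_id, molecule_ids), ,
                                        drop = FALSE])
    d <- as.numeric(cross_dist(E[1, , drop = FALSE],
                               E[-1, , drop = FALSE]))
  } else {
    space <- "raw_profile"
    ph <- profiles[phenotype_id, ]
    d <- 1 - as.numeric(stats::cor(ph, t(profiles[molecule_ids, ,
                                                  drop = FALSE])))
  }
  ord <- order(d, molecule_ids)
  out <- data.frame(molecule_id = molecule_ids[ord], distance = d[ord],
                    stringsAsFactors = FALSE)[seq_len(k), ]
  rownames(out) <- NULL
  structure(out, phenotype_id = phenotype_id, ranking_space = space,
            class = c("molecule_ranking", "data.frame"))
}

#' Filter a molecule ranking by curated modulation direction
#'
#' Keeps, in ranking order, the molecules whose curated direction equals
#' `keep`; molecules absent from the curated list are dropped (diffusion
#' proximity alone cannot sign the modulation).
#'
#' @param ranking a `molecule_ranking`.
#' @param curated data.frame with columns `molecule_id`, `direction`
#'   (one of `"positive"`, `"negative"`, `"unknown"`), optional `evidence`.
#' @param keep direction to retain (`"positive"` or `"negative"`).
#' @return the filtered `molecule_ranking` (possibly empty, with a warning).
#' @export
apply_direction_filter <- function(ranking, curated,
                                   keep = c("positive", "negative")) {
  keep <- match.arg(keep)
  stopifnot(all(c("molecule_id", "direction") %in% names(curated)))
  if (anyDuplicated(curated$molecule_id))
    stopf("curated list has duplicate molecule_id(s)")
  dir <- stats::setNames(as.character(curated$direction),
                         curated$molecule_id)
  status <- dir[ranking$molecule_id]
  dropped_unknown <- sum(is.na(status))
  if (dropped_unknown > 0L)
    message(sprintf("%d ranked molecule(s) absent from the curated list were dropped",
                    dropped_unknown))
  out <- ranking[!is.na(status) & status == keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) warnf("direction filter left no molecules")
  structure(out, phenotype_id = attr(ranking, "phenotype_id"),
            ranking_space = attr(ranking, "ranking_space"),
            class = c("molecule_ranking", "data.frame"))
}

#' Rank ingredients by how many distinct modulators they contain
#'
#' @param modulators character vector of modulator molecule ids.
#' @param composition data.frame with columns `ingredient`, `molecule_id`.
#' @return data.frame (`ingredient`, `n_modulators`) sorted by descending
#'   distinct-modulator count, ties lexicographic; ingredients containing no
#'   modulator appear last with count 0.
#' @export
ingredients_by_modulator_count <- function(modulators, composition) {
  stopifnot(all(c("ingredient", "molecule_id") %in% names(composition)))
  comp <- unique(composition[c("ingredient", "molecule_id")])
  ingredients <- sort(unique(comp$ingredient))
  hits <- comp[comp$molecule_id %in% modulators, , drop = FALSE]
  counts <- table(factor(hits$ingredient, levels = ingredients))
  out <- data.frame(ingredient = ingredients,
                    n_modulators = as.integer(counts),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_modulators, out$ingredient), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mechanistic subnetwork linking a molecule to the phenotype
#'
#' Returns the induced subgraph over the union of the two seed sets plus the
#' `q` nodes most co-visited by both walks (largest
#' `min(profile_molecule, profile_phenotype)`), with the shortest paths
#' between the seed sets annotated — the network context in which the
#' molecule's targets reach the phenotype's proteins and functions.
#'
#' @param molecule_seed,phenotype_seed `seed_vector`s on the same graph.
#' @param graph the `interactome_graph`.
#' @param molecule_profile,phenotype_profile their `diffusion_profile`s.
#' @param q number of top co-visited nodes to add (default 10).
#' @return list with `subgraph` (igraph), `nodes` (data.frame: node_id,
#'   role, co_visit), `paths` (list of shortest node paths between the seed
#'   sets) and `no_path` flag.
#' @export
explain_association <- function(molecule_seed, phenotype_seed, graph,
                                molecule_profile, phenotype_profile,
                                q = 10L) {
  co <- pmin(molecule_profile$values, phenotype_profile$values)
  mol_nodes <- names(molecule_seed$indicator)[molecule_seed$indicator > 0]
  phe_nodes <- names(phenotype_seed$indicator)[phenotype_seed$indicator > 0]
  seeds <- union(mol_nodes, phe_nodes)
  top_q <- names(sort(co[setdiff(names(co), seeds)], decreasing = TRUE))
  top_q <- utils::head(top_q, q)
  keep <- c(seeds, top_q)
  ig <- igraph::graph_from_data_frame(
    graph$edges[c("from", "to", "edge_type")], directed = FALSE,
    vertices = graph$nodes)
  sub <- igraph::induced_subgraph(ig, keep)
  paths <- list()
  no_path <- TRUE
  for (m in mol_nodes) {
    sp <- suppressWarnings(
      igraph::shortest_paths(ig, from = m, to = phe_nodes,
                             output = "vpath")$vpath)
    sp <- Filter(function(p) length(p) > 0, sp)
    if (length(sp) > 0) {
      no_path <- FALSE
      lens <- vapply(sp, length, integer(1))
      best <- sp[[which.min(lens)]]
      paths[[m]] <- names(best)
    }
  }
  role <- ifelse(keep %in% mol_nodes & keep %in% phe_nodes, "shared_seed",
          ifelse(keep %in% mol_nodes, "molecule_target",
          ifelse(keep %in% phe_nodes, "phenotype_gene", "co_visited")))
  list(subgraph = sub,
       nodes = data.frame(node_id = keep, role = role,
                          co_visit = as.numeric(co[keep]),
                          stringsAsFactors = FALSE),
       paths = paths, no_path = no_path)
}
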