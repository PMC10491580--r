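#' @title Seeded synthetic-data generators with planted signal
#'
#' @description
#' Desk-scale generators for every input the pipeline consumes: a two-layer
#' interactome with community structure, a drug-disease benchmark whose
#' positive pairs share network neighbourhoods, clustered ingredient
#' occurrence embeddings, recipes drawing ingredients from culinary
#' clusters, a food composition table with planted modulator-enriched
#' ingredients, an allergen database and a curated direction list. Every
#' generator is a pure function of the `simulation_config`, so identical
#' configs reproduce outputs byte-for-byte, and the planted structure makes
#' each stage's recovery behaviour testable: diseases and their positive
#' drugs target the same protein community, modulator molecules target the
#' phenotype's community, and modulator molecules concentrate in a known
#' enriched ingredient subset.
#'
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' @param n_proteins,n_functions node counts for the two interactome layers.
#' @param community_count protein (and function) community count.
#' @param ppi_within,ppi_between protein-protein edge densities inside /
#'   across communities.
#' @param pf_per_protein protein-function links per protein.
#' @param ff_shortcuts extra ancestor-descendant shortcut edges in the
#'   function hierarchy beyond the spanning tree.
#' @param within_function_bias probability a protein-function link stays in
#'   the protein's community.
#' @param n_diseases,n_drugs,n_food_molecules entity counts.
#' @param targets_per_entity protein targets per disease/drug/molecule.
#' @param phenotype_targets protein targets of the phenotype seed.
#' @param positives_per_disease positive drugs drawn per disease.
#' @param positive_overlap probability a positive drug is drawn from the
#'   disease's own community (0 = no signal, positives uniform over drugs).
#' @param offtarget_pools,offtarget_pool_size number and size of
#'   "frequent-hitter" protein pools modelling promiscuous off-target
#'   binding; every entity additionally seeds proteins from one such pool.
#' @param offtarget_min,offtarget_max range of off-target seeds per entity
#'   (uniform integer draw).
#' @param n_modulator_molecules molecules planted to target the phenotype's
#'   community.
#' @param n_ingredients,occurrences_per_ingredient food-world sizes.
#' @param n_culinary_clusters ingredient cluster count.
#' @param embedding_dim occurrence-embedding dimension (>= 2).
#' @param cluster_spread within-cluster Gaussian sd of occurrence vectors
#'   (cluster centers have sd 2).
#' @param n_enriched_ingredients ingredients carrying planted modulators.
#' @param n_recipes recipe count.
#' @param recipe_size length-2 integer range of ingredients per recipe.
#' @param rng_seed master seed; all generators derive their streams from it.
#' @return a validated `simulation_config` list.
#' @export
simulation_config <- function(n_proteins = 350L, n_functions = 150L,
                              community_count = 10L,
                              ppi_within = 0.15, ppi_between = 0.004,
                              pf_per_protein = 2L, ff_shortcuts = 15L,
                              within_function_bias = 0.8,
                              n_diseases = 60L, n_drugs = 300L,
                              n_food_molecules = 100L,
                              targets_per_entity = 6L,
                              phenotype_targets = 8L,
                              positives_per_disease = 5L,
                              positive_overlap = 0.8,
                              offtarget_pools = 3L,
                              offtarget_pool_size = 12L,
                              offtarget_min = 4L, offtarget_max = 8L,
                              n_modulator_molecules = 15L,
                              n_ingredients = 40L,
                              occurrences_per_ingredient = 20L,
                              n_culinary_clusters = 5L,
                              embedding_dim = 16L, cluster_spread = 0.5,
                              n_enriched_ingredients = 10L,
                              n_recipes = 30L, recipe_size = c(4L, 8L),
                              rng_seed = 1L) {
  cfg <- list(n_proteins = n_proteins, n_functions = n_functions,
              community_count = community_count, ppi_within = ppi_within,
              ppi_between = ppi_between, pf_per_protein = pf_per_protein,
              ff_shortcuts = ff_shortcuts,
              within_function_bias = within_function_bias,
              n_diseases = n_diseases, n_drugs = n_drugs,
              n_food_molecules = n_food_molecules,
              targets_per_entity = targets_per_entity,
              phenotype_targets = phenotype_targets,
              positives_per_disease = positives_per_disease,
              positive_overlap = positive_overlap,
              offtarget_pools = offtarget_pools,
              offtarget_pool_size = offtarget_pool_size,
              offtarget_min = offtarget_min, offtarget_max = offtarget_max,
              n_modulator_molecules = n_modulator_molecules,
              n_ingredients = n_ingredients,
              occurrences_per_ingredient = occurrences_per_ingredient,
              n_culinary_clusters = n_culinary_clusters,
              embedding_dim = embedding_dim,
              cluster_spread = cluster_spread,
              n_enriched_ingredients = n_enriched_ingredients,
              n_recipes = n_recipes, recipe_size = recipe_size,
              rng_seed = rng_seed)
  counts <- cfg[c("n_proteins", "n_functions", "community_count",
                  "n_diseases", "n_drugs", "n_food_molecules",
                  "targets_per_entity", "n_ingredients",
                  "occurrences_per_ingredient", "n_culinary_clusters",
                  "n_recipes")]
  if (any(unlist(counts) <= 0)) stopf("all counts must be positive")
  if (cfg$positive_overlap < 0 || cfg$positive_overlap > 1)
    stopf("positive_overlap must lie in [0, 1]")
  if (cfg$embedding_dim < 2) stopf("embedding_dim must be >= 2")
  structure(cfg, class = "simulation_config")
}

protein_names <- function(cfg) sprintf("p%04d", seq_len(cfg$n_proteins))
function_names <- function(cfg) sprintf("f%04d", seq_len(cfg$n_functions))
molecule_names <- function(cfg)
  sprintf("molecule%03d", seq_len(cfg$n_food_molecules))

#' Generate the synthetic two-layer interactome
#'
#' Protein layer: stochastic-block pattern, dense within communities and
#' sparse across. Function layer: a rooted random recursive tree plus
#' ancestor-to-descendant shortcut edges (a DAG with a single root).
#' Protein-function links prefer functions assigned to the protein's
#' community. Bridge edges are added afterwards if the graph is
#' disconnected, so every node is reachable.
#'
#' @param cfg a `simulation_config`.
#' @return an `interactome_graph` with attributes `protein_communities` and
#'   `function_communities` (named integer vectors).
#' @export
generate_interactome <- function(cfg) {
  with_seed(cfg$rng_seed, {
    prot <- protein_names(cfg)
    fun <- function_names(cfg)
    C <- cfg$community_count
    pcomm <- stats::setNames(rep_len(seq_len(C), cfg$n_proteins), prot)
    # communities for functions; the root (f0001) belongs to none
    fcomm <- stats::setNames(rep_len(seq_len(C), cfg$n_functions), fun)
    fcomm[1] <- NA_integer_
    # protein-protein: Bernoulli per unordered pair
    ut <- which(upper.tri(matrix(0, cfg$n_proteins, cfg$n_proteins)),
                arr.ind = TRUE)
    same <- pcomm[ut[, 1]] == pcomm[ut[, 2]]
    p_edge <- ifelse(same, cfg$ppi_within, cfg$ppi_between)
    hit <- stats::runif(nrow(ut)) < p_edge
    if (!any(hit)) stopf("edge densities produced an empty protein layer")
    ppi <- data.frame(from = prot[ut[hit, 1]], to = prot[ut[hit, 2]],
                      edge_type = "protein-protein",
                      stringsAsFactors = FALSE)
    # function hierarchy: random recursive tree rooted at fun[1]
    if (cfg$n_functions < 2) stopf("function layer needs >= 2 nodes")
    parent <- c(NA_integer_,
                vapply(2:cfg$n_functions, function(i)
                  if (i == 2) 1L else sample.int(i - 1L, 1L), integer(1)))
    ff <- data.frame(from = fun[parent[-1]], to = fun[-1],
                     edge_type = "function-function",
                     stringsAsFactors = FALSE)
    # shortcuts from a strict ancestor to a deeper descendant (keeps the
    # parent->child orientation acyclic with a single root)
    ancestors <- function(i) {
      out <- integer(0)
      while (!is.na(parent[i])) {
        i <- parent[i]
        out <- c(out, i)
      }
      out
    }
    sc <- 0L
    tries <- 0L
    while (sc < cfg$ff_shortcuts && tries < cfg$ff_shortcuts * 20L) {
      tries <- tries + 1L
      d <- sample(2:cfg$n_functions, 1L)
      anc <- setdiff(ancestors(d), parent[d])
      if (length(anc) == 0L) next
      a <- anc[sample.int(length(anc), 1L)]
      ff <- rbind(ff, data.frame(from = fun[a], to = fun[d],
                                 edge_type = "function-function",
                                 stringsAsFactors = FALSE))
      sc <- sc + 1L
    }
    # protein-function links, biased within community
    pf_rows <- lapply(seq_len(cfg$n_proteins), function(i) {
      picks <- vapply(seq_len(cfg$pf_per_protein), function(.) {
        pool <- if (stats::runif(1) < cfg$within_function_bias)
          fun[!is.na(fcomm) & fcomm == pcomm[i]] else fun[-1]
        if (length(pool) == 0L) pool <- fun[-1]
        pool[sample.int(length(pool), 1L)]
      }, character(1))
      data.frame(from = prot[i], to = unique(picks),
                 edge_type = "protein-function", stringsAsFactors = FALSE)
    })
    pf <- do.call(rbind, pf_rows)
    g <- new_interactome(prot, fun, rbind(ppi, pf, ff))
    # connect stray components to the largest one
    ig <- igraph::graph_from_data_frame(g$edges[c("from", "to")],
                                        directed = FALSE,
                                        vertices = g$nodes$node_id)
    comp <- igraph::components(ig)
    if (comp$no > 1L) {
      main <- which.max(comp$csize)
      anchor <- names(comp$membership)[comp$membership == main][1]
      extra <- lapply(setdiff(seq_len(comp$no), main), function(k) {
        v <- names(comp$membership)[comp$membership == k][1]
        et <- if (v %in% prot && anchor %in% prot) "protein-protein"
        else if (v %in% fun && anchor %in% fun) "function-function"
        else "protein-function"
        # protein-function edges must run protein -> function
        if (et == "protein-function" && v %in% fun)
          data.frame(from = anchor, to = v, edge_type = et,
                     stringsAsFactors = FALSE)
        else data.frame(from = v, to = anchor, edge_type = et,
                        stringsAsFactors = FALSE)
      })
      g <- new_interactome(prot, fun,
                           rbind(g$edges, do.call(rbind, extra)))
    }
    attr(g, "protein_communities") <- pcomm
    attr(g, "function_communities") <- fcomm
    g
  })
}

#' Generate the planted drug-disease benchmark and all seed vectors
#'
#' Each disease seeds proteins within one community; each of its positive
#' drugs targets the same community with probability `positive_overlap`
#' (otherwise a uniformly random drug is taken, so `positive_overlap = 0`
#' yields positives indistinguishable from negatives). On top of its
#' community targets, every disease, drug and molecule also seeds a random
#' number of proteins from one of a few shared "frequent-hitter" pools,
#' emulating promiscuous off-target binding and generic stress-response
#' co-dysregulation: this treatment-irrelevant mass confounds raw-profile
#' similarity while remaining learnable nuisance for the metric model. Food
#' molecule seeds are also generated here: the first
#' `n_modulator_molecules` molecules target the phenotype's community
#' (community 1), the rest target other communities.
#'
#' @param graph an interactome from [generate_interactome()] (communities
#'   are read from its attributes).
#' @param cfg the same `simulation_config`.
#' @return list with `benchmark` (an `association_benchmark`), `seeds`
#'   (list: `phenotype`, `diseases`, `drugs`, `molecules` — `seed_vector`s),
#'   `modulator_ids`, `disease_communities`, `drug_communities`.
#' @export
generate_benchmark <- function(graph, cfg) {
  pcomm <- attr(graph, "protein_communities")
  if (is.null(pcomm)) stopf("graph lacks community annotations")
  with_seed(cfg$rng_seed + 1L, {
    C <- cfg$community_count
    by_comm <- split(names(pcomm), pcomm)
    too_small <- vapply(by_comm, length, integer(1)) < cfg$targets_per_entity
    if (any(too_small))
      stopf("targets_per_entity (%d) exceeds the size of community(ies) %s",
            cfg$targets_per_entity,
            paste(names(by_comm)[too_small], collapse = ", "))
    n_sticky <- min(cfg$offtarget_pools * cfg$offtarget_pool_size,
                    length(pcomm))
    sticky_pools <- split(
      sample(names(pcomm), n_sticky),
      rep_len(seq_len(cfg$offtarget_pools), n_sticky))
    sample_targets <- function(comm, n, offtarget = TRUE) {
      base <- sample(by_comm[[as.character(comm)]], n)
      if (!offtarget || cfg$offtarget_max < 1L) return(base)
      pool <- sticky_pools[[sample.int(cfg$offtarget_pools, 1L)]]
      k <- sample(cfg$offtarget_min:cfg$offtarget_max, 1L)
      unique(c(base, sample(pool, min(k, length(pool)))))
    }
    phenotype <- make_seed_vector(
      sample_targets(1L, min(cfg$phenotype_targets, length(by_comm[["1"]])),
                     offtarget = FALSE),
      graph, "phenotype", "phenotype")
    dis_comm <- stats::setNames(rep_len(seq_len(C), cfg$n_diseases),
                                sprintf("disease%03d",
                                        seq_len(cfg$n_diseases)))
    drug_comm <- stats::setNames(rep_len(seq_len(C), cfg$n_drugs),
                                 sprintf("drug%03d", seq_len(cfg$n_drugs)))
    diseases <- lapply(names(dis_comm), function(d)
      make_seed_vector(sample_targets(dis_comm[d], cfg$targets_per_entity),
                       graph, d, "disease"))
    names(diseases) <- names(dis_comm)
    drugs <- lapply(names(drug_comm), function(d)
      make_seed_vector(sample_targets(drug_comm[d], cfg$targets_per_entity),
                       graph, d, "drug"))
    names(drugs) <- names(drug_comm)
    mols <- molecule_names(cfg)
    modulator_ids <- mols[seq_len(min(cfg$n_modulator_molecules,
                                      length(mols)))]
    molecules <- lapply(mols, function(m) {
      comm <- if (m %in% modulator_ids) 1L
      else sample(setdiff(seq_len(C), 1L), 1L)
      make_seed_vector(sample_targets(comm, cfg$targets_per_entity),
                       graph, m, "molecule")
    })
    names(molecules) <- mols
    pairs <- do.call(rbind, lapply(names(dis_comm), function(d) {
      own <- names(drug_comm)[drug_comm == dis_comm[d]]
      picks <- vapply(seq_len(cfg$positives_per_disease), function(.) {
        if (stats::runif(1) < cfg$positive_overlap)
          own[sample.int(length(own), 1L)]
        else names(drug_comm)[sample.int(length(drug_comm), 1L)]
      }, character(1))
      data.frame(disease_id = d, drug_id = unique(picks),
                 stringsAsFactors = FALSE)
    }))
    benchmark <- association_benchmark(pairs, diseases = names(dis_comm),
                                       drugs = names(drug_comm))
    list(benchmark = benchmark,
         seeds = list(phenotype = phenotype, diseases = diseases,
                      drugs = drugs, molecules = molecules),
         modulator_ids = modulator_ids,
         disease_communities = dis_comm, drug_communities = drug_comm,
         offtarget_pools = sticky_pools)
  })
}

#' Generate the synthetic food world
#'
#' Ingredients are grouped into culinary clusters; occurrence embeddings
#' are drawn from per-cluster Gaussian centers (sd 2) with within-cluster
#' spread `cluster_spread`; recipes sample ingredients within one cluster;
#' modulator molecules are planted into a known enriched ingredient subset;
#' allergens are assigned from the 14 canonical labels; the curated
#' direction list marks planted modulators `"positive"`.
#'
#' @param cfg a `simulation_config`.
#' @param modulator_ids planted modulator molecule ids; defaults to the ids
#'   [generate_benchmark()] plants (the first `n_modulator_molecules`
#'   molecule names).
#' @return list with `composition`, `embeddings`
#'   (`occurrence_embeddings`), `recipes` (list of `recipe`),
#'   `allergen_db`, `curated`, `enriched_ingredients`, `clusters` (named
#'   integer vector), `modulator_ids`.
#' @export
generate_food_world <- function(cfg, modulator_ids = NULL) {
  if (cfg$embedding_dim < 2) stopf("embedding_dim must be >= 2")
  mols <- molecule_names(cfg)
  modulator_ids <- modulator_ids %||%
    mols[seq_len(min(cfg$n_modulator_molecules, length(mols)))]
  background <- setdiff(mols, modulator_ids)
  with_seed(cfg$rng_seed + 2L, {
    ings <- sprintf("ingredient_%02d", seq_len(cfg$n_ingredients))
    clusters <- stats::setNames(
      rep_len(seq_len(cfg$n_culinary_clusters), cfg$n_ingredients), ings)
    enriched <- sort(sample(ings, min(cfg$n_enriched_ingredients,
                                      length(ings))))
    comp_rows <- lapply(ings, function(ing) {
      mset <- character(0)
      if (ing %in% enriched)
        mset <- sample(modulator_ids, sample(2:4, 1L))
      mset <- c(mset, sample(background, sample(1:3, 1L)))
      data.frame(ingredient = ing, molecule_id = mset,
                 stringsAsFactors = FALSE)
    })
    composition <- unique(do.call(rbind, comp_rows))
    centers <- matrix(stats::rnorm(cfg$n_culinary_clusters *
                                     cfg$embedding_dim, sd = 2),
                      nrow = cfg$n_culinary_clusters)
    occ_id <- character(0)
    occ_ing <- character(0)
    vecs <- matrix(0, nrow = cfg$n_ingredients *
                     cfg$occurrences_per_ingredient,
                   ncol = cfg$embedding_dim)
    row <- 0L
    for (ing in ings) {
      for (j in seq_len(cfg$occurrences_per_ingredient)) {
        row <- row + 1L
        occ_id[row] <- sprintf("%s_occ%03d", ing, j)
        occ_ing[row] <- ing
        vecs[row, ] <- centers[clusters[ing], ] +
          stats::rnorm(cfg$embedding_dim, sd = cfg$cluster_spread)
      }
    }
    embeddings <- occurrence_embeddings(occ_id, occ_ing, vecs)
    recipes <- lapply(seq_len(cfg$n_recipes), function(k) {
      cl <- sample.int(cfg$n_culinary_clusters, 1L)
      members <- ings[clusters == cl]
      size <- sample(cfg$recipe_size[1]:cfg$recipe_size[2], 1L)
      picked <- sample(members, min(size, length(members)))
      recipe(sprintf("recipe%03d", k), sprintf("Synthetic recipe %d", k),
             picked,
             sprintf("Combine %s and cook.", paste(picked, collapse = ", ")))
    })
    allergic <- sample(ings, max(1L, round(0.3 * length(ings))))
    allergen_db <- do.call(rbind, lapply(allergic, function(ing)
      data.frame(ingredient = ing,
                 allergen = sample(ALLERGENS14, sample(1:2, 1L)),
                 stringsAsFactors = FALSE)))
    seen_background <- intersect(unique(composition$molecule_id), background)
    curated <- rbind(
      data.frame(molecule_id = modulator_ids, direction = "positive",
                 evidence = "planted modulator (synthetic)",
                 stringsAsFactors = FALSE),
      data.frame(molecule_id = seen_background,
                 direction = sample(c("negative", "unknown"),
                                    length(seen_background), replace = TRUE),
                 evidence = "synthetic background molecule",
                 stringsAsFactors = FALSE))
    list(composition = composition, embeddings = embeddings,
         recipes = recipes, allergen_db = allergen_db, curated = curated,
         enriched_ingredients = enriched, clusters = clusters,
         modulator_ids = modulator_ids)
  })
}

#' Write a full simulated input set to disk
#'
#' Emits every file format the other modules read: the three interactome
#' edge TSVs, a seeds TSV (`entity_id`, `kind`, comma-separated targets),
#' the benchmark TSV, recipes JSON, occurrence-embedding TSV, and the
#' composition / curated-direction / allergen CSVs.
#'
#' @param cfg a `simulation_config`.
#' @param dir output directory (created if needed).
#' @return invisibly, the list of generated objects.
#' @export
write_simulation <- function(cfg, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  graph <- generate_interactome(cfg)
  bench <- generate_benchmark(graph, cfg)
  food <- generate_food_world(cfg, bench$modulator_ids)
  write_interactome(graph, dir)
  all_seeds <- c(list(bench$seeds$phenotype), bench$seeds$diseases,
                 bench$seeds$drugs, bench$seeds$molecules)
  seed_df <- do.call(rbind, lapply(all_seeds, function(s)
    data.frame(entity_id = s$entity_id, kind = s$kind,
               targets = paste(names(s$indicator)[s$indicator > 0],
                               collapse = ","),
               stringsAsFactors = FALSE)))
  utils::write.table(seed_df, file.path(dir, "seeds.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_benchmark(bench$benchmark, file.path(dir, "benchmark.tsv"))
  write_recipes_json(food$recipes, file.path(dir, "recipes.json"))
  write_embeddings(food$embeddings, file.path(dir, "embeddings.tsv"))
  utils::write.csv(food$composition, file.path(dir, "composition.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(food$curated, file.path(dir, "curated_directions.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(food$allergen_db, file.path(dir, "allergen_db.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(list(graph = graph, benchmark = bench, food = food))
}

#' Read a seeds TSV written by [write_simulation()]
#'
#' @param path seeds TSV.
#' @param graph the matching `interactome_graph`.
#' @return named list of `seed_vector`s.
#' @export
read_seeds <- function(path, graph) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i)
    make_seed_vector(strsplit(df$targets[i], ",")[[1]], graph,
                     df$entity_id[i], df$kind[i]))
  stats::setNames(out, df$entity_id)
}
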