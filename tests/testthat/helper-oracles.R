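# Independent oracles used across the suite. Each one re-derives the target
# quantity by the most direct means available (dense linear algebra,
# exhaustive enumeration, explicit loops) and stays independent of the code
# paths it checks.

# Dense linear-system oracle for the RWR fixed point:
# s = r p + (1 - r) W s  =>  (I - (1 - r) W) s = r p
oracle_diffusion_exact <- function(p_hat, W, r) {
  n <- length(p_hat)
  A <- diag(n) - (1 - r) * as.matrix(W)
  as.numeric(solve(A, r * p_hat))
}

# Exhaustive concordant-pair AUROC with ties counted one half.
oracle_auroc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (if (p > q) 1 else if (p == q) 0.5 else 0)
  total / (length(pos) * length(neg))
}

# Exhaustive pair-counting AUROC via outer comparison (same convention as
# oracle_auroc_pairs, vectorized for larger inputs).
oracle_auroc_outer <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
    (length(pos) * length(neg))
}

# Brute-force all-pairs substitution tally: per-occurrence loop with direct
# per-pair Euclidean distances, the same (distance, index) tie order.
oracle_substitution_table <- function(emb, k, min_score, max_ratio) {
  X <- emb$vectors
  ids <- emb$ids$canonical_id
  n <- nrow(X)
  tally <- list()
  Xt <- t(X)
  for (i in seq_len(n)) {
    d <- sqrt(colSums((Xt - X[i, ])^2))
    d[ids == ids[i]] <- Inf
    ord <- order(d, seq_len(n))
    ord <- ord[is.finite(d[ord])]
    nn <- ord[seq_len(min(k, length(ord)))]
    key <- ids[i]
    cur <- tally[[key]]
    if (is.null(cur)) cur <- integer(0)
    for (cand in ids[nn]) {
      if (is.null(cur[cand]) || is.na(cur[cand])) cur[cand] <- 0L
      cur[cand] <- cur[cand] + 1L
    }
    tally[[key]] <- cur
  }
  out <- lapply(sort(unique(ids)), function(key) {
    sc <- tally[[key]]
    if (is.null(sc) || length(sc) == 0L)
      return(data.frame(candidate_id = character(0), score = integer(0),
                        stringsAsFactors = FALSE))
    keep <- sc > min_score & sc > max_ratio * max(sc)
    sc <- sc[keep]
    df <- data.frame(candidate_id = names(sc), score = as.integer(sc),
                     stringsAsFactors = FALSE)
    df <- df[order(-df$score, df$candidate_id), , drop = FALSE]
    rownames(df) <- NULL
    df
  })
  names(out) <- sort(unique(ids))
  out
}

# Union-find closure oracle for the lexicon component structure.
oracle_components <- function(n, pairs) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (length(pairs) > 0) for (r in seq_len(nrow(pairs))) {
    a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(n), find, integer(1))
}

# Small test interactomes written as TSV triples and loaded through the
# package reader, so fixtures exercise the documented input path.
write_graph_fixture <- function(ppi, pf = character(0), ff = character(0)) {
  dir <- tempfile("graph")
  dir.create(dir)
  writeLines(ppi, file.path(dir, "ppi.tsv"))
  writeLines(pf, file.path(dir, "pf.tsv"))
  writeLines(ff, file.path(dir, "ff.tsv"))
  load_interactome(file.path(dir, "ppi.tsv"), file.path(dir, "pf.tsv"),
                   file.path(dir, "ff.tsv"))
}

# The 3-node path a-b-c used repeatedly for closed-form checks.
path3_graph <- function() write_graph_fixture(c("a\tb", "b\tc"))

# Random small interactome via the seeded generator, sized for oracles.
random_small_graph <- function(seed) {
  cfg <- simulation_config(
    n_proteins = 20L + (seed %% 7L) * 20L,
    n_functions = 10L + (seed %% 5L) * 10L,
    community_count = 2L + (seed %% 3L),
    rng_seed = seed)
  generate_interactome(cfg)
}

random_seed_on <- function(graph, seed, n_targets = 3L) {
  prot <- node_ids(graph, "protein")
  with_seed(seed, make_seed_vector(sample(prot, n_targets), graph,
                                   sprintf("s%d", seed), "disease"))
}

with_seed <- nutriwalk:::with_seed
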