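#' @title Network propagation by biased random walks with restarts
#'
#' @description
#' A walker starts on the (uniformly normalized) seed distribution and at
#' every step either restarts with probability `r` or jumps to a neighbour
#' according to the transition matrix. The stationary visit-frequency vector
#' — the diffusion profile — solves the fixed point
#' `s = r * p_hat + (1 - r) * W %*% s` and encodes the seeded entity's
#' influence on every protein and biological function in the interactome.
#'
#' @name propagation
NULL

# Pad an N-length protein indicator to the full N+M node ordering and
# normalize to sum 1 (uniform over seed nodes).
seed_distribution <- function(seed, node_names) {
  p <- stats::setNames(numeric(length(node_names)), node_names)
  nz <- names(seed$indicator)[seed$indicator > 0]
  if (length(nz) == 0L) stopf("seed '%s' has no nonzero entry", seed$entity_id)
  missing <- setdiff(nz, node_names)
  if (length(missing) > 0L)
    stopf("seed '%s' references unknown node(s): %s", seed$entity_id,
          paste(missing, collapse = ", "))
  p[nz] <- 1 / length(nz)
  p
}

#' Diffusion profile of a single seed set
#'
#' Power iteration `s <- r * p_hat + (1 - r) * W %*% s` starting from the
#' normalized seed distribution, stopped when the L1 change drops below
#' `tol` or after `max_iter` sweeps. Non-convergence is flagged on the
#' result (with a warning), not raised as an error.
#'
#' @param seed a `seed_vector`.
#' @param W column-stochastic transition matrix from
#'   [build_transition_matrix()].
#' @param restart_prob restart probability `r` in (0, 1]; default 0.64.
#' @param tol L1 convergence tolerance on successive iterates.
#' @param max_iter maximum number of power-iteration sweeps.
#' @return a `diffusion_profile`: list with `entity_id`, `values` (named,
#'   non-negative, summing to 1), `restart_prob`, `iterations`, `residual`
#'   and `converged`.
#' @export
diffusion_profile <- function(seed, W, restart_prob = 0.64, tol = 1e-10,
                              max_iter = 10000L) {
  if (!(restart_prob > 0 && restart_prob <= 1))
    stopf("restart_prob must be in (0, 1], got %g", restart_prob)
  node_names <- colnames(W)
  p <- seed_distribution(seed, node_names)
  s <- p
  r <- restart_prob
  res <- Inf
  it <- 0L
  while (it < max_iter) {
    s_new <- r * p + (1 - r) * as.numeric(W %*% s)
    res <- sum(abs(s_new - s))
    s <- s_new
    it <- it + 1L
    if (res < tol) break
  }
  converged <- res < tol
  if (!converged)
    warnf("diffusion profile for '%s' did not converge in %d iterations (L1 residual %.3g)",
          seed$entity_id, max_iter, res)
  structure(list(entity_id = seed$entity_id,
                 values = stats::setNames(s, node_names),
                 restart_prob = r, iterations = it, residual = res,
                 converged = converged),
            class = "diffusion_profile")
}

#' @export
print.diffusion_profile <- function(x, ...) {
  cat(sprintf(
    "diffusion_profile '%s': %d nodes, r = %.3g, %d iterations%s\n",
    x$entity_id, length(x$values), x$restart_prob, x$iterations,
    if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Propagate a batch of seed sets simultaneously
#'
#' All seed distributions are stacked into one matrix and iterated together
#' (one sparse matrix product per sweep); each column is checked for
#' convergence independently.
#'
#' @param seeds list of `seed_vector`s.
#' @param W transition matrix.
#' @param restart_prob restart probability.
#' @param tol per-entity L1 tolerance.
#' @param max_iter maximum sweeps.
#' @param verbose log progress every `log_every` entities during setup.
#' @param log_every integer.
#' @return numeric matrix, one row per entity (rownames = entity ids,
#'   colnames = node ids), rows in input order, each row a diffusion profile.
#' @export
propagate_batch <- function(seeds, W, restart_prob = 0.64, tol = 1e-10,
                            max_iter = 10000L, verbose = FALSE,
                            log_every = 50L) {
  node_names <- colnames(W)
  n <- length(node_names)
  if (length(seeds) == 0L)
    return(matrix(numeric(0), nrow = 0, ncol = n,
                  dimnames = list(NULL, node_names)))
  ids <- vapply(seeds, function(s) s$entity_id, character(1))
  P <- matrix(0, nrow = n, ncol = length(seeds),
              dimnames = list(node_names, ids))
  for (k in seq_along(seeds)) {
    P[, k] <- seed_distribution(seeds[[k]], node_names)
    if (verbose && k %% log_every == 0L)
      message(sprintf("prepared %d / %d seed distributions", k, length(seeds)))
  }
  r <- restart_prob
  S <- P
  active <- rep(TRUE, ncol(P))
  for (it in seq_len(max_iter)) {
    S_new <- r * P + (1 - r) * as.matrix(W %*% S)
    delta <- colSums(abs(S_new - S))
    S <- S_new
    active <- delta >= tol
    if (!any(active)) break
  }
  if (any(active))
    warnf("%d of %d profiles did not converge in %d iterations",
          sum(active), ncol(P), max_iter)
  t(S)
}

#' Write / read a profile matrix as TSV
#'
#' One row per entity: the entity id followed by one numeric column per
#' node, with a header row carrying the node ordering.
#'
#' @param profiles matrix from [propagate_batch()].
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_profiles <- function(profiles, path) {
  df <- data.frame(entity_id = rownames(profiles), profiles,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
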