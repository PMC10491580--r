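#' @title Multiscale interactome graph
#'
#' @description
#' The interactome is a heterogeneous, undirected graph whose nodes are
#' proteins and biological functions, connected by three edge classes:
#' protein-protein (physical interaction), protein-function (a protein
#' affecting a biological function), and function-function (the hierarchy of
#' biological-function terms). All downstream propagation treats the graph
#' as undirected with unit edge weights unless per-edge-type weights are
#' supplied.
#'
#' Nodes are kept in a fixed, documented ordering: all protein identifiers
#' sorted lexicographically, followed by all function identifiers sorted
#' lexicographically. Seed vectors index the protein block of this ordering;
#' transition matrices and diffusion profiles use the full ordering. The
#' ordering is exposed via `node_ids()` and is stable across load, matrix
#' construction and propagation.
#'
#' @name interactome
NULL

EDGE_TYPES <- c("protein-protein", "protein-function", "function-function")

new_interactome <- function(proteins, functions, edges) {
  proteins <- sort(unique(as.character(proteins)))
  functions <- sort(unique(as.character(functions)))
  both <- intersect(proteins, functions)
  if (length(both) > 0L)
    stopf("node(s) typed as both protein and biological function: %s",
          paste(both, collapse = ", "))
  nodes <- data.frame(
    node_id = c(proteins, functions),
    node_type = rep(c("protein", "biological_function"),
                    c(length(proteins), length(functions))),
    stringsAsFactors = FALSE
  )
  edges <- canonicalize_edges(edges)
  known <- nodes$node_id
  missing <- setdiff(unique(c(edges$from, edges$to)), known)
  if (length(missing) > 0L)
    stopf("edge endpoint(s) not in node table: %s",
          paste(missing, collapse = ", "))
  g <- structure(
    list(nodes = nodes, edges = edges,
         n_proteins = length(proteins), n_functions = length(functions),
         node_index = stats::setNames(seq_len(nrow(nodes)), nodes$node_id)),
    class = "interactome_graph"
  )
  g
}

# Undirected canonical form: endpoints ordered lexicographically within each
# edge, self-loops dropped, duplicates collapsed (weights are NOT summed:
# every edge carries unit weight by default), rows sorted.
canonicalize_edges <- function(edges) {
  stopifnot(all(c("from", "to", "edge_type") %in% names(edges)))
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  swap <- edges$from > edges$to
  tmp <- edges$from[swap]
  edges$from[swap] <- edges$to[swap]
  edges$to[swap] <- tmp
  edges <- edges[!duplicated(edges[c("from", "to", "edge_type")]), ,
                 drop = FALSE]
  edges <- edges[order(edges$edge_type, edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' @export
print.interactome_graph <- function(x, ...) {
  cat(sprintf(
    "interactome_graph: %d nodes (%d proteins, %d functions), %d edges\n",
    nrow(x$nodes), x$n_proteins, x$n_functions, nrow(x$edges)))
  tab <- table(x$edges$edge_type)
  for (nm in names(tab)) cat(sprintf("  %s: %d\n", nm, tab[[nm]]))
  invisible(x)
}

#' Node identifiers in the canonical ordering
#'
#' @param graph an `interactome_graph`.
#' @param type `"all"`, `"protein"` or `"biological_function"`.
#' @return character vector of node ids.
#' @export
node_ids <- function(graph, type = c("all", "protein", "biological_function")) {
  type <- match.arg(type)
  if (type == "all") return(graph$nodes$node_id)
  graph$nodes$node_id[graph$nodes$node_type == type]
}

# Header detection: a first row whose fields look like column labels rather
# than identifiers. Matching is case-insensitive on a fixed vocabulary.
HEADERISH <- c("source", "target", "from", "to", "node1", "node2", "protein",
               "protein1", "protein2", "function", "function1", "function2",
               "parent", "child", "gene", "id", "id1", "id2", "node_1",
               "node_2", "term", "go_term")

read_edge_tsv <- function(path) {
  if (!file.exists(path)) stopf("input file does not exist: %s", path)
  if (length(readLines(path, n = 1L)) == 0L)
    return(data.frame(from = character(0), to = character(0),
                      stringsAsFactors = FALSE))
  raw <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  if (ncol(raw) < 2L) stopf("expected >= 2 tab-separated columns in %s", path)
  raw <- raw[, 1:2, drop = FALSE]
  if (nrow(raw) > 0L &&
      all(tolower(trimws(unlist(raw[1, ]))) %in% HEADERISH)) {
    raw <- raw[-1, , drop = FALSE]
  }
  raw[[1]] <- trimws(raw[[1]])
  raw[[2]] <- trimws(raw[[2]])
  bad <- raw[[1]] == "" | raw[[2]] == ""
  if (any(bad)) stopf("empty identifier(s) in %s (row %d)", path,
                      which(bad)[1])
  names(raw) <- c("from", "to")
  raw
}

#' Load a multiscale interactome from three typed edge lists
#'
#' Reads protein-protein, protein-function and function-function edge files
#' (two tab-separated identifier columns each; extra columns ignored; an
#' optional header row is auto-detected). Node types are inferred from which
#' file introduced each node: endpoints of the PPI file and the first column
#' of the protein-function file are proteins; the second column of the
#' protein-function file and both columns of the hierarchy file are
#' biological functions. Duplicate edges are collapsed and self-loops
#' dropped.
#'
#' @param ppi_path TSV of protein-protein edges.
#' @param protein_function_path TSV of protein-function edges
#'   (protein in column 1, function in column 2).
#' @param function_hierarchy_path TSV of function-function hierarchy edges.
#' @return an `interactome_graph`.
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' writeLines(c("P1\tP2", "P2\tP3"), file.path(dir, "ppi.tsv"))
#' writeLines("P1\tF1", file.path(dir, "pf.tsv"))
#' writeLines("F1\tF2", file.path(dir, "ff.tsv"))
#' g <- load_interactome(file.path(dir, "ppi.tsv"), file.path(dir, "pf.tsv"),
#'                       file.path(dir, "ff.tsv"))
#' @export
load_interactome <- function(ppi_path, protein_function_path,
                             function_hierarchy_path) {
  ppi <- read_edge_tsv(ppi_path)
  pf <- read_edge_tsv(protein_function_path)
  ff <- read_edge_tsv(function_hierarchy_path)
  proteins <- unique(c(ppi$from, ppi$to, pf$from))
  functions <- unique(c(pf$to, ff$from, ff$to))
  typed <- function(df, type)
    if (nrow(df) > 0L) data.frame(df, edge_type = type,
                                  stringsAsFactors = FALSE)
  edges <- rbind(typed(ppi, "protein-protein"),
                 typed(pf, "protein-function"),
                 typed(ff, "function-function"))
  if (is.null(edges))
    edges <- data.frame(from = character(0), to = character(0),
                        edge_type = character(0), stringsAsFactors = FALSE)
  new_interactome(proteins, functions, edges)
}

#' Write an interactome back to its three canonical edge files
#'
#' Edges are written sorted lexicographically with a header row, one file
#' per edge class, so that `load_interactome()` on the output reproduces the
#' canonicalized edge set exactly.
#'
#' @param graph an `interactome_graph`.
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
write_interactome <- function(graph, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c("protein-protein" = file.path(dir, "ppi.tsv"),
             "protein-function" = file.path(dir, "protein_function.tsv"),
             "function-function" = file.path(dir, "function_hierarchy.tsv"))
  headers <- c("protein1\tprotein2", "protein\tfunction", "parent\tchild")
  is_protein <- stats::setNames(graph$nodes$node_type == "protein",
                                graph$nodes$node_id)
  for (i in seq_along(files)) {
    sub <- graph$edges[graph$edges$edge_type == names(files)[i], ,
                       drop = FALSE]
    if (names(files)[i] == "protein-function" && nrow(sub) > 0L) {
      # canonical edge order is lexicographic; the file contract wants the
      # protein endpoint in column 1
      swap <- !is_protein[sub$from]
      tmp <- sub$from[swap]
      sub$from[swap] <- sub$to[swap]
      sub$to[swap] <- tmp
    }
    lines <- c(headers[i], paste(sub$from, sub$to, sep = "\t"))
    writeLines(lines, files[[i]])
  }
  invisible(files)
}

#' Build the column-stochastic transition matrix of the random walker
#'
#' Column `j` holds the walker's jump distribution out of node `j`:
#' weight-proportional probabilities over the neighbours of `j`, with a
#' default weight of 1 for every edge type. Dangling nodes (degree zero)
#' receive a uniform column so the matrix stays stochastic without deleting
#' nodes that seed vectors may reference.
#'
#' @param graph an `interactome_graph`.
#' @param edge_weights optional named numeric vector of per-edge-type
#'   weights, names among `"protein-protein"`, `"protein-function"`,
#'   `"function-function"`; missing types default to 1.
#' @return a sparse `dgCMatrix` over all N+M nodes, columns summing to 1,
#'   with node ids as dimnames in the canonical ordering.
#' @export
build_transition_matrix <- function(graph, edge_weights = NULL) {
  w <- stats::setNames(rep(1, length(EDGE_TYPES)), EDGE_TYPES)
  if (!is.null(edge_weights)) {
    if (any(edge_weights < 0)) stopf("edge weights must be non-negative")
    unknown <- setdiff(names(edge_weights), EDGE_TYPES)
    if (length(unknown) > 0L)
      stopf("unknown edge type(s): %s", paste(unknown, collapse = ", "))
    w[names(edge_weights)] <- edge_weights
  }
  n <- nrow(graph$nodes)
  idx <- graph$node_index
  i <- idx[graph$edges$from]
  j <- idx[graph$edges$to]
  ew <- w[graph$edges$edge_type]
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(ew, ew),
                            dims = c(n, n),
                            dimnames = list(graph$nodes$node_id,
                                            graph$nodes$node_id))
  colsum <- Matrix::colSums(A)
  dangling <- which(colsum == 0)
  nz <- colsum
  nz[dangling] <- 1
  W <- A %*% Matrix::Diagonal(n, 1 / nz)
  if (length(dangling) > 0L) {
    U <- Matrix::sparseMatrix(
      i = rep(seq_len(n), length(dangling)),
      j = rep(dangling, each = n),
      x = 1 / n, dims = c(n, n))
    W <- W + U
  }
  dimnames(W) <- list(graph$nodes$node_id, graph$nodes$node_id)
  methods::as(W, "CsparseMatrix")
}

#' Build a binary seed vector over the protein nodes
#'
#' Marks each mappable gene/protein identifier with a 1 in the protein block
#' of the canonical node ordering. Identifier matching is exact-string and
#' case-preserving; unmapped identifiers are counted, not silently dropped.
#'
#' @param gene_ids non-empty character vector of protein identifiers.
#' @param graph an `interactome_graph`.
#' @param entity_id label for the seeded entity.
#' @param kind one of `"phenotype"`, `"molecule"`, `"drug"`, `"disease"`.
#' @return a `seed_vector`: list with `entity_id`, `kind`, `indicator`
#'   (named 0/1 vector of length N over proteins) and `n_unmapped`.
#' @export
make_seed_vector <- function(gene_ids, graph, entity_id = "seed",
                             kind = c("phenotype", "molecule", "drug",
                                      "disease")) {
  kind <- match.arg(kind)
  if (length(gene_ids) == 0L) stopf("gene_ids must be non-empty")
  prot <- node_ids(graph, "protein")
  indicator <- stats::setNames(numeric(length(prot)), prot)
  hit <- intersect(unique(gene_ids), prot)
  if (length(hit) == 0L)
    stopf("none of the %d identifier(s) map to protein nodes (entity '%s')",
          length(unique(gene_ids)), entity_id)
  indicator[hit] <- 1
  structure(list(entity_id = entity_id, kind = kind, indicator = indicator,
                 n_unmapped = length(unique(gene_ids)) - length(hit)),
            class = "seed_vector")
}

#' @export
print.seed_vector <- function(x, ...) {
  cat(sprintf("seed_vector '%s' (%s): %d seed protein(s), %d unmapped\n",
              x$entity_id, x$kind, sum(x$indicator), x$n_unmapped))
  invisible(x)
}
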