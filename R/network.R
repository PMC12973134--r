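#' Spearman co-regulation network
#'
#' Vertices are features; an edge joins features i and j when their Spearman
#' correlation across samples reaches `rho_min` (closed bound), weighted by
#' the correlation. Constant features are excluded with a warning; vertices
#' left without edges are removed.
#'
#' @param X [expression_matrix()] or matrix, features x samples (>= 3).
#' @param features features to include (default: all rows of `X`).
#' @param rho_min edge threshold; required, no silent default by design.
#' @return An `igraph` graph with edge attribute `weight` and graph
#'   attributes `threshold`, `kind = "correlation"`.
#' @export
correlation_network <- function(X, features = NULL, rho_min) {
  if (missing(rho_min)) stop("rho_min must be given explicitly")
  values <- as_values(X)
  if (ncol(values) < 3) stop("need >= 3 samples")
  if (!is.null(features)) {
    miss <- setdiff(features, rownames(values))
    if (length(miss)) stop("features not in X: ", paste(head(miss, 5), collapse = ", "))
    values <- values[features, , drop = FALSE]
  }
  const <- apply(values, 1, stats::sd) == 0
  if (any(const)) {
    warning(sum(const), " constant feature(s) excluded (correlation undefined)")
    values <- values[!const, , drop = FALSE]
  }
  rho <- stats::cor(t(values), method = "spearman")
  adj <- rho * (rho >= rho_min)
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE)
  g <- igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
  g <- igraph::set_graph_attr(g, "threshold", rho_min)
  igraph::set_graph_attr(g, "kind", "correlation")
}

#' Jaccard similarity network of gene signatures
#'
#' Vertices are gene sets; edges join sets with Jaccard index
#' `|A ∩ B| / |A ∪ B| >= j_min` (closed bound), weighted by the index.
#'
#' @param sets named list of character vectors.
#' @param j_min edge threshold.
#' @return An `igraph` graph with `weight` edge attributes.
#' @export
jaccard_network <- function(sets, j_min = 0.3) {
  stopifnot(is.list(sets), all(lengths(sets) > 0))
  nm <- names(sets)
  k <- length(sets)
  J <- matrix(0, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j <= i) next
    J[i, j] <- J[j, i] <-
      length(intersect(sets[[i]], sets[[j]])) /
      length(union(sets[[i]], sets[[j]]))
  }
  adj <- J * (J >= j_min)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE)
  g <- igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
  g <- igraph::set_graph_attr(g, "threshold", j_min)
  igraph::set_graph_attr(g, "kind", "jaccard")
}

#' Leiden community detection on a weighted network
#'
#' Weighted-modularity Leiden partition; deterministic for a fixed seed.
#'
#' @param graph an `igraph` graph with edge weights.
#' @param resolution resolution parameter of the modularity objective.
#' @param seed integer seed.
#' @param n_iterations Leiden refinement iterations.
#' @return List: `membership` (named by vertex), `modularity`, `sizes`.
#' @export
leiden_communities <- function(graph, resolution = 1.0, seed = 1L,
                               n_iterations = 5) {
  if (igraph::ecount(graph) == 0) stop("graph has no edges after filtering")
  set.seed(stage_seed(seed, "leiden"))
  comm <- igraph::cluster_leiden(graph, objective_function = "modularity",
                                 resolution = resolution,
                                 weights = igraph::E(graph)$weight,
                                 n_iterations = n_iterations)
  membership <- igraph::membership(comm)
  names(membership) <- igraph::V(graph)$name
  list(membership = membership,
       modularity = igraph::modularity(graph, membership,
                                       weights = igraph::E(graph)$weight),
       sizes = table(membership))
}

#' Write a network as GraphML
#'
#' @param graph an `igraph` graph.
#' @param path output path.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}
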