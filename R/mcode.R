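#' K-core decomposition by iterative peeling
#'
#' The core number of a vertex is the largest k such that the vertex
#' belongs to a subgraph in which every vertex has degree >= k. Computed by
#' repeatedly peeling minimum-degree vertices; the maximum core number is
#' the graph degeneracy.
#'
#' @param graph An igraph object or `coex_network` (simple, undirected).
#' @return Named integer vector of core numbers (empty graph gives an empty
#'   vector).
#' @export
k_core_decomposition <- function(graph) {
  g <- as_coex_graph(graph)
  n <- igraph::vcount(g)
  out <- stats::setNames(integer(n), igraph::V(g)$name)
  if (n == 0) return(out)
  adj <- igraph::as_adj_list(g)
  deg <- as.integer(igraph::degree(g))
  alive <- rep(TRUE, n)
  k <- 0L
  while (any(alive)) {
    k <- max(k, min(deg[alive]))
    repeat {
      peel <- which(alive & deg <= k)
      if (length(peel) == 0) break
      out[peel] <- k
      alive[peel] <- FALSE
      for (v in peel) {
        nb <- as.integer(adj[[v]])
        nb <- nb[alive[nb]]
        deg[nb] <- deg[nb] - 1L
      }
    }
  }
  out
}

# Highest k-core of a graph: induced subgraph on vertices with maximal core
# number, plus that k. Edgeless graphs give k = 0.
highest_k_core <- function(g) {
  core <- k_core_decomposition(g)
  if (length(core) == 0 || max(core) == 0)
    return(list(k = 0L, graph = NULL))
  k <- max(core)
  list(k = k, graph = igraph::induced_subgraph(g, names(core)[core == k]))
}

graph_density <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2) return(0)
  2 * igraph::ecount(g) / (n * (n - 1))
}

#' MCODE vertex weights
#'
#' For each vertex v, form the closed neighborhood (v plus its neighbors),
#' extract its highest k-core, and set
#' `weight(v) = k_max * density(core)` with `density = 2E / (N (N - 1))`.
#' Isolated vertices get weight 0.
#'
#' @param graph An igraph object or `coex_network`.
#' @return Named numeric vector of weights.
#' @export
mcode_vertex_weights <- function(graph) {
  g <- as_coex_graph(graph)
  vs <- igraph::V(g)$name
  w <- stats::setNames(numeric(length(vs)), vs)
  adj <- igraph::as_adj_list(g)
  for (i in seq_along(vs)) {
    nb <- as.integer(adj[[i]])
    if (length(nb) == 0) next
    sub <- igraph::induced_subgraph(g, c(i, nb))
    hk <- highest_k_core(sub)
    if (hk$k == 0) next
    w[i] <- hk$k * graph_density(hk$graph)
  }
  w
}

#' Detect dense complexes with the MCODE procedure
#'
#' Greedy seeded expansion: vertices are weighted with
#' [mcode_vertex_weights()]; starting from the highest-weight unvisited
#' vertex, neighbors whose weight exceeds `seed_weight * (1 - vwp)` are
#' recursively included (bounded by `max_depth`), each vertex joining at
#' most one complex. The haircut option then reduces each complex to its
#' 2-core (the fixed point of removing singly-connected vertices), and
#' complexes whose induced subgraph contains no `min_core`-core are
#' discarded. Complexes are scored `density * n_nodes` and returned in
#' decreasing score; all ties (seed choice and ordering) break by gene id,
#' so the result is invariant to input edge order.
#'
#' @param graph An igraph object or `coex_network`.
#' @param vwp Vertex weight percentage in \[0, 1) (default 0.2).
#' @param haircut Reduce complexes to their 2-core (default TRUE).
#' @param min_core Discard complexes without a k-core of this order
#'   (default 2).
#' @param max_depth Maximum expansion distance from the seed (default 100).
#' @return List of `gene_module` objects (see [module_stats()]), ordered by
#'   decreasing score.
#' @export
mcode_complexes <- function(graph, vwp = 0.2, haircut = TRUE,
                            min_core = 2, max_depth = 100) {
  g <- as_coex_graph(graph)
  parent <- g
  n <- igraph::vcount(g)
  if (n == 0 || igraph::ecount(g) == 0) return(list())
  w <- mcode_vertex_weights(g)
  vs <- igraph::V(g)$name
  adj <- igraph::as_adj_list(g)
  order_idx <- order(-w, vs)
  visited <- rep(FALSE, n)
  complexes <- list()

  for (seed in order_idx) {
    if (visited[seed] || w[seed] <= 0) next
    threshold <- w[seed] * (1 - vwp)
    members <- seed
    visited[seed] <- TRUE
    frontier <- seed
    depth <- 0
    while (length(frontier) > 0 && depth < max_depth) {
      nxt <- integer(0)
      for (v in frontier) {
        nb <- as.integer(adj[[v]])
        take <- nb[!visited[nb] & w[nb] > threshold]
        if (length(take) > 0) {
          visited[take] <- TRUE
          members <- c(members, take)
          nxt <- c(nxt, take)
        }
      }
      frontier <- nxt
      depth <- depth + 1
    }
    if (length(members) < 2) next
    sub_names <- sort(vs[members])
    sub <- igraph::induced_subgraph(g, sub_names)
    if (haircut) {
      core <- k_core_decomposition(sub)
      keep <- names(core)[core >= 2]
      if (length(keep) < 2) next
      sub <- igraph::induced_subgraph(sub, keep)
      sub_names <- sort(keep)
    }
    if (max(k_core_decomposition(sub)) < min_core) next
    complexes[[length(complexes) + 1]] <-
      new_gene_module(sub_names, seed = vs[seed], parent = parent)
  }

  scores <- vapply(complexes, `[[`, numeric(1), "score")
  seeds <- vapply(complexes, `[[`, character(1), "seed")
  complexes[order(-scores, seeds)]
}

new_gene_module <- function(members, seed, parent) {
  stats <- module_stats(members, parent)
  structure(c(list(members = members, seed = seed,
                   score = stats$density * stats$n_nodes),
              stats),
            class = "gene_module")
}

#' Topology statistics of a gene module
#'
#' Statistics are computed on the subgraph the members induce in the parent
#' network: `avg_connectivity` is the mean within-module degree and
#' `clustering_coefficient` the mean local clustering coefficient over
#' members with within-module degree >= 2 (NA if there is none).
#'
#' @param members Character vector of gene ids.
#' @param graph The parent network (igraph or `coex_network`).
#' @return List with `n_nodes`, `n_edges`, `density`, `avg_connectivity`,
#'   `clustering_coefficient`, `connected`.
#' @export
module_stats <- function(members, graph) {
  g <- as_coex_graph(graph)
  sub <- igraph::induced_subgraph(g, members)
  deg <- igraph::degree(sub)
  local_cc <- igraph::transitivity(sub, type = "local", isolates = "zero")
  list(n_nodes = igraph::vcount(sub),
       n_edges = igraph::ecount(sub),
       density = graph_density(sub),
       avg_connectivity = if (length(deg)) mean(deg) else 0,
       clustering_coefficient =
         if (any(deg >= 2)) mean(local_cc[deg >= 2]) else NA_real_,
       connected = igraph::is_connected(sub))
}

#' @export
print.gene_module <- function(x, ...) {
  cat("<gene_module>", x$n_nodes, "genes, seed", x$seed,
      sprintf("(score %.3f, avg connectivity %.2f, CC %.2f)\n",
              x$score, x$avg_connectivity, x$clustering_coefficient))
  invisible(x)
}

#' Filter modules on size, connectivity and clustering
#'
#' Keeps modules with at least `min_nodes` genes, mean within-module
#' degree >= `min_avg_connectivity` and clustering coefficient >= `min_cc`.
#' A module with an undefined clustering coefficient fails the clustering
#' gate.
#'
#' @param modules List of `gene_module` objects.
#' @param min_nodes,min_avg_connectivity,min_cc Thresholds (defaults 10,
#'   10, 0.5).
#' @return The surviving modules, order preserved.
#' @export
filter_modules <- function(modules, min_nodes = 10,
                           min_avg_connectivity = 10, min_cc = 0.5) {
  keep <- vapply(modules, function(m) {
    m$n_nodes >= min_nodes &&
      m$avg_connectivity >= min_avg_connectivity &&
      !is.na(m$clustering_coefficient) &&
      m$clustering_coefficient >= min_cc
  }, logical(1))
  modules[keep]
}

#' Tabulate a module list
#'
#' @param modules List of `gene_module` objects.
#' @return Tibble with one row per module membership: `module_id`, `gene`,
#'   `seed_flag`.
#' @export
module_membership <- function(modules) {
  if (length(modules) == 0)
    return(tibble::tibble(module_id = character(), gene = character(),
                          seed_flag = logical()))
  purrr::imap_dfr(modules, function(m, i) {
    tibble::tibble(module_id = sprintf("M%d", i), gene = m$members,
                   seed_flag = m$members == m$seed)
  })
}

#' @export
tidy.gene_module <- function(x, ...) {
  tibble::tibble(gene = x$members, seed_flag = x$members == x$seed)
}

#' @export
glance.gene_module <- function(x, ...) {
  tibble::tibble(seed = x$seed, score = x$score, n_nodes = x$n_nodes,
                 n_edges = x$n_edges,
                 avg_connectivity = x$avg_connectivity,
                 clustering_coefficient = x$clustering_coefficient)
}
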