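# Independent oracles and small fixture builders used across the suite.

# Random Erdos-Renyi graph with named vertices, optionally with a clique
# planted on the first `clique` vertices.
random_graph <- function(n, p, clique = 0) {
  m <- matrix(stats::runif(n * n) < p, n, n)
  m[lower.tri(m, diag = TRUE)] <- FALSE
  g <- igraph::graph_from_adjacency_matrix(m | t(m), mode = "undirected")
  igraph::V(g)$name <- sprintf("v%03d", seq_len(n))
  if (clique >= 2) {
    g <- igraph::add_edges(g, as.vector(utils::combn(seq_len(clique), 2)))
    g <- igraph::simplify(g)
  }
  g
}

# Exact densest subgraph (maximum E/V) via Goldberg's max-flow construction:
# binary search on the density guess; the source-side of the min cut at the
# final lower bound is the optimal vertex set. Independent of the MCODE path.
densest_subgraph_oracle <- function(g) {
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  if (m == 0) return(character(0))
  deg <- igraph::degree(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  lo <- 0; hi <- m
  best <- igraph::V(g)$name
  while (hi - lo >= 1 / (n * (n + 1))) {
    mid <- (lo + hi) / 2
    from <- c(rep(n + 1, n), seq_len(n), el[, 1], el[, 2])
    to <- c(seq_len(n), rep(n + 2, n), el[, 2], el[, 1])
    cap <- c(rep(m, n), m + 2 * mid - deg, rep(1, 2 * m))
    fg <- igraph::graph_from_edgelist(cbind(from, to), directed = TRUE)
    mf <- igraph::max_flow(fg, source = n + 1, target = n + 2, capacity = cap)
    s_side <- setdiff(as.integer(mf$partition1), n + 1)
    s_side <- s_side[s_side <= n]
    if (length(s_side) > 0) {
      lo <- mid
      best <- igraph::V(g)$name[s_side]
    } else hi <- mid
  }
  best
}

# Permutation p-value for a Pearson correlation (two-sided).
perm_cor_p <- function(x, y, B = 20000) {
  r_obs <- abs(stats::cor(x, y))
  hits <- sum(replicate(B, abs(stats::cor(x, sample(y))) >= r_obs - 1e-12))
  (hits + 1) / (B + 1)
}

# Data with EXACT sample correlation r between all pairs: shared orthonormal
# factor plus per-gene orthonormal noise, all orthogonal to the intercept.
exact_cs_data <- function(n_genes, n_samples, r, seed = 1) {
  stopifnot(n_samples > n_genes + 1)
  set.seed(seed)
  q <- qr.Q(qr(cbind(1, matrix(stats::rnorm(n_samples * (n_genes + 1)),
                               n_samples))))[, -1]
  z <- q[, 1]
  x <- sapply(seq_len(n_genes), function(i) sqrt(r) * z + sqrt(1 - r) * q[, i + 1])
  out <- t(x) * 10 + 100  # positive intensities, correlation unchanged
  rownames(out) <- sprintf("E%02d", seq_len(n_genes))
  colnames(out) <- sprintf("S%02d", seq_len(n_samples))
  out
}

# Metadata for a matrix whose first n_inv columns are invasive.
split_metadata <- function(mat, n_inv) {
  tibble::tibble(
    sample_id = colnames(mat),
    phenotype = rep(c("invasive", "non-invasive"),
                    c(n_inv, ncol(mat) - n_inv)))
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# Hand-built gene_module for filter fixtures (exported surface only).
new_test_module <- function(members, graph) {
  stats <- coexmod::module_stats(members, graph)
  structure(c(list(members = members, seed = members[1],
                   score = stats$density * stats$n_nodes),
              stats),
            class = "gene_module")
}
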