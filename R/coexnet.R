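#' Pearson correlation with a two-sided p-value
#'
#' Standard Pearson estimator with p from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom;
#' `|r| = 1` gives p = 0.
#'
#' @param x,y Numeric vectors of equal length (n >= 4), finite values.
#' @return Named list with `r` and `p`.
#' @export
correlation_with_p <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 4,
            all(is.finite(x)), all(is.finite(y)))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero-variance vector: correlation undefined", call. = FALSE)
  r <- stats::cor(x, y)
  list(r = r, p = cor_pvalue(r, length(x)))
}

cor_pvalue <- function(r, n) {
  p <- ifelse(abs(r) >= 1, 0,
              2 * stats::pt(-abs(r) * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps)),
                            df = n - 2))
  pmin(p, 1)
}

# All unordered pairs of rows of `mat` (genes x samples): r, p. Zero-variance
# genes are excluded with a warning (pairs involving them are not scored).
pairwise_correlations <- function(mat) {
  sds <- apply(mat, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance gene(s) excluded from correlation",
            call. = FALSE)
    mat <- mat[sds > 0, , drop = FALSE]
  }
  genes <- rownames(mat)
  if (length(genes) < 2)
    return(tibble::tibble(gene_a = character(), gene_b = character(),
                          r = numeric(), p = numeric()))
  cm <- stats::cor(t(mat))
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  r <- cm[idx]
  tibble::tibble(gene_a = genes[idx[, 1]], gene_b = genes[idx[, 2]],
                 r = r, p = cor_pvalue(r, ncol(mat)))
}

#' Score all gene pairs for co-expression within one phenotype
#'
#' Computes Pearson r and p for every unordered gene pair using only the
#' samples of one phenotype, BH-adjusts the p-values across all scored
#' pairs within that phenotype, and flags pairs with `|r| >= r_min` and
#' adjusted p <= `p_max` as co-expressed.
#'
#' @param mat Numeric matrix (typically restricted to DEGs), genes x
#'   samples.
#' @param metadata Data frame with `sample_id`, `phenotype`.
#' @param phenotype Which phenotype's samples to use (needs >= 4).
#' @param r_min Absolute-correlation gate (default 0.80).
#' @param p_max Adjusted-p gate (default 0.05).
#' @return Tibble `gene_a`, `gene_b` (canonical order `gene_a < gene_b`),
#'   `r`, `p`, `adj_p`, `coexpressed`.
#' @export
phenotype_edges <- function(mat, metadata, phenotype,
                            r_min = 0.80, p_max = 0.05) {
  mat <- as.matrix(mat)
  metadata <- as.data.frame(metadata)
  keep <- metadata$sample_id[metadata$phenotype == phenotype]
  keep <- intersect(colnames(mat), keep)
  if (length(keep) < 4)
    stop("phenotype '", phenotype, "' needs at least 4 samples", call. = FALSE)
  edges <- pairwise_correlations(mat[, keep, drop = FALSE])
  edges <- canonicalize_pairs(edges)
  edges$adj_p <- bh_adjust(edges$p)
  edges$coexpressed <- abs(edges$r) >= r_min & edges$adj_p <= p_max
  edges
}

canonicalize_pairs <- function(edges) {
  swap <- edges$gene_a > edges$gene_b
  tmp <- edges$gene_a[swap]
  edges$gene_a[swap] <- edges$gene_b[swap]
  edges$gene_b[swap] <- tmp
  dplyr::arrange(edges, .data$gene_a, .data$gene_b)
}

#' Score gene pairs in both phenotypes and compute the differential ratio
#'
#' Runs [phenotype_edges()] in the invasive and non-invasive phenotypes and
#' joins the results per pair, adding the differential co-expression ratio
#' `D = |(r_noninv - r_inv) / r_inv|`. A pair with `r_inv` exactly 0 is
#' maximally differential: D is `Inf`.
#'
#' @inheritParams phenotype_edges
#' @return Tibble with `gene_a`, `gene_b`, `r_inv`, `r_noninv`, `p_inv`,
#'   `p_noninv`, `adj_p_inv`, `adj_p_noninv`, `coexpressed_inv`,
#'   `coexpressed_noninv`, `D`.
#' @export
coexpression_edges <- function(mat, metadata, r_min = 0.80, p_max = 0.05) {
  inv <- phenotype_edges(mat, metadata, "invasive", r_min, p_max)
  non <- phenotype_edges(mat, metadata, "non-invasive", r_min, p_max)
  edges <- dplyr::inner_join(
    dplyr::rename(inv, r_inv = "r", p_inv = "p", adj_p_inv = "adj_p",
                  coexpressed_inv = "coexpressed"),
    dplyr::rename(non, r_noninv = "r", p_noninv = "p", adj_p_noninv = "adj_p",
                  coexpressed_noninv = "coexpressed"),
    by = c("gene_a", "gene_b"))
  edges$D <- differential_ratio(edges$r_noninv, edges$r_inv)
  edges
}

differential_ratio <- function(r_noninv, r_inv) {
  ifelse(r_inv == 0, Inf, abs((r_noninv - r_inv) / r_inv))
}

#' Keep pairs whose co-expression changes between phenotypes
#'
#' The differential criterion retains a pair iff
#' `D = |(r_noninv - r_inv) / r_inv| >= d_min` (default 1, a 100% relative
#' change). Pairs with `r_inv = 0` are kept (infinite relative change).
#'
#' @param edges Tibble from [coexpression_edges()].
#' @param d_min Minimum differential ratio (default 1).
#' @return The filtered tibble.
#' @export
differential_filter <- function(edges, d_min = 1) {
  stopifnot(all(c("r_inv", "r_noninv") %in% names(edges)))
  if (!"D" %in% names(edges))
    edges$D <- differential_ratio(edges$r_noninv, edges$r_inv)
  dplyr::filter(edges, .data$D >= d_min)
}

#' Build a phenotype-specific differential co-expression network
#'
#' The network for a phenotype contains the pairs that (a) satisfy the
#' co-expression criterion in that phenotype and (b) pass the differential
#' filter; nodes are the endpoints of surviving edges. With default
#' thresholds this yields the invasive (ICON) and non-invasive (NICON)
#' networks.
#'
#' @param edges Tibble from [coexpression_edges()].
#' @param phenotype `"invasive"` or `"non-invasive"`.
#' @param d_min Minimum differential ratio (default 1).
#' @return Object of class `coex_network`: list with `phenotype`, `edges`
#'   (tibble), `graph` (igraph).
#' @export
build_network <- function(edges, phenotype = c("invasive", "non-invasive"),
                          d_min = 1) {
  phenotype <- match.arg(phenotype)
  flag <- if (phenotype == "invasive") "coexpressed_inv" else "coexpressed_noninv"
  kept <- differential_filter(edges[edges[[flag]], , drop = FALSE], d_min)
  kept <- canonicalize_pairs(kept)
  g <- igraph::graph_from_data_frame(
    kept[, c("gene_a", "gene_b")], directed = FALSE,
    vertices = sort(unique(c(kept$gene_a, kept$gene_b))))
  structure(list(phenotype = phenotype, edges = kept, graph = g),
            class = "coex_network")
}

#' @export
print.coex_network <- function(x, ...) {
  cat("<coex_network> phenotype:", x$phenotype, "-",
      igraph::vcount(x$graph), "genes,", igraph::ecount(x$graph), "links\n")
  invisible(x)
}

#' Node and network topology metrics
#'
#' Per-node degree and (unnormalized, shortest-path) betweenness, plus
#' network-level summaries: the clustering coefficient (mean local
#' clustering coefficient over nodes with degree >= 2) and Freeman degree
#' centralization `sum(d_max - d_v) / ((N - 1) (N - 2))` (NA for networks
#' with fewer than 3 nodes).
#'
#' @param network A `coex_network` or an igraph object.
#' @return List with `nodes` (tibble `gene`, `degree`, `betweenness`,
#'   `clustering`) and `network` (tibble `n_nodes`, `n_edges`,
#'   `clustering_coefficient`, `centralization`).
#' @export
topology_metrics <- function(network) {
  g <- as_coex_graph(network)
  if (igraph::vcount(g) == 0) stop("network is empty", call. = FALSE)
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  local_cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  names(local_cc) <- igraph::V(g)$name
  n <- igraph::vcount(g)
  cc <- if (any(deg >= 2)) mean(local_cc[deg >= 2]) else NA_real_
  centr <- if (n >= 3) sum(max(deg) - deg) / ((n - 1) * (n - 2)) else NA_real_
  list(
    nodes = tibble::tibble(gene = names(deg), degree = unname(deg),
                           betweenness = unname(btw),
                           clustering = unname(local_cc)),
    network = tibble::tibble(n_nodes = n, n_edges = igraph::ecount(g),
                             clustering_coefficient = cc,
                             centralization = centr))
}

as_coex_graph <- function(network) {
  if (inherits(network, "coex_network")) network$graph
  else if (inherits(network, "igraph")) network
  else stop("expected a coex_network or igraph object", call. = FALSE)
}

#' Rank hub genes by degree, then betweenness
#'
#' Genes sorted by degree (descending), ties broken by betweenness
#' (descending), then lexicographically; the top `k` are returned.
#'
#' @param network A `coex_network` or igraph object.
#' @param k Number of hubs (default 8); `k` larger than the node count
#'   returns all nodes.
#' @return Tibble `gene`, `degree`, `betweenness`, ranked.
#' @export
hub_genes <- function(network, k = 8) {
  nodes <- topology_metrics(network)$nodes
  ranked <- dplyr::arrange(nodes, dplyr::desc(.data$degree),
                           dplyr::desc(.data$betweenness), .data$gene)
  utils::head(ranked[, c("gene", "degree", "betweenness")], k)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.coex_network <- function(x, ...) x$edges

#' @export
glance.coex_network <- function(x, ...) {
  if (igraph::vcount(x$graph) == 0)
    return(tibble::tibble(phenotype = x$phenotype, n_nodes = 0L, n_edges = 0L,
                          clustering_coefficient = NA_real_,
                          centralization = NA_real_))
  dplyr::bind_cols(tibble::tibble(phenotype = x$phenotype),
                   topology_metrics(x)$network)
}
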