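#' Read / write an expression matrix as TSV
#'
#' Gene x sample table; the first column (`gene`) holds gene ids, the
#' header holds sample ids.
#'
#' @param path File path.
#' @return `read_expression_tsv`: numeric matrix with gene rownames.
#' @export
read_expression_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(names(df)[1] == "gene")
  mat <- as.matrix(df[, -1])
  rownames(mat) <- df$gene
  if (anyNA(mat)) stop("expression matrix contains missing values", call. = FALSE)
  mat
}

#' @rdname read_expression_tsv
#' @param mat Numeric matrix, genes x samples, with dimnames.
#' @return `write_expression_tsv`: invisibly, `path`.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- dplyr::bind_cols(tibble::tibble(gene = rownames(mat)),
                         tibble::as_tibble(mat))
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read / write sample metadata as TSV
#'
#' Columns: `sample_id`, `phenotype`, and optionally `grade`,
#' `followup_years`, `event`.
#'
#' @param path File path.
#' @return `read_metadata_tsv`: a tibble.
#' @export
read_metadata_tsv <- function(path) {
  md <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("sample_id", "phenotype") %in% names(md)))
  md
}

#' @rdname read_metadata_tsv
#' @param metadata Data frame of sample metadata.
#' @return `write_metadata_tsv`: invisibly, `path`.
#' @export
write_metadata_tsv <- function(metadata, path) {
  readr::write_tsv(tibble::as_tibble(metadata), path)
  invisible(path)
}

#' Write a network as an edge-list TSV or GraphML
#'
#' The edge list carries `gene_a`, `gene_b`, `r_inv`, `r_noninv`, `D`;
#' GraphML export attaches degree and betweenness as node attributes and
#' the per-phenotype correlations as edge attributes.
#'
#' @param network A `coex_network`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_edges_tsv <- function(network, path) {
  cols <- intersect(c("gene_a", "gene_b", "r_inv", "r_noninv", "D"),
                    names(network$edges))
  readr::write_tsv(network$edges[, cols], path)
  invisible(path)
}

#' @rdname write_edges_tsv
#' @export
write_graphml <- function(network, path) {
  g <- network$graph
  if (igraph::vcount(g) > 0) {
    metrics <- topology_metrics(network)$nodes
    idx <- match(igraph::V(g)$name, metrics$gene)
    igraph::V(g)$degree <- metrics$degree[idx]
    igraph::V(g)$betweenness <- metrics$betweenness[idx]
    e <- network$edges
    if (igraph::ecount(g) > 0 && all(c("r_inv", "r_noninv") %in% names(e))) {
      el <- igraph::as_edgelist(g)
      key <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
      m <- match(key, paste(e$gene_a, e$gene_b))
      igraph::E(g)$r_inv <- e$r_inv[m]
      igraph::E(g)$r_noninv <- e$r_noninv[m]
      igraph::E(g)$D <- ifelse(is.finite(e$D[m]), e$D[m], -1)
    }
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read an edge-list TSV back into a tibble
#'
#' @param path File path.
#' @return Tibble with the stored edge columns.
#' @export
read_edges_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
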