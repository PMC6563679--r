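#' Refine merged modules into a core module under a tightened cutoff
#'
#' Recomputes phenotype-specific Pearson correlations among the union of
#' the selected module genes, keeps edges with `|r| >= r_min` in the
#' reference phenotype (non-invasive by default, where the differential
#' modules are active) that still satisfy the differential criterion
#' `D >= d_min`, and returns the genes of the largest connected component
#' of the surviving edge set — the minimal gene set that retains the
#' tightened co-expression pattern.
#'
#' @param module_union Character vector of gene ids (union of the selected
#'   modules).
#' @param mat Expression matrix, genes x samples.
#' @param metadata Data frame with `sample_id`, `phenotype`.
#' @param r_min Tightened absolute-correlation cutoff (default 0.90, up
#'   from the 0.80 used for network construction).
#' @param d_min Minimum differential ratio (default 1).
#' @param phenotype Phenotype in which the tightened cutoff is applied
#'   (default `"non-invasive"`).
#' @return Object of class `core_module`: list with `members`, `r_min`,
#'   `edges` (surviving edge tibble), `source_genes`. An empty core (no
#'   surviving edges) is returned with a warning.
#' @export
refine_core <- function(module_union, mat, metadata, r_min = 0.90,
                        d_min = 1, phenotype = "non-invasive") {
  module_union <- unique(module_union)
  stopifnot(length(module_union) >= 2)
  missing <- setdiff(module_union, rownames(mat))
  if (length(missing) > 0)
    stop("genes absent from the matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  sub <- as.matrix(mat)[module_union, , drop = FALSE]
  edges <- coexpression_edges(sub, metadata, r_min = r_min)
  rcol <- if (phenotype == "non-invasive") "r_noninv" else "r_inv"
  kept <- differential_filter(edges[abs(edges[[rcol]]) >= r_min, , drop = FALSE],
                              d_min)
  if (nrow(kept) == 0) {
    warning("no edges survive the tightened cutoff; core module is empty",
            call. = FALSE)
    members <- character(0)
  } else {
    g <- igraph::graph_from_data_frame(kept[, c("gene_a", "gene_b")],
                                       directed = FALSE)
    comp <- igraph::components(g)
    sizes <- comp$csize
    # largest component; ties broken by smallest member gene id
    best <- which(sizes == max(sizes))
    if (length(best) > 1) {
      firsts <- vapply(best, function(k)
        min(names(comp$membership)[comp$membership == k]), character(1))
      best <- best[order(firsts)][1]
    }
    members <- sort(names(comp$membership)[comp$membership == best])
  }
  structure(list(members = members, r_min = r_min, d_min = d_min,
                 phenotype = phenotype, edges = kept,
                 source_genes = sort(module_union)),
            class = "core_module")
}

#' @export
print.core_module <- function(x, ...) {
  cat("<core_module>", length(x$members), "genes at |r| >=", x$r_min,
      "in the", x$phenotype, "phenotype\n")
  invisible(x)
}

#' Project samples onto principal components of a gene set
#'
#' PCA of the samples in the space of the selected genes (per-gene
#' centered, unscaled). Components are ordered by eigenvalue; each
#' component's sign is fixed so that its largest-magnitude gene loading is
#' positive. The retained components are the minimal prefix whose
#' cumulative variance fraction reaches `var_threshold`.
#'
#' @param mat Expression matrix, genes x samples.
#' @param genes Gene ids to project on (>= 2, present in `mat`).
#' @param var_threshold Cumulative variance fraction to retain
#'   (default 0.85).
#' @return Object of class `subtype_projection`: list with `scores`
#'   (tibble, `sample_id` + `PC1..PCk`, all components), `var_explained`
#'   (numeric, sums to 1), `n_retained`, `var_threshold`, `loadings`
#'   (matrix genes x components).
#' @export
pca_project <- function(mat, genes, var_threshold = 0.85) {
  mat <- as.matrix(mat)
  stopifnot(length(unique(genes)) >= 2, ncol(mat) >= 3)
  missing <- setdiff(genes, rownames(mat))
  if (length(missing) > 0)
    stop("genes absent from the matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  x <- t(mat[unique(genes), , drop = FALSE])
  if (sum(apply(x, 2, stats::var)) == 0)
    stop("gene set has zero total variance", call. = FALSE)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  keep <- pc$sdev > 1e-12 * pc$sdev[1]
  scores <- pc$x[, keep, drop = FALSE]
  loadings <- pc$rotation[, keep, drop = FALSE]
  # sign convention: largest-magnitude loading of each component positive
  for (j in seq_len(ncol(loadings))) {
    lead <- which.max(abs(loadings[, j]))
    if (loadings[lead, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ve <- pc$sdev[keep]^2 / sum(pc$sdev^2)
  n_retained <- which(cumsum(ve) >= var_threshold - 1e-12)[1]
  if (is.na(n_retained)) n_retained <- length(ve)
  structure(list(
    scores = dplyr::bind_cols(tibble::tibble(sample_id = rownames(x)),
                              tibble::as_tibble(scores)),
    var_explained = unname(ve),
    n_retained = n_retained,
    var_threshold = var_threshold,
    loadings = loadings),
    class = "subtype_projection")
}

#' @export
print.subtype_projection <- function(x, ...) {
  cat("<subtype_projection>", nrow(x$scores), "samples;",
      x$n_retained, "component(s) retained at",
      sprintf("%.0f%%", 100 * x$var_threshold), "variance",
      sprintf("(PC1 %.1f%%)\n", 100 * x$var_explained[1]))
  invisible(x)
}

#' @export
tidy.subtype_projection <- function(x, ...) x$scores

#' @export
glance.subtype_projection <- function(x, ...) {
  tibble::tibble(n_components = length(x$var_explained),
                 n_retained = x$n_retained,
                 var_threshold = x$var_threshold,
                 pc1_var = x$var_explained[1],
                 retained_var = sum(x$var_explained[seq_len(x$n_retained)]))
}

#' Silhouette-based separation of labeled samples in retained-PC space
#'
#' Mean silhouette coefficient of the samples over the retained principal
#' components (Euclidean distance). Samples in singleton classes get a
#' silhouette of 0.
#'
#' @param projection A `subtype_projection`.
#' @param labels Class labels, one per sample (>= 2 classes).
#' @return Mean silhouette in \[-1, 1\].
#' @export
separation_score <- function(projection, labels) {
  stopifnot(inherits(projection, "subtype_projection"))
  scores <- as.matrix(projection$scores[, -1, drop = FALSE])
  scores <- scores[, seq_len(projection$n_retained), drop = FALSE]
  labels <- as.integer(factor(labels))
  if (length(labels) != nrow(scores))
    stop("one label per sample required", call. = FALSE)
  if (length(unique(labels)) < 2)
    stop("need at least 2 distinct labels", call. = FALSE)
  sil <- cluster::silhouette(labels, stats::dist(scores))
  mean(sil[, "sil_width"])
}
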