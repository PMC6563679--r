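#' Read a gene-set collection from a GMT file
#'
#' Each GMT line is tab-separated: set name, description, then member gene
#' ids. Duplicate members within a set are dropped.
#'
#' @param path Path to a GMT file.
#' @return Tibble with `set`, `description`, `genes` (list column of
#'   character vectors).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad) > 0)
    stop("malformed GMT line (fewer than 3 fields) at line ", bad[1],
         call. = FALSE)
  out <- tibble::tibble(
    set = vapply(fields, `[[`, character(1), 1),
    description = vapply(fields, `[[`, character(1), 2),
    genes = lapply(fields, function(f) unique(f[-(1:2)])))
  if (anyDuplicated(out$set))
    stop("duplicate set names in GMT file", call. = FALSE)
  out
}

#' Write a gene-set collection to a GMT file
#'
#' @param collection Tibble as returned by [read_gmt()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(collection, path) {
  lines <- purrr::pmap_chr(collection, function(set, description, genes, ...) {
    paste(c(set, description, genes), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

#' Over-representation analysis of a gene list
#'
#' One-sided hypergeometric (Fisher upper-tail) test per gene set: the
#' probability of observing at least the actual overlap between the query
#' and the set, drawing `|query|` genes from the background. Set members
#' outside the background are discarded before testing; p-values are
#' BH-adjusted across tested sets and flagged significant at
#' `adj_p < alpha`.
#'
#' @param query Character vector of genes of interest (non-empty, a subset
#'   of `background`).
#' @param background Character vector, the gene universe (e.g. all genes
#'   measured on the platform after probe collapse).
#' @param collection Tibble from [read_gmt()] (columns `set`, `genes`).
#' @param alpha Adjusted-p significance cutoff (default 0.01).
#' @return Tibble `set`, `overlap`, `set_size`, `query_size`,
#'   `background_size`, `p`, `adj_p`, `significant`, ordered by `p`.
#' @export
overrepresentation <- function(query, background, collection, alpha = 0.01) {
  query <- unique(query)
  background <- unique(background)
  if (length(query) == 0) stop("empty query gene list", call. = FALSE)
  stray <- setdiff(query, background)
  if (length(stray) > 0)
    stop("query genes outside the background: ",
         paste(utils::head(stray, 5), collapse = ", "), call. = FALSE)
  n_bg <- length(background)
  n_q <- length(query)
  rows <- purrr::map2_dfr(collection$set, collection$genes, function(nm, g) {
    g <- intersect(g, background)
    k <- length(intersect(g, query))
    p <- if (length(g) == 0) 1 else
      stats::phyper(k - 1, length(g), n_bg - length(g), n_q,
                    lower.tail = FALSE)
    tibble::tibble(set = nm, overlap = k, set_size = length(g),
                   query_size = n_q, background_size = n_bg, p = p)
  })
  rows$adj_p <- bh_adjust(rows$p)
  rows$significant <- rows$adj_p < alpha
  dplyr::arrange(rows, .data$p, .data$set)
}
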