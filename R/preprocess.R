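#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) to share the same empirical distribution:
#' the across-sample mean of order statistics. Ranks within each sample are
#' preserved and ties receive the mean of their tied quantile values.
#'
#' @param mat Numeric matrix, genes as rows, samples as columns (>= 2
#'   columns).
#' @return Matrix of the same shape and dimnames.
#' @examples
#' m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
#' quantile_normalize(m)  # both columns become 2.5, 3.5, 4.5
#' @export
quantile_normalize <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) == 0 || ncol(mat) < 2)
    stop("quantile normalization needs a non-empty matrix with >= 2 samples",
         call. = FALSE)
  if (anyNA(mat)) stop("expression matrix contains missing values", call. = FALSE)
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Collapse duplicate measurements to one row per gene
#'
#' Rows (probes) mapping to the same gene symbol are replaced by their
#' per-sample arithmetic mean. Probes absent from the map are retained under
#' their measurement id, so unannotated probes survive into downstream
#' analyses.
#'
#' @param mat Numeric matrix with probe ids as rownames.
#' @param gene_map Data frame with columns `probe_id` and `symbol`; an empty
#'   map is the identity transform.
#' @return Matrix with one row per symbol plus one per unmapped probe,
#'   ordered symbols first.
#' @export
collapse_duplicates <- function(mat, gene_map) {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat))) stop("matrix must have probe rownames", call. = FALSE)
  if (nrow(gene_map) == 0) return(mat)
  stopifnot(all(c("probe_id", "symbol") %in% names(gene_map)))
  key <- gene_map$symbol[match(rownames(mat), gene_map$probe_id)]
  unmapped <- is.na(key)
  key[unmapped] <- rownames(mat)[unmapped]
  sums <- rowsum(mat, group = key)
  counts <- as.vector(table(key)[rownames(sums)])
  out <- sums / counts
  mapped_first <- order(rownames(out) %in% rownames(mat)[unmapped], rownames(out))
  out[mapped_first, , drop = FALSE]
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate control:
#' `adj_p(i) = min over rank j >= rank(i) of m * p(j) / j`, capped at 1.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Differential expression between invasive and non-invasive groups
#'
#' Tests run on `log2(x + 1)`-transformed intensities; fold change is
#' reported on the linear scale as `mean(invasive) / mean(non-invasive)`.
#' The moderated t shrinks per-gene variances toward a pooled prior by
#' empirical Bayes (limma); `welch_t` is an unequal-variance two-sample t.
#' A gene is called `up` when FC > `fc_up` and BH-adjusted p < `alpha`,
#' `down` when FC < `fc_down` and adjusted p < `alpha`, otherwise `none` —
#' the fold-change gate is applied after multiple-testing adjustment.
#'
#' @param mat Numeric matrix, genes x samples, non-negative intensities.
#' @param metadata Data frame with `sample_id` and `phenotype`
#'   (`"invasive"` / `"non-invasive"`); both groups need >= 2 samples.
#' @param method `"moderated_t"` (default) or `"welch_t"`.
#' @param alpha Adjusted-p significance gate (default 0.05).
#' @param fc_down,fc_up Linear fold-change gates (default 0.9 / 1.1, i.e. a
#'   10% change in mean expression).
#' @return Tibble with columns `gene`, `fc`, `p`, `adj_p`, `direction`.
#' @export
differential_expression <- function(mat, metadata,
                                    method = c("moderated_t", "welch_t"),
                                    alpha = 0.05,
                                    fc_down = 0.9, fc_up = 1.1) {
  method <- match.arg(method)
  mat <- as.matrix(mat)
  metadata <- as.data.frame(metadata)
  stopifnot(all(c("sample_id", "phenotype") %in% names(metadata)))
  md <- metadata[match(colnames(mat), metadata$sample_id), ]
  if (anyNA(md$phenotype))
    stop("every sample needs a phenotype label", call. = FALSE)
  grp <- factor(md$phenotype, levels = c("non-invasive", "invasive"))
  if (any(table(grp) < 2))
    stop("both phenotype groups need at least 2 samples", call. = FALSE)

  logx <- log2(mat + 1)
  inv <- grp == "invasive"
  fc <- rowMeans(mat[, inv, drop = FALSE]) /
    rowMeans(mat[, !inv, drop = FALSE])

  if (method == "moderated_t") {
    design <- stats::model.matrix(~grp)
    fit <- limma::eBayes(limma::lmFit(logx, design))
    p <- fit$p.value[, 2]
  } else {
    p <- welch_t_rows(logx[, inv, drop = FALSE], logx[, !inv, drop = FALSE])
  }
  adj_p <- bh_adjust(p)
  direction <- dplyr::case_when(
    adj_p < alpha & fc > fc_up ~ "up",
    adj_p < alpha & fc < fc_down ~ "down",
    .default = "none")
  tibble::tibble(gene = rownames(mat), fc = unname(fc), p = unname(p),
                 adj_p = unname(adj_p), direction = direction)
}

# Row-wise Welch t-test p-values (two-sided). Zero-variance rows get a small
# variance floor; equal-mean zero-variance rows get p = 1.
welch_t_rows <- function(a, b) {
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- apply(a, 1, stats::var); v2 <- apply(b, 1, stats::var)
  floor_v <- 1e-12
  degenerate <- (v1 + v2) == 0
  v1 <- pmax(v1, floor_v); v2 <- pmax(v2, floor_v)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  p[degenerate & m1 == m2] <- 1
  p
}
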