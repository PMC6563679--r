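#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Volcano plot of a differential-expression table
#'
#' Linear fold change (log2 axis) against -log10 adjusted p, colored by
#' call direction.
#'
#' @param deg_table Tibble from [differential_expression()].
#' @return A ggplot object.
#' @export
plot_volcano <- function(deg_table) {
  ggplot2::ggplot(deg_table,
                  ggplot2::aes(x = log2(.data$fc),
                               y = -log10(pmax(.data$adj_p, 1e-300)),
                               color = .data$direction)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_color_manual(
      values = c(up = "#d73027", down = "#4575b4", none = "grey60")) +
    ggplot2::labs(x = "log2 fold change (invasive / non-invasive)",
                  y = "-log10 adjusted p", color = "call") +
    ggplot2::theme_minimal()
}

#' @describeIn pca_project Scatter of samples on the first two components,
#'   optionally colored by a label vector (e.g. phenotype or cluster).
#' @param object A `subtype_projection`.
#' @param labels Optional per-sample labels for coloring.
#' @param ... Unused.
#' @export
autoplot.subtype_projection <- function(object, labels = NULL, ...) {
  df <- object$scores
  if (!is.null(labels)) df$label <- as.factor(labels)
  ve <- object$var_explained
  p <- if (ncol(df) >= 3 && "PC2" %in% names(df)) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
      ggplot2::labs(
        x = sprintf("PC1 (%.1f%%)", 100 * ve[1]),
        y = sprintf("PC2 (%.1f%%)", 100 * ve[2]))
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = 0)) +
      ggplot2::labs(x = sprintf("PC1 (%.1f%%)", 100 * ve[1]), y = NULL)
  }
  p <- p + ggplot2::theme_minimal()
  if (is.null(labels)) p + ggplot2::geom_point()
  else p + ggplot2::geom_point(ggplot2::aes(color = .data$label)) +
    ggplot2::labs(color = NULL)
}

#' @describeIn evaluate_prognosis Kaplan-Meier step curves per group.
#' @param object A `prognosis_result`.
#' @param ... Unused.
#' @export
autoplot.prognosis_result <- function(object, ...) {
  km <- object$km
  # prepend the (0, 1) origin per group so curves start at full survival
  origins <- dplyr::distinct(km, .data$group)
  origins$time <- 0; origins$survival <- 1
  df <- dplyr::bind_rows(origins, km[, c("group", "time", "survival")])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival,
                                   color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "follow-up (years)", y = "survival probability",
                  color = "group") +
    ggplot2::theme_minimal()
}
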