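#' Cluster patients on principal-component scores
#'
#' k-means on the first `n_components` PC scores of a
#' [pca_project()] projection, 25 random restarts, best inertia kept.
#' Cluster ids are relabeled in increasing order of mean PC1 score so the
#' labeling is stable: cluster 1 has the lowest mean PC1.
#'
#' @param projection A `subtype_projection`.
#' @param k Number of clusters (default 3).
#' @param n_components How many leading components to use (default 3;
#'   truncated to what is available).
#' @param seed Integer seed for the restarts.
#' @return Tibble `sample_id`, `cluster` (integer).
#' @export
cluster_patients <- function(projection, k = 3, n_components = 3, seed = 1L) {
  stopifnot(inherits(projection, "subtype_projection"))
  scores <- as.matrix(projection$scores[, -1, drop = FALSE])
  n_components <- min(n_components, ncol(scores))
  x <- scores[, seq_len(n_components), drop = FALSE]
  if (k > nrow(x)) stop("k exceeds the number of samples", call. = FALSE)
  set.seed(seed)
  km <- stats::kmeans(x, centers = k, nstart = 25)
  # relabel by increasing mean PC1
  pc1_means <- tapply(x[, 1], km$cluster, mean)
  relabel <- match(km$cluster, as.integer(names(sort(pc1_means))))
  tibble::tibble(sample_id = projection$scores$sample_id,
                 cluster = as.integer(relabel))
}

as_survival_df <- function(records) {
  records <- as.data.frame(records)
  if (!"time" %in% names(records) && "followup_years" %in% names(records))
    records$time <- records$followup_years
  stopifnot(all(c("time", "event") %in% names(records)))
  if (any(records$time <= 0)) stop("survival times must be > 0", call. = FALSE)
  records$event <- as.integer(records$event)
  records
}

#' Kaplan-Meier survival curves
#'
#' Product-limit estimator `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over
#' distinct event times, per group if a `group` column is present.
#'
#' @param records Data frame with `time` (> 0, years), `event` (logical or
#'   0/1) and optionally `group`.
#' @return Tibble with `group`, `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival` — one row per distinct observed time per group.
#' @export
kaplan_meier <- function(records) {
  records <- as_survival_df(records)
  if (nrow(records) == 0) stop("no survival records", call. = FALSE)
  has_group <- "group" %in% names(records)
  fit <- if (has_group) {
    survival::survfit(survival::Surv(time, event) ~ group, data = records)
  } else {
    survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  }
  s <- summary(fit, censored = TRUE)
  grp <- if (has_group) sub("^group=", "", as.character(s$strata))
         else rep("all", length(s$time))
  tibble::tibble(group = grp, time = s$time, n_risk = s$n.risk,
                 n_event = s$n.event, n_censor = s$n.censor,
                 survival = s$surv)
}

#' Log-rank test for survival differences between groups
#'
#' Standard observed-minus-expected statistic with hypergeometric variance
#' at each distinct event time; for more than two groups the k-sample form.
#' p is from a chi-square with (groups - 1) degrees of freedom.
#'
#' @param records Data frame with `time`, `event`, `group` (at least 2
#'   groups and 1 event overall).
#' @return Tibble `chi_square`, `df`, `p`.
#' @export
log_rank_test <- function(records) {
  records <- as_survival_df(records)
  stopifnot("group" %in% names(records))
  records$group <- factor(records$group)
  if (nlevels(records$group) < 2)
    stop("log-rank test needs >= 2 groups", call. = FALSE)
  if (sum(records$event) == 0)
    stop("log-rank test needs at least one event", call. = FALSE)
  fit <- survival::survdiff(survival::Surv(time, event) ~ group,
                            data = records)
  df <- length(fit$n) - 1
  tibble::tibble(chi_square = fit$chisq, df = df,
                 p = stats::pchisq(fit$chisq, df, lower.tail = FALSE))
}

#' Cox proportional hazards fit for a single covariate
#'
#' Partial-likelihood maximization (Newton iterations, Efron tie handling)
#' via the survival package. Reports the coefficient, hazard ratio, 95%
#' Wald confidence interval and Wald p-value.
#'
#' @param records Data frame with `time`, `event`.
#' @param covariate Numeric (or 2-level factor) vector, one value per
#'   record; must be non-constant.
#' @return Tibble `term`, `beta`, `se`, `hr`, `ci_lower`, `ci_upper`, `p`.
#' @export
cox_ph <- function(records, covariate) {
  records <- as_survival_df(records)
  if (length(unique(covariate)) < 2)
    stop("covariate is constant", call. = FALSE)
  if (sum(records$event) == 0)
    stop("Cox model needs at least one event", call. = FALSE)
  d <- data.frame(time = records$time, event = records$event, x = covariate)
  fit <- survival::coxph(survival::Surv(time, event) ~ x, data = d,
                         ties = "efron",
                         control = survival::coxph.control(eps = 1e-8,
                                                           iter.max = 50))
  beta <- unname(stats::coef(fit))
  se <- sqrt(diag(stats::vcov(fit)))
  if (!is.finite(se) || se > 50)
    warning("monotone likelihood suspected (near-complete separation); ",
            "coefficient unreliable", call. = FALSE)
  tibble::tibble(term = names(stats::coef(fit)), beta = beta, se = unname(se),
                 hr = exp(beta), ci_lower = exp(beta - 1.96 * se),
                 ci_upper = exp(beta + 1.96 * se),
                 p = 2 * stats::pnorm(-abs(beta / se)))
}

#' Risk split and survival assessment for a gene signature
#'
#' Fits a multivariate Cox model on the signature genes' expression, forms
#' the prognostic index `PI = sum_g beta_g x_g` per sample (the Cox linear
#' predictor), splits samples at the median index into low/high risk, and
#' evaluates the split by Kaplan-Meier curves, the log-rank test and a
#' two-group Cox hazard ratio (high vs low risk).
#'
#' @param mat Expression matrix, genes x samples.
#' @param genes Signature gene ids; absent genes are reported and skipped,
#'   but at least 2 must be present.
#' @param records Data frame with `sample_id`, `time`, `event` covering the
#'   matrix samples.
#' @return Object of class `prognosis_result` (see
#'   [evaluate_prognosis()]), with an extra `prognostic_index` tibble.
#' @export
signature_risk_assessment <- function(mat, genes, records) {
  mat <- as.matrix(mat)
  records <- as_survival_df(records)
  stopifnot("sample_id" %in% names(records))
  present <- intersect(genes, rownames(mat))
  absent <- setdiff(genes, present)
  if (length(absent) > 0)
    warning("signature genes absent and skipped: ",
            paste(absent, collapse = ", "), call. = FALSE)
  if (length(present) < 2)
    stop("fewer than 2 signature genes present in the matrix", call. = FALSE)
  records <- records[match(colnames(mat), records$sample_id), ]
  if (anyNA(records$time))
    stop("survival records missing for some samples", call. = FALSE)
  x <- scale(t(mat[present, , drop = FALSE]))
  d <- data.frame(time = records$time, event = records$event)
  fit <- survival::coxph(survival::Surv(time, event) ~ x, data = d,
                         ties = "efron")
  pi_score <- as.vector(x %*% stats::coef(fit))
  risk <- ifelse(pi_score > stats::median(pi_score), "high", "low")
  if (min(table(risk)) < 2)
    stop("degenerate median split: a risk group has < 2 samples",
         call. = FALSE)
  res <- evaluate_prognosis(
    tibble::tibble(sample_id = records$sample_id, time = records$time,
                   event = records$event == 1, group = risk),
    reference = "low")
  res$prognostic_index <- tibble::tibble(sample_id = records$sample_id,
                                         index = pi_score, risk = risk)
  res
}

#' Evaluate grouped survival records
#'
#' Bundles the Kaplan-Meier curves, log-rank test and (for the two-group
#' contrast) the Cox hazard ratio of grouped survival records into one
#' result object with [tidy()]/[glance()] methods.
#'
#' @param records Data frame with `time`, `event`, `group` (and optionally
#'   `sample_id`).
#' @param reference Group treated as baseline in the Cox contrast; default
#'   is the first group level. With more than 2 groups the Cox fit
#'   contrasts the last group level against the reference.
#' @return Object of class `prognosis_result`: list with `km` (tibble),
#'   `log_rank` (tibble), `cox` (tibble), `records`.
#' @export
evaluate_prognosis <- function(records, reference = NULL) {
  records <- as_survival_df(records)
  stopifnot("group" %in% names(records))
  grp <- factor(records$group)
  if (!is.null(reference)) grp <- stats::relevel(grp, ref = reference)
  km <- kaplan_meier(records)
  lr <- log_rank_test(records)
  covariate <- as.integer(grp == levels(grp)[nlevels(grp)])
  cox <- cox_ph(records, covariate)
  cox$term <- paste0(levels(grp)[nlevels(grp)], "_vs_", levels(grp)[1])
  structure(list(km = km, log_rank = lr, cox = cox,
                 records = tibble::as_tibble(records)),
            class = "prognosis_result")
}

#' @export
print.prognosis_result <- function(x, ...) {
  cat("<prognosis_result>", length(unique(x$records$group)), "groups,",
      nrow(x$records), "samples,", sum(x$records$event), "events\n")
  cat(sprintf("  log-rank chi-square %.3f (df %d), p = %.4g\n",
              x$log_rank$chi_square, x$log_rank$df, x$log_rank$p))
  cat(sprintf("  Cox %s: HR %.2f [%.2f, %.2f], p = %.4g\n", x$cox$term,
              x$cox$hr, x$cox$ci_lower, x$cox$ci_upper, x$cox$p))
  invisible(x)
}

#' @export
tidy.prognosis_result <- function(x, ...) x$km

#' @export
glance.prognosis_result <- function(x, ...) {
  tibble::tibble(chi_square = x$log_rank$chi_square, df = x$log_rank$df,
                 log_rank_p = x$log_rank$p, term = x$cox$term,
                 hr = x$cox$hr, ci_lower = x$cox$ci_lower,
                 ci_upper = x$cox$ci_upper, cox_p = x$cox$p)
}

#' Compare one gene's expression between phenotype groups
#'
#' Two-sided Welch two-sample t-test on the gene's expression between the
#' invasive and non-invasive groups, reporting per-group mean and standard
#' error — the classical single-marker verification (e.g. the MKI67
#' proliferation marker).
#'
#' @param mat Expression matrix, genes x samples.
#' @param metadata Data frame with `sample_id`, `phenotype`.
#' @param gene Gene id (must be present; both groups need >= 2 samples).
#' @return Tibble `gene`, `mean_invasive`, `se_invasive`,
#'   `mean_noninvasive`, `se_noninvasive`, `t`, `p`.
#' @export
marker_group_test <- function(mat, metadata, gene) {
  mat <- as.matrix(mat)
  if (!gene %in% rownames(mat))
    stop("gene '", gene, "' not present in the matrix", call. = FALSE)
  metadata <- as.data.frame(metadata)
  md <- metadata[match(colnames(mat), metadata$sample_id), ]
  x <- mat[gene, md$phenotype == "invasive"]
  y <- mat[gene, md$phenotype == "non-invasive"]
  if (length(x) < 2 || length(y) < 2)
    stop("both phenotype groups need >= 2 samples", call. = FALSE)
  se <- function(v) stats::sd(v) / sqrt(length(v))
  if (stats::sd(x) == 0 && stats::sd(y) == 0 && mean(x) == mean(y)) {
    tt <- list(statistic = 0, p.value = 1)
  } else {
    tt <- stats::t.test(x, y)
  }
  tibble::tibble(gene = gene, mean_invasive = mean(x), se_invasive = se(x),
                 mean_noninvasive = mean(y), se_noninvasive = se(y),
                 t = unname(tt$statistic), p = tt$p.value)
}
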