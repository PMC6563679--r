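#' Simulation configuration for two-phenotype expression data
#'
#' Describes a synthetic cohort of invasive and non-invasive tumor samples
#' with planted co-expression blocks, differential expression effects, and
#' survival outcomes. Defaults emulate a 40-sample (22 invasive /
#' 18 non-invasive) microarray cohort with follow-up between 3 and 10.5
#' years.
#'
#' Planted modules are gene blocks drawn from a shared latent factor so that
#' within-block pairwise correlation equals `r_noninv` in non-invasive
#' samples and `r_inv` in invasive samples (compound symmetry on the
#' Gaussian latent scale; the exponentiation to intensities attenuates the
#' Pearson correlation by a factor that is negligible at the default
#' `noise_sd`).
#'
#' @param n_genes Number of genes.
#' @param n_invasive,n_noninvasive Group sizes (each must be >= 3).
#' @param planted_modules List of blocks, each a list/vector with elements
#'   `size`, `r_noninv`, `r_inv` (|r| < 1). Blocks occupy the first genes.
#' @param deg_fraction Fraction of genes given a multiplicative
#'   fold-change effect in the invasive group. Planted module genes are
#'   covered first so that blocks survive a differential-expression gate.
#' @param fc_effect Multiplicative fold change (> 0) for planted DEGs; half
#'   of the DEGs are shifted up (x `fc_effect`), half down (/ `fc_effect`).
#' @param noise_sd Standard deviation of the per-gene Gaussian latent on the
#'   natural-log scale.
#' @param followup_range Length-2 numeric, (min, max) administrative
#'   follow-up in years.
#' @param true_hr Hazard ratio of the high-risk latent group (> 0).
#' @param event_rate_baseline Baseline hazard (events per year) of the
#'   low-risk group; 0 means no events ever occur.
#' @param seed Integer seed; all randomness in [simulate_expression()] and
#'   [simulate_survival()] flows from it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_expression()], [simulate_survival()]
#' @export
sim_config <- function(n_genes = 2000L,
                       n_invasive = 22L,
                       n_noninvasive = 18L,
                       planted_modules = list(),
                       deg_fraction = 0,
                       fc_effect = 1.5,
                       noise_sd = 0.3,
                       followup_range = c(3, 10.5),
                       true_hr = 1,
                       event_rate_baseline = 0.15,
                       seed = 1L) {
  stopifnot(n_genes >= 1, noise_sd > 0, fc_effect > 0,
            deg_fraction >= 0, deg_fraction <= 1,
            length(followup_range) == 2)
  if (n_invasive < 3 || n_noninvasive < 3)
    stop("each phenotype group needs at least 3 samples", call. = FALSE)
  if (followup_range[1] <= 0 || followup_range[1] >= followup_range[2])
    stop("followup_range must satisfy 0 < min < max", call. = FALSE)
  if (true_hr <= 0) stop("true_hr must be positive", call. = FALSE)
  if (event_rate_baseline < 0)
    stop("event_rate_baseline must be non-negative", call. = FALSE)
  planted_modules <- lapply(planted_modules, function(m) {
    m <- as.list(m)
    stopifnot(all(c("size", "r_noninv", "r_inv") %in% names(m)))
    if (m$size > n_genes)
      stop("planted module size exceeds n_genes", call. = FALSE)
    if (abs(m$r_noninv) >= 1 || abs(m$r_inv) >= 1)
      stop("planted module correlations must satisfy |r| < 1", call. = FALSE)
    if (m$r_noninv < 0 || m$r_inv < 0)
      stop("shared-factor construction requires non-negative block correlations",
           call. = FALSE)
    m
  })
  if (sum(vapply(planted_modules, `[[`, numeric(1), "size")) > n_genes)
    stop("planted modules exceed n_genes in total", call. = FALSE)
  structure(
    list(n_genes = as.integer(n_genes),
         n_invasive = as.integer(n_invasive),
         n_noninvasive = as.integer(n_noninvasive),
         planted_modules = planted_modules,
         deg_fraction = deg_fraction,
         fc_effect = fc_effect,
         noise_sd = noise_sd,
         followup_range = as.numeric(followup_range),
         true_hr = true_hr,
         event_rate_baseline = event_rate_baseline,
         seed = as.integer(seed)),
    class = "sim_config")
}

#' Simulate a two-phenotype expression cohort with planted structure
#'
#' Draws strictly positive intensities for `n_genes` genes across invasive
#' and non-invasive samples. Genes of a planted block share a per-phenotype
#' latent factor: within block, gene latents are
#' `sqrt(r) * z_block + sqrt(1 - r) * eps`, giving exact compound symmetry
#' with target correlation `r` for that phenotype. Intensities are
#' `exp(mu_g + noise_sd * latent)`, optionally multiplied by the fold-change
#' effect for planted DEGs in invasive samples.
#'
#' The latent risk group is tied to phenotype (invasive = high risk) and
#' grades are assigned deterministically from it (high risk = grade IV,
#' low risk = grade II), so that survival simulated from the risk labels
#' aligns with phenotype the way an invasiveness-driven prognosis would.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `coex_sim` with elements:
#'   * `expression` — numeric matrix, genes x samples, positive intensities;
#'   * `metadata` — tibble with `sample_id`, `phenotype`, `grade`,
#'     `followup_years`, `event` (the last two filled by
#'     [simulate_survival()], already applied);
#'   * `truth` — list with `planted_deg_ids` (tibble gene/direction),
#'     `planted_module_members` (list of character vectors), `risk_labels`,
#'     `true_hr`.
#' @examples
#' sim <- simulate_expression(sim_config(n_genes = 50, seed = 7))
#' dim(sim$expression)
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_inv <- config$n_invasive
  n_non <- config$n_noninvasive
  n_samp <- n_inv + n_non
  n_genes <- config$n_genes

  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  sample_ids <- c(sprintf("INV%02d", seq_len(n_inv)),
                  sprintf("NON%02d", seq_len(n_non)))
  phenotype <- rep(c("invasive", "non-invasive"), c(n_inv, n_non))

  # independent latents, then overwrite planted blocks with shared-factor draws
  latent <- matrix(stats::rnorm(n_genes * n_samp), n_genes, n_samp)
  members <- list()
  offset <- 0L
  for (m in config$planted_modules) {
    idx <- offset + seq_len(m$size)
    members <- c(members, list(gene_ids[idx]))
    for (ph in c("invasive", "non-invasive")) {
      cols <- which(phenotype == ph)
      r <- if (ph == "invasive") m$r_inv else m$r_noninv
      z_block <- stats::rnorm(length(cols))
      eps <- matrix(stats::rnorm(m$size * length(cols)), m$size)
      latent[idx, cols] <- sqrt(r) * rep(z_block, each = m$size) +
        sqrt(1 - r) * eps
    }
    offset <- offset + m$size
  }

  mu <- stats::rnorm(n_genes, mean = log(100), sd = 1)
  expr <- exp(mu + config$noise_sd * latent)

  # planted DEGs: module genes first, then random others, alternate up/down
  n_deg <- round(config$deg_fraction * n_genes)
  deg_truth <- tibble::tibble(gene = character(), direction = character())
  if (n_deg > 0) {
    block_idx <- seq_len(offset)
    extra <- setdiff(seq_len(n_genes), block_idx)
    deg_idx <- c(block_idx, sample(extra))[seq_len(n_deg)]
    dir <- rep(c("up", "down"), length.out = n_deg)
    fc <- ifelse(dir == "up", config$fc_effect, 1 / config$fc_effect)
    expr[deg_idx, phenotype == "invasive"] <-
      expr[deg_idx, phenotype == "invasive"] * fc
    deg_truth <- tibble::tibble(gene = gene_ids[deg_idx], direction = dir)
  }

  dimnames(expr) <- list(gene_ids, sample_ids)
  risk <- ifelse(phenotype == "invasive", "high", "low")
  metadata <- tibble::tibble(
    sample_id = sample_ids,
    phenotype = phenotype,
    grade = ifelse(risk == "high", "IV", "II"))

  surv <- simulate_survival(risk, config)
  metadata$followup_years <- surv$time
  metadata$event <- surv$event

  structure(
    list(expression = expr,
         metadata = metadata,
         truth = list(planted_deg_ids = deg_truth,
                      planted_module_members = members,
                      risk_labels = risk,
                      true_hr = config$true_hr)),
    class = "coex_sim")
}

#' Simulate survival outcomes from latent risk labels
#'
#' Event times are exponential with hazard
#' `event_rate_baseline * true_hr^(risk == "high")`; administrative
#' censoring times are uniform on `followup_range`. The recorded time is the
#' minimum of the two, and the event flag indicates the event occurred
#' before censoring.
#'
#' @param risk_labels Character vector, one `"high"`/`"low"` label per
#'   sample.
#' @param config A [sim_config()] object.
#' @return Tibble with `risk`, `time` (years), `event` (logical).
#' @export
simulate_survival <- function(risk_labels, config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$true_hr <= 0) stop("true_hr must be positive", call. = FALSE)
  n <- length(risk_labels)
  rate <- config$event_rate_baseline *
    ifelse(risk_labels == "high", config$true_hr, 1)
  event_time <- ifelse(rate > 0, stats::rexp(n) / pmax(rate, 1e-300), Inf)
  censor_time <- stats::runif(n, config$followup_range[1],
                              config$followup_range[2])
  tibble::tibble(
    risk = risk_labels,
    time = pmin(event_time, censor_time),
    event = event_time <= censor_time)
}

#' Write a simulated cohort to plain-text files
#'
#' Expression as gene x sample TSV (first column `gene`), metadata as TSV,
#' ground truth as JSON.
#'
#' @param sim A `coex_sim` object from [simulate_expression()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "coex_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             truth = file.path(dir, "truth.json"))
  write_expression_tsv(sim$expression, paths[["expression"]])
  readr::write_tsv(sim$metadata, paths[["metadata"]])
  truth <- sim$truth
  truth$planted_deg_ids <- as.list(truth$planted_deg_ids)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
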