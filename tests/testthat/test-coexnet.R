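test_that("correlation estimator and p-value behave canonically", {
  set.seed(1)
  x <- rnorm(10)
  expect_equal(correlation_with_p(x, x)$r, 1)
  expect_equal(correlation_with_p(x, x)$p, 0)
  expect_equal(correlation_with_p(x, -x)$r, -1)
  expect_error(correlation_with_p(x, rep(2, 10)), "zero-variance")
  expect_error(correlation_with_p(x, rnorm(9)))

  # analytic p tracks the permutation null; at n = 10 the two nulls differ
  # by up to a few percent for individual samples (the permutation null
  # conditions on the data), so compare in aggregate
  set.seed(42)
  diffs <- replicate(10, {
    x <- rnorm(10); y <- rnorm(10)
    abs(correlation_with_p(x, y)$p - perm_cor_p(x, y, B = 4000))
  })
  expect_lt(median(diffs), 0.02)
  expect_lt(max(diffs), 0.12)
})

test_that("phenotype edge scoring flags planted blocks and respects gates", {
  # strongly co-expressed block in the non-invasive group: the bulk of the
  # 45 within-block pairs clears the |r| >= 0.8 + BH gate in every seed,
  # and >= 90% of pairs on average (all-45-in-one-seed is not typical at
  # n = 18 even for exact compound symmetry, by simulation oracle)
  frac <- sapply(1:10, function(s) {
    cfg <- sim_config(n_genes = 60,
                      planted_modules = list(list(size = 10, r_noninv = 0.9,
                                                  r_inv = 0.1)),
                      seed = s)
    sim <- simulate_expression(cfg)
    block <- sim$truth$planted_module_members[[1]]
    e <- phenotype_edges(sim$expression[block, ], sim$metadata, "non-invasive")
    mean(e$coexpressed)
  })
  expect_true(all(frac >= 0.6))
  expect_gte(mean(frac), 0.85)

  # unattainable threshold: no edges on noisy data
  sim <- simulate_expression(sim_config(n_genes = 20, seed = 1))
  e1 <- phenotype_edges(sim$expression, sim$metadata, "non-invasive",
                        r_min = 1.0)
  expect_equal(sum(e1$coexpressed), 0)
  expect_error(phenotype_edges(sim$expression, sim$metadata[1:10, ],
                               "non-invasive"),
               "at least 4 samples")
})

test_that("differential ratio follows the arithmetic rule and its policies", {
  edges <- tibble::tibble(gene_a = c("a", "a", "a"), gene_b = c("b", "c", "d"),
                          r_inv = c(0.3, 0.85, 0), r_noninv = c(0.9, 0.85, 0.9))
  out <- differential_filter(edges)
  expect_setequal(out$gene_b, c("b", "d"))       # D = 2 kept; D = 0 dropped
  expect_equal(out$D[out$gene_b == "b"], 2)
  expect_equal(out$D[out$gene_b == "d"], Inf)    # r_inv = 0 policy

  # symmetric in gene order, not in phenotype order
  swapped <- tibble::tibble(gene_a = edges$gene_b, gene_b = edges$gene_a,
                            r_inv = edges$r_inv, r_noninv = edges$r_noninv)
  expect_equal(differential_filter(swapped)$D, out$D)
  flipped <- tibble::tibble(gene_a = edges$gene_a, gene_b = edges$gene_b,
                            r_inv = edges$r_noninv, r_noninv = edges$r_inv)
  expect_false(identical(sort(differential_filter(flipped)$gene_b),
                         sort(out$gene_b)))
})

test_that("network membership needs own-phenotype co-expression AND change", {
  cfg <- sim_config(n_genes = 40,
                    planted_modules = list(list(size = 8, r_noninv = 0.9,
                                                r_inv = 0.1)),
                    seed = 2)
  sim <- simulate_expression(cfg)
  block <- sim$truth$planted_module_members[[1]]
  edges <- coexpression_edges(sim$expression, sim$metadata)
  non <- build_network(edges, "non-invasive")
  inv <- build_network(edges, "invasive")
  block_pairs <- function(net)
    sum(net$edges$gene_a %in% block & net$edges$gene_b %in% block)
  expect_gt(block_pairs(non), 20)   # block lights up in its active phenotype
  expect_equal(block_pairs(inv), 0) # and not in the other

  # no pair passing gives an empty network
  e0 <- edges
  e0$coexpressed_inv <- FALSE
  empty <- build_network(e0, "invasive")
  expect_equal(igraph::vcount(empty$graph), 0)
  expect_equal(nrow(tidy(empty)), 0)

  # canonicalization: shuffled input rows give an identical network
  shuffled <- edges[sample(nrow(edges)), ]
  net2 <- build_network(shuffled, "non-invasive")
  expect_identical(tidy(non), tidy(net2))
  expect_true(all(non$edges$gene_a < non$edges$gene_b))
})

test_that("null data yields almost no surviving edges", {
  sim <- simulate_expression(sim_config(n_genes = 200, seed = 4))
  edges <- coexpression_edges(sim$expression, sim$metadata)
  surviving <- nrow(build_network(edges, "non-invasive")$edges) +
    nrow(build_network(edges, "invasive")$edges)
  expect_lte(surviving, 0.01 * nrow(edges))
})

test_that("topology metrics match closed-form values on canonical graphs", {
  star <- igraph::make_star(6, mode = "undirected")
  igraph::V(star)$name <- paste0("s", 1:6)
  ts <- topology_metrics(star)
  expect_equal(ts$network$centralization, 1)

  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$name <- c("a", "b", "c")
  expect_equal(topology_metrics(tri)$network$clustering_coefficient, 1)

  path <- igraph::make_graph(~ a - b, b - c)
  tp <- topology_metrics(path)
  expect_equal(tp$nodes$betweenness[tp$nodes$gene == "b"], 1)
  expect_equal(sum(tp$nodes$betweenness), 1)

  two <- igraph::make_graph(~ x - y)
  expect_true(is.na(topology_metrics(two)$network$centralization))
})

test_that("hub ranking uses degree, then betweenness, then gene id", {
  star <- igraph::make_star(6, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("center", paste0("leaf", 1:5))
  expect_equal(hub_genes(star, k = 1)$gene, "center")
  expect_equal(nrow(hub_genes(star, k = 99)), 6)  # k beyond node count

  # two nodes of equal degree: higher betweenness first
  g <- igraph::make_graph(~ a - b, b - c, c - d, d - e, c - f)
  hubs <- hub_genes(g, k = 2)
  expect_equal(hubs$gene[1], "c")

  # random graph: equals a brute-force sort oracle
  set.seed(5)
  rg <- random_graph(25, 0.15)
  got <- hub_genes(rg, k = 8)
  deg <- igraph::degree(rg)
  btw <- igraph::betweenness(rg, directed = FALSE)
  oracle <- names(deg)[order(-deg, -btw, names(deg))][1:8]
  expect_equal(got$gene, oracle)
})

test_that("network summaries surface through glance", {
  cfg <- sim_config(n_genes = 40,
                    planted_modules = list(list(size = 8, r_noninv = 0.9,
                                                r_inv = 0.1)),
                    seed = 6)
  sim <- simulate_expression(cfg)
  net <- build_network(coexpression_edges(sim$expression, sim$metadata),
                       "non-invasive")
  g <- glance(net)
  expect_equal(g$phenotype, "non-invasive")
  expect_equal(g$n_edges, nrow(net$edges))
  expect_true(g$clustering_coefficient >= 0 && g$clustering_coefficient <= 1)
})
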