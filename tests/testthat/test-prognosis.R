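test_that("patient clustering recovers separated clouds deterministically", {
  set.seed(31)
  # three clouds along one dominant axis
  m <- cbind(matrix(rnorm(30, 0, .5), 2), matrix(rnorm(30, 10, .5), 2),
             matrix(rnorm(30, 20, .5), 2))
  rownames(m) <- c("g1", "g2"); colnames(m) <- paste0("s", 1:45)
  pr <- pca_project(m, rownames(m))
  cl <- cluster_patients(pr, k = 3, n_components = 2, seed = 5)
  truth <- rep(1:3, each = 15)
  expect_equal(cl$cluster, truth)  # relabeled by increasing mean PC1

  expect_identical(cl, cluster_patients(pr, k = 3, n_components = 2, seed = 5))
  expect_equal(unique(cluster_patients(pr, k = 1)$cluster), 1L)
  expect_error(cluster_patients(pr, k = 46), "exceeds")
})

test_that("Kaplan-Meier estimates equal hand-computed product limits", {
  two <- data.frame(time = c(5, 10), event = c(TRUE, TRUE))
  km <- kaplan_meier(two)
  expect_equal(km$survival[km$time == 5], 0.5)
  expect_equal(km$survival[km$time == 10], 0)

  none <- data.frame(time = c(2, 4, 9), event = FALSE)
  expect_true(all(kaplan_meier(none)$survival == 1))

  mix <- data.frame(time = c(2, 4, 6), event = c(TRUE, FALSE, TRUE))
  km3 <- kaplan_meier(mix)
  expect_equal(km3$survival[km3$time == 2], 2 / 3)
  expect_equal(km3$survival[km3$time == 6], 0)

  expect_error(kaplan_meier(data.frame(time = c(-1, 2), event = TRUE)),
               "> 0")
})

test_that("uncensored KM equals the empirical survival function", {
  set.seed(32)
  for (i in 1:5) {
    t_obs <- round(rexp(30, 0.2) + 0.1, 2)
    km <- kaplan_meier(data.frame(time = t_obs, event = TRUE))
    for (j in seq_len(nrow(km)))
      expect_equal(km$survival[j], mean(t_obs > km$time[j]))
  }
})

test_that("log-rank matches a hand-computed O-E table and the null", {
  # identical groups: statistic 0, p 1
  rec <- data.frame(time = rep(c(1, 2, 3), 2), event = TRUE,
                    group = rep(c("a", "b"), each = 3))
  lr0 <- log_rank_test(rec)
  expect_equal(lr0$chi_square, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1)
  # invariant to permuting the labels of identical groups
  rec2 <- rec; rec2$group <- rev(rec2$group)
  expect_equal(log_rank_test(rec2), lr0)

  # 6-subject fixture, hand O-E: O_A = 2, E_A = 1.4, V = 0.74
  fix <- data.frame(time = c(1, 3, 5, 2, 4, 6),
                    event = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE),
                    group = rep(c("A", "B"), each = 3))
  lr <- log_rank_test(fix)
  expect_equal(lr$chi_square, (2 - 1.4)^2 / 0.74, tolerance = 1e-10)
  expect_equal(lr$df, 1)

  expect_error(log_rank_test(within(fix, event <- FALSE)), "one event")
  expect_error(log_rank_test(within(fix, group <- "A")), "2 groups")
})

test_that("log-rank p agrees with a label-permutation null", {
  set.seed(33)
  n <- 40
  rec <- data.frame(time = rexp(n, 0.2) + 0.01,
                    event = runif(n) < 0.7,
                    group = rep(c("a", "b"), each = n / 2))
  p_an <- log_rank_test(rec)$p
  obs <- log_rank_test(rec)$chi_square
  p_perm <- mean(replicate(2000, {
    shuf <- rec; shuf$group <- sample(shuf$group)
    log_rank_test(shuf)$chi_square >= obs - 1e-12
  }))
  expect_lt(abs(p_an - p_perm), 0.05)
})

test_that("Cox fits are unbiased under the null and recover a true HR", {
  set.seed(34)
  # null: covariate independent of survival
  small_beta <- replicate(100, {
    n <- 500
    x <- rnorm(n)
    rec <- data.frame(time = rexp(n, 0.2), event = runif(n) < 0.8)
    abs(cox_ph(rec, x)$beta) < 0.2
  })
  expect_gte(sum(small_beta), 90)

  # true HR = 3: point estimate near truth, CI usually covers
  covered <- replicate(20, {
    n <- 500
    x <- rep(0:1, each = n)
    t_ev <- rexp(2 * n, rate = 0.1 * 3^x)
    cens <- runif(2 * n, 3, 10.5)
    rec <- data.frame(time = pmin(t_ev, cens), event = t_ev <= cens)
    fit <- cox_ph(rec, x)
    fit$ci_lower <= 3 && 3 <= fit$ci_upper
  })
  expect_gte(sum(covered), 16)

  rec <- data.frame(time = 1:4, event = TRUE)
  expect_error(cox_ph(rec, rep(1, 4)), "constant")
})

test_that("signature risk split behaves under null and loaded signals", {
  set.seed(35)
  # loaded signature: genes carry the latent risk, true HR = 3
  cfg <- sim_config(true_hr = 3, event_rate_baseline = 0.25, seed = 35)
  risk <- rep(c("high", "low"), c(22, 18))
  surv <- simulate_survival(risk, cfg)
  sig <- t(sapply(1:4, function(i) (risk == "high") * 2 + rnorm(40, sd = 0.5)))
  rownames(sig) <- paste0("sig", 1:4)
  colnames(sig) <- sprintf("P%02d", 1:40)
  rec <- tibble::tibble(sample_id = colnames(sig), time = surv$time,
                        event = surv$event)
  res <- signature_risk_assessment(sig, rownames(sig), rec)
  expect_s3_class(res, "prognosis_result")
  expect_gt(glance(res)$hr, 1)
  # stochastic dominance: high-risk KM curve never above the low-risk curve
  km <- res$km
  s_at <- function(g, t) {
    kk <- km[km$group == g & km$time <= t + 1e-12, ]
    if (nrow(kk) == 0) 1 else min(kk$survival)
  }
  for (t in sort(unique(km$time[km$n_event > 0])))
    expect_lte(s_at("high", t), s_at("low", t) + 1e-12)

  # absent genes are reported, fit proceeds on the rest
  expect_warning(
    signature_risk_assessment(sig, c(rownames(sig), "ghost"), rec),
    "ghost")
  expect_error(suppressWarnings(
    signature_risk_assessment(sig, c("sig1", "ghost"), rec)),
    "fewer than 2")
})

test_that("a survival-orthogonal signature rarely yields a confident split", {
  set.seed(36)
  cfg <- sim_config(true_hr = 1, event_rate_baseline = 0.2, seed = 36)
  contains_1 <- replicate(100, {
    surv <- simulate_survival(rep(c("high", "low"), c(22, 18)), cfg)
    sig <- matrix(rnorm(3 * 40), 3,
                  dimnames = list(paste0("n", 1:3), sprintf("P%02d", 1:40)))
    rec <- tibble::tibble(sample_id = colnames(sig), time = surv$time,
                          event = surv$event)
    g <- glance(signature_risk_assessment(sig, rownames(sig), rec))
    g$ci_lower <= 1 && 1 <= g$ci_upper
  })
  expect_gte(sum(contains_1), 80)
})

test_that("single-marker group comparison matches the textbook t", {
  m <- rbind(mk = c(1, 2, 3, 4, 5, 6), other = rep(1, 6))
  colnames(m) <- paste0("s", 1:6)
  md <- split_metadata(m, 3)
  res <- marker_group_test(m, md, "mk")
  # Welch statistic by hand: means 2 and 5, each variance 1, n = 3
  se2 <- 1 / 3 + 1 / 3
  t_hand <- (2 - 5) / sqrt(se2)
  df_hand <- se2^2 / ((1 / 3)^2 / 2 + (1 / 3)^2 / 2)
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-12)
  expect_equal(res$mean_invasive, 2)
  expect_equal(res$se_noninvasive, 1 / sqrt(3))

  expect_equal(marker_group_test(m, md, "other")$p, 1)
  expect_error(marker_group_test(m, md, "absent"), "not present")
})
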