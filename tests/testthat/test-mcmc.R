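balanced_records <- function(n_per_cluster = 10, n_clusters = 4) {
  # exactly half problems in every cluster: pooled prevalence is exactly 0.5
  tibble::tibble(
    woman_id = sprintf("w%03d", seq_len(n_per_cluster * n_clusters)),
    cluster_id = rep(sprintf("S01D01C%03d", seq_len(n_clusters)),
                     each = n_per_cluster),
    district_id = "S01D01", state_id = "S01", round = "baseline",
    residence = "rural", weight = 1,
    y_afford = rep(rep(0:1, each = n_per_cluster / 2), n_clusters),
    y_prox = 0L, y_perm = 0L, y_support = 1L)
}

test_that("start values sit at the pooled logit with floored variances", {
  rec <- balanced_records()
  start <- fit_initial(rec, "afford")
  expect_equal(start$beta0, 0)
  # identical clusters: no between-group variation anywhere, so every level
  # variance start lands on the 1e-4 floor
  expect_equal(unname(start$sigma2),
               c(1e-4, 1e-4, 1e-4))
  expect_error(fit_initial(rec, "prox"), "degenerate")
  expect_error(fit_initial(rec, "support"), "degenerate")
})

test_that("method-of-moments start recovers the cluster variance", {
  rel_err <- sapply(1:3, function(s) {
    cfg <- pahc_config(n_states = 1, districts_per_state = 1,
                       clusters_per_district = 50, women_per_cluster = 200,
                       beta0 = rep(0, 4), sigma2_state = 0,
                       sigma2_district = 0, sigma2_cluster = 0.8,
                       outcome_coupling = 0, seed = 100 + s)
    rec <- simulate_round(cfg)
    start <- fit_initial(rec, "afford")
    abs(start$sigma2[["cluster"]] - 0.8) / 0.8
  })
  expect_lt(mean(rel_err), 0.5)
})

test_that("the sampler collapses to the pooled model when effects vanish", {
  cfg <- pahc_config(n_states = 2, districts_per_state = 2,
                     clusters_per_district = 6, women_per_cluster = 40,
                     beta0 = rep(qlogis(0.35), 4), sigma2_state = 0,
                     sigma2_district = 0, sigma2_cluster = 0,
                     outcome_coupling = 0, seed = 9)
  rec <- simulate_round(cfg)
  fit <- fit_pahc(rec, "afford",
                  fast_control(seed = 1, n_monitored = 2000,
                               fix_variances = c(cluster = 1e-4,
                                                 district = 1e-4,
                                                 state = 1e-4)))
  p_pool <- mean(rec$y_afford)
  p_draws <- plogis(fit$beta0_draws)
  expect_lt(abs(mean(p_draws) - p_pool), 2 * stats::sd(p_draws) + 1e-3)
})

test_that("posterior-mean residuals centre near zero at every level", {
  rec <- simulate_round(small_cfg(seed = 23, sigma2_state = 0.3,
                                  sigma2_cluster = 0.4))
  fit <- fit_pahc(rec, "afford", fast_control(seed = 3))
  means <- dplyr::summarise(dplyr::group_by(fit$residuals, level),
                            m = mean(mean))
  expect_true(all(abs(means$m) < 0.05 + 0.15))  # slack for the state level
  expect_lt(abs(means$m[means$level == "cluster"]), 0.05)
})

test_that("small clusters are shrunk harder than large ones", {
  set.seed(8)
  probs <- plogis(rnorm(20, 0, 0.7))
  sizes <- c(rep(15, 10), rep(150, 10))
  rec <- make_records(sizes, probs, seed = 88)
  fit <- fit_pahc(rec, "afford", fast_control(seed = 4))
  cl <- dplyr::summarise(dplyr::group_by(rec, cluster_id),
                         y = sum(y_afford), n = dplyr::n())
  # raw deviation measured from the fitted centre (intercept + state +
  # district), which is what the cluster residual is a deviation from
  centre <- mean(fit$beta0_draws) +
    sum(fit$residuals$mean[fit$residuals$level != "cluster"])
  raw_dev <- qlogis((cl$y + 0.5) / (cl$n + 1)) - centre
  post <- fit$residuals[fit$residuals$level == "cluster", ]
  post <- post$mean[match(cl$cluster_id, post$unit_id)]
  shrink <- abs(post) / pmax(abs(raw_dev), 1e-8)
  # every posterior mean is pulled toward zero relative to the raw deviation
  expect_true(all(abs(post) <= abs(raw_dev) + 0.05))
  # and the pull is stronger where there are fewer observations
  expect_lt(mean(shrink[cl$n == 15]), mean(shrink[cl$n == 150]))
})

test_that("results attach to the data, not to unit labels", {
  rec <- simulate_round(small_cfg(seed = 55))
  # order-preserving relabel of every cluster
  relabel <- function(x) paste0(x, "x")
  rec2 <- dplyr::mutate(rec, cluster_id = relabel(cluster_id))
  f1 <- fit_pahc(rec, "prox", fast_control(seed = 6, n_monitored = 500))
  f2 <- fit_pahc(rec2, "prox", fast_control(seed = 6, n_monitored = 500))
  r1 <- f1$residuals[f1$residuals$level == "cluster", ]
  r2 <- f2$residuals[f2$residuals$level == "cluster", ]
  expect_identical(relabel(r1$unit_id), r2$unit_id)
  expect_identical(r1$mean, r2$mean)
  expect_identical(f1$beta0_draws, f2$beta0_draws)
})

test_that("doubling the monitored chain does not move the posterior", {
  rec <- simulate_round(small_cfg(seed = 77, sigma2_cluster = 0.4))
  f1 <- fit_pahc(rec, "afford",
                 fast_control(seed = 10, n_monitored = 1500))
  f2 <- fit_pahc(rec, "afford",
                 fast_control(seed = 11, n_monitored = 3000))
  t1 <- tidy(f1)
  t2 <- tidy(f2)
  for (term in t1$term) {
    a <- t1[t1$term == term, ]
    b <- t2[t2$term == term, ]
    mcse <- a$std.error / sqrt(a$ess) + b$std.error / sqrt(b$ess)
    expect_lt(abs(a$estimate - b$estimate), 4 * mcse)
  }
})

test_that("chains are reproducible and have the declared shape", {
  rec <- simulate_round(small_cfg(seed = 5))
  ctl <- fast_control(seed = 12, n_monitored = 600, thin = 3)
  f1 <- fit_pahc(rec, "perm", ctl)
  f2 <- fit_pahc(rec, "perm", ctl)
  expect_identical(f1$beta0_draws, f2$beta0_draws)
  expect_identical(f1$residuals, f2$residuals)
  expect_length(f1$beta0_draws, 200)
  expect_true(all(as.matrix(f1$sigma2_draws) > 0))
  # one residual summary per unit at each level
  counts <- table(f1$residuals$level)
  expect_equal(unname(counts[c("cluster", "district", "state")]),
               c(4 * 3 * 4, 4 * 3, 4), ignore_attr = TRUE)
})

test_that("ESS follows the iid and AR(1) sampling behaviour", {
  ess_iid <- sapply(1:10, function(s) {
    set.seed(s)
    as.numeric(ess(rnorm(5000)))
  })
  expect_true(all(ess_iid >= 3500 & ess_iid <= 5000))
  expect_gt(mean(ess_iid), 4000)

  closed_form <- 5000 * (1 - 0.9) / (1 + 0.9)  # ~263
  ess_ar <- sapply(1:5, function(s) as.numeric(ess(ar1_chain(5000, 0.9, s))))
  expect_true(all(ess_ar > closed_form / 2 & ess_ar < closed_form * 2))
})

test_that("a constant chain reports full length with a zero-variance flag", {
  e <- ess(rep(2.5, 100))
  expect_equal(as.numeric(e), 100)
  expect_true(attr(e, "zero_variance"))
  expect_error(ess(rnorm(5)), "length")
})

test_that("tidy and glance expose the fit summary", {
  rec <- simulate_round(small_cfg(seed = 6))
  fit <- fit_pahc(rec, "support", fast_control(seed = 14, n_monitored = 500))
  td <- tidy(fit)
  expect_setequal(td$term, c("beta0", "sigma2_cluster", "sigma2_district",
                             "sigma2_state"))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  gl <- glance(fit)
  expect_equal(gl$n_records, nrow(rec))
  expect_equal(gl$n_clusters, 48)
})
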