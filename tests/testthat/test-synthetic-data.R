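test_that("config validation rejects impossible populations", {
  expect_error(pahc_config(n_states = 0, seed = 1), "counts")
  expect_error(pahc_config(sigma2_state = -0.1, seed = 1), "sigma2_state")
  expect_error(pahc_config(outcome_coupling = 1.5, seed = 1),
               "outcome_coupling")
  expect_error(pahc_config(seed = NULL), "seed")
})

test_that("generated records respect the nesting and weight contract", {
  rec <- simulate_round(small_cfg(seed = 21), "baseline")
  expect_s3_class(validate_records(rec), "tbl_df")
  expect_true(all(rec$weight > 0))
  expect_equal(mean(rec$weight), 1, tolerance = 1e-12)
  # residence is a cluster-level attribute
  per_cluster <- dplyr::n_distinct(
    dplyr::distinct(rec, cluster_id, residence)$cluster_id)
  expect_equal(per_cluster, dplyr::n_distinct(rec$cluster_id))
})

test_that("a fixed seed reproduces the record set byte-identically", {
  cfg <- small_cfg(seed = 99)
  a <- simulate_round(cfg, "endline")
  b <- simulate_round(cfg, "endline")
  attr(a, "ground_truth") <- attr(b, "ground_truth") <- NULL
  expect_identical(a, b)
  c <- simulate_round(small_cfg(seed = 100), "endline")
  expect_false(identical(a$y_afford, c$y_afford))
})

test_that("zero-effects population hits 50% prevalence within 3 SE", {
  cfg <- pahc_config(n_states = 2, districts_per_state = 2,
                     clusters_per_district = 50, women_per_cluster = 50,
                     beta0 = rep(0, 4), sigma2_state = 0, sigma2_district = 0,
                     sigma2_cluster = 0, outcome_coupling = 0, seed = 7)
  rec <- simulate_round(cfg)
  n <- nrow(rec)
  expect_equal(n, 10000)
  se <- sqrt(0.25 / n)
  for (o in pahc_outcomes()) {
    expect_lt(abs(mean(rec[[paste0("y_", o)]]) - 0.5), 3 * se)
  }
})

test_that("empirical prevalence matches the logit-normal quadrature truth", {
  v <- c(state = 0.2, district = 0.1, cluster = 0.3)
  b0 <- 0.4
  cfg <- pahc_config(n_states = 10, districts_per_state = 5,
                     clusters_per_district = 20, women_per_cluster = 30,
                     beta0 = rep(b0, 4), sigma2_state = v[["state"]],
                     sigma2_district = v[["district"]],
                     sigma2_cluster = v[["cluster"]],
                     outcome_coupling = 0, seed = 31)
  rec <- simulate_round(cfg)
  truth <- integrated_prevalence(b0, sum(v))
  p_cl <- tapply(rec$y_afford, rec$cluster_id, mean)
  se <- stats::sd(p_cl) / sqrt(length(p_cl))
  expect_lt(abs(mean(rec$y_afford) - truth), 3 * se)
})

test_that("national affordability margin is emulated at the published level", {
  # intercept at logit(0.5475) with small level variances reproduces the
  # 54.75% any-problem affordability share up to logit-normal attenuation
  cfg <- pahc_config(n_states = 20, districts_per_state = 10,
                     clusters_per_district = 20, women_per_cluster = 30,
                     beta0 = rep(qlogis(0.5475), 4),
                     sigma2_state = 0.05, sigma2_district = 0.05,
                     sigma2_cluster = 0.05, outcome_coupling = 0, seed = 17)
  rec <- simulate_round(cfg)
  truth <- integrated_prevalence(qlogis(0.5475), 0.15)
  p_cl <- tapply(rec$y_afford, rec$cluster_id, mean)
  se <- stats::sd(p_cl) / sqrt(length(p_cl))
  expect_lt(abs(mean(rec$y_afford) - truth), 3 * se)
  expect_lt(abs(100 * mean(rec$y_afford) - 54.75), 1.0)
})

test_that("method-of-moments on cluster log-odds recovers the total variance", {
  v <- c(state = 0.15, district = 0.1, cluster = 0.4)
  cfg <- pahc_config(n_states = 8, districts_per_state = 5,
                     clusters_per_district = 15, women_per_cluster = 100,
                     beta0 = rep(0, 4), sigma2_state = v[["state"]],
                     sigma2_district = v[["district"]],
                     sigma2_cluster = v[["cluster"]],
                     outcome_coupling = 0, seed = 13)
  rec <- simulate_round(cfg)
  cl <- dplyr::summarise(dplyr::group_by(rec, cluster_id),
                         y = sum(y_afford), n = dplyr::n())
  lo <- qlogis((cl$y + 0.5) / (cl$n + 1))
  samp <- mean(1 / (cl$y + 0.5) + 1 / (cl$n - cl$y + 0.5))
  expect_equal(stats::var(lo) - samp, sum(v), tolerance = 0.35)
})

test_that("outcome coupling induces positive cross-outcome dependence", {
  base <- list(n_states = 4, districts_per_state = 3,
               clusters_per_district = 10, women_per_cluster = 50,
               beta0 = rep(0, 4), sigma2_state = 0, sigma2_district = 0,
               sigma2_cluster = 0, seed = 5)
  ind <- simulate_round(do.call(pahc_config,
                                c(base, list(outcome_coupling = 0))))
  dep <- simulate_round(do.call(pahc_config,
                                c(base, list(outcome_coupling = 1))))
  expect_lt(abs(stats::cor(ind$y_afford, ind$y_prox)), 0.05)
  expect_gt(stats::cor(dep$y_afford, dep$y_prox), 0.1)
})

test_that("panel generation builds a refinement-only crosswalk", {
  cfg_b <- small_cfg(seed = 61)
  cfg_e <- small_cfg(seed = 62)
  n_clusters <- 4 * 3 * 4
  drop3 <- c("S01D01C001", "S02D02C003", "S04D03C002")
  panel <- simulate_panel(cfg_b, cfg_e,
                          boundary_scenario(split_districts = "S01D02",
                                            drop_clusters = drop3))
  cw <- panel$crosswalk
  expect_equal(nrow(cw), n_clusters)
  expect_equal(sum(cw$action == "drop"), 3)
  expect_setequal(cw$cluster_id[cw$action == "drop"], drop3)
  # the split district maps onto exactly two new districts
  split_dest <- unique(cw$new_district_id[cw$old_district_id == "S01D02" &
                                            cw$action == "map"])
  expect_setequal(split_dest, c("S01D02a", "S01D02b"))
  # endline geometry matches the crosswalk's destination set
  expect_true(all(unique(panel$endline$district_id) %in%
                    c(setdiff(unique(panel$baseline$district_id), "S01D02"),
                      "S01D02a", "S01D02b")))
  expect_error(
    simulate_panel(cfg_b, cfg_e,
                   boundary_scenario(split_districts = "S09D99")),
    "unknown district")
})

test_that("a zero-change scenario yields the identity crosswalk", {
  cfg <- small_cfg(seed = 71)
  panel <- simulate_panel(cfg, small_cfg(seed = 72))
  expect_true(all(panel$crosswalk$action == "map"))
  expect_identical(panel$crosswalk$new_district_id,
                   panel$crosswalk$old_district_id)
  mapped <- apply_crosswalk(panel$baseline, panel$crosswalk)
  expect_equal(nrow(mapped), nrow(panel$baseline))
})

test_that("fractional cluster drops survive round-trip accounting", {
  cfg_b <- pahc_config(n_states = 6, districts_per_state = 6,
                       clusters_per_district = 15, women_per_cluster = 13,
                       seed = 81)
  cfg_e <- pahc_config(n_states = 6, districts_per_state = 6,
                       clusters_per_district = 15, women_per_cluster = 13,
                       seed = 82)
  panel <- simulate_panel(cfg_b, cfg_e,
                          boundary_scenario(drop_fraction = 0.0019))
  mapped <- apply_crosswalk(panel$baseline, panel$crosswalk)
  rep <- crosswalk_report(mapped)
  expect_equal(rep$n_input_records,
               rep$n_retained_records + rep$n_dropped_records)
  n_dropped_clusters <- sum(panel$crosswalk$action == "drop")
  expect_equal(n_dropped_clusters,
               round(0.0019 * dplyr::n_distinct(panel$baseline$cluster_id)))
  expect_equal(rep$n_dropped_records, n_dropped_clusters * 13)
})
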