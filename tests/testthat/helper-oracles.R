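# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

# population prevalence implied by a logit-normal mixture:
# E[expit(b0 + Z)], Z ~ N(0, v_total), by adaptive quadrature
integrated_prevalence <- function(beta0, v_total) {
  if (v_total == 0) return(plogis(beta0))
  stats::integrate(function(z) {
    plogis(beta0 + z) * stats::dnorm(z, 0, sqrt(v_total))
  }, -Inf, Inf, rel.tol = 1e-10)$value
}

# posterior mean of the intercept for a tiny two-cluster model with fixed
# variances, by dense grid quadrature. The state and district effects enter
# the likelihood only through their sum u ~ N(0, v_state + v_district), so
# the integral is over (beta0, u, c1, c2) with the cluster dimensions
# collapsed by one-dimensional quadrature each.
quadrature_beta0_mean <- function(y, n, v_cluster, v_u, prior_var_beta0) {
  bgrid <- seq(-8, 8, length.out = 321)
  ugrid <- seq(-5 * sqrt(v_u), 5 * sqrt(v_u), length.out = 201)
  cgrid <- seq(-5 * sqrt(v_cluster), 5 * sqrt(v_cluster), length.out = 201)
  wc <- stats::dnorm(cgrid, 0, sqrt(v_cluster))
  wc <- wc / sum(wc)
  t_mat <- outer(bgrid, ugrid, "+")
  lik <- matrix(1, nrow(t_mat), ncol(t_mat))
  for (j in seq_along(y)) {
    fj <- matrix(0, nrow(t_mat), ncol(t_mat))
    for (ci in seq_along(cgrid)) {
      eta <- t_mat + cgrid[ci]
      fj <- fj + wc[ci] * exp(y[j] * eta - n[j] * log1p(exp(eta)))
    }
    lik <- lik * fj
  }
  wb <- stats::dnorm(bgrid, 0, sqrt(prior_var_beta0))
  wu <- stats::dnorm(ugrid, 0, sqrt(v_u))
  post <- lik * (wb %o% wu)
  sum(bgrid * rowSums(post)) / sum(post)
}

ar1_chain <- function(n, rho, seed) {
  set.seed(seed)
  x <- numeric(n)
  x[1] <- rnorm(1)
  for (t in 2:n) x[t] <- rho * x[t - 1] + rnorm(1, 0, sqrt(1 - rho^2))
  x
}

# hand-built single-state, single-district records with given cluster sizes
# and per-cluster success probabilities
make_records <- function(sizes, probs, seed = 1, round = "baseline") {
  set.seed(seed)
  n_c <- length(sizes)
  cluster_id <- sprintf("S01D01C%03d", seq_len(n_c))
  rows <- purrr::map2_dfr(seq_len(n_c), sizes, function(j, nj) {
    tibble::tibble(cluster_id = cluster_id[j],
                   y = rbinom(nj, 1L, probs[j]))
  })
  tibble::tibble(
    woman_id = sprintf("w%05d", seq_len(nrow(rows))),
    cluster_id = rows$cluster_id,
    district_id = "S01D01",
    state_id = "S01",
    round = round,
    residence = "rural",
    weight = 1,
    y_afford = rows$y, y_prox = rows$y, y_perm = rows$y, y_support = rows$y)
}

small_cfg <- function(seed, ...) {
  args <- utils::modifyList(
    list(n_states = 4, districts_per_state = 3, clusters_per_district = 4,
         women_per_cluster = 25, seed = seed),
    list(...))
  do.call(pahc_config, args)
}

fast_control <- function(seed, ...) {
  args <- utils::modifyList(
    list(burn_in = 200, n_monitored = 1000, seed = seed), list(...))
  do.call(mcmc_control, args)
}
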