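#' MCMC settings for the four-level model
#'
#' Tuning and prior settings for [fit_pahc()]. The defaults follow the
#' common multilevel-MCMC protocol for this model class: a 500-iteration
#' burn-in, 5,000 monitored iterations of a single chain, a diffuse
#' Normal(0, 1e6) prior on the intercept and inverse-gamma(0.001, 0.001)
#' priors on the three random-intercept variances, with quasi-likelihood
#' (method-of-moments) starting values supplied by [fit_initial()].
#'
#' @param burn_in Burn-in iterations discarded before monitoring.
#' @param n_monitored Monitored iterations; stored chain length is
#'   `n_monitored / thin`.
#' @param thin Keep every `thin`-th monitored draw.
#' @param seed Integer seed making the chain reproducible.
#' @param proposal_sd_init Initial random-walk proposal standard deviation
#'   for the intercept and every residual block.
#' @param adapt Adapt each proposal scale toward 44% acceptance during
#'   burn-in (frozen afterwards, so the monitored chain is a fixed kernel).
#' @param intercept_prior_var Variance of the Normal(0, .) intercept prior.
#' @param variance_prior_shape,variance_prior_scale Shape/scale of the
#'   inverse-gamma prior on each level variance.
#' @param fix_variances Optional named vector (names among
#'   `cluster`, `district`, `state`) pinning those variances at fixed values
#'   instead of sampling them — mainly for validation against numerical
#'   integration on tiny models.
#' @param variance_floor Lower bound applied to sampled variances to avoid
#'   numerical collapse of a level.
#' @return An object of class `pahc_control` (a validated list).
#' @export
mcmc_control <- function(burn_in = 500,
                         n_monitored = 5000,
                         thin = 1,
                         seed = 1,
                         proposal_sd_init = 0.4,
                         adapt = TRUE,
                         intercept_prior_var = 1e6,
                         variance_prior_shape = 0.001,
                         variance_prior_scale = 0.001,
                         fix_variances = NULL,
                         variance_floor = 1e-6) {
  if (burn_in < 0) abort("burn_in must be >= 0")
  if (n_monitored < 1) abort("n_monitored must be >= 1")
  if (thin < 1 || n_monitored %% thin != 0) {
    abort("thin must be a positive divisor of n_monitored")
  }
  if (proposal_sd_init <= 0) abort("proposal_sd_init must be positive")
  if (intercept_prior_var <= 0 || variance_prior_shape <= 0 ||
      variance_prior_scale <= 0) {
    abort("priors must be proper: positive variance/shape/scale")
  }
  if (!is.null(fix_variances)) {
    bad <- setdiff(names(fix_variances), c("cluster", "district", "state"))
    if (length(bad) > 0 || is.null(names(fix_variances))) {
      abort("fix_variances must be named with cluster/district/state")
    }
    if (any(fix_variances <= 0)) abort("fixed variances must be positive")
  }
  structure(list(burn_in = as.integer(burn_in),
                 n_monitored = as.integer(n_monitored),
                 thin = as.integer(thin),
                 seed = as.integer(seed),
                 proposal_sd_init = proposal_sd_init,
                 adapt = isTRUE(adapt),
                 intercept_prior_var = intercept_prior_var,
                 variance_prior_shape = variance_prior_shape,
                 variance_prior_scale = variance_prior_scale,
                 fix_variances = fix_variances,
                 variance_floor = variance_floor),
            class = "pahc_control")
}

# Per-cluster sufficient statistics: with an intercept-only linear predictor
# the likelihood depends on the data only through (#problems, #women) per
# cluster, so the sampler never touches unit records after this step.
cluster_stats <- function(records, outcome) {
  col <- outcome_col(outcome)
  if (dplyr::n_distinct(records$round) > 1) {
    abort("records span multiple rounds; fit one round at a time")
  }
  y <- records[[col]]
  if (!all(y %in% c(0, 1))) abort(sprintf("outcome %s is not binary", col))
  cl <- records |>
    dplyr::group_by(.data$state_id, .data$district_id, .data$cluster_id) |>
    dplyr::summarise(y = sum(.data[[col]]), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::arrange(.data$state_id, .data$district_id, .data$cluster_id)
  if (sum(cl$y) == 0 || sum(cl$y) == sum(cl$n)) {
    abort(sprintf("outcome %s is degenerate (all 0 or all 1)", col))
  }
  cl
}

#' Quasi-likelihood starting values for the four-level model
#'
#' Initializes the chain where the posterior mass plausibly sits: the
#' intercept at the logit of the pooled prevalence (clamped away from 0/1),
#' the three level variances by method-of-moments on empirical group
#' log-odds (cluster-level sampling noise subtracted, all floored at 1e-4),
#' and the residuals at empirical group deviations shrunk halfway to zero.
#'
#' @param records Survey records for a single round.
#' @param outcome One of [pahc_outcomes()].
#' @return A list with `beta0`, `sigma2` (named: cluster, district, state)
#'   and per-level residual start vectors.
#' @export
fit_initial <- function(records, outcome) {
  cl <- cluster_stats(records, outcome)
  if (dplyr::n_distinct(cl$cluster_id) < 2) {
    abort("need at least 2 clusters")
  }
  p_pool <- sum(cl$y) / sum(cl$n)
  beta0 <- qlogis(min(max(p_pool, 1e-3), 1 - 1e-3))

  # empirical log-odds with a half-count continuity correction
  emp_lo <- function(y, n) qlogis((y + 0.5) / (n + 1))
  cl_lo <- emp_lo(cl$y, cl$n)
  di <- cl |>
    dplyr::group_by(.data$state_id, .data$district_id) |>
    dplyr::summarise(y = sum(.data$y), n = sum(.data$n), .groups = "drop")
  st <- di |>
    dplyr::group_by(.data$state_id) |>
    dplyr::summarise(y = sum(.data$y), n = sum(.data$n), .groups = "drop")
  di_lo <- emp_lo(di$y, di$n)
  st_lo <- emp_lo(st$y, st$n)

  st_of_di <- match(di$state_id, st$state_id)
  di_of_cl <- match(cl$district_id, di$district_id)

  s_dev <- st_lo - beta0
  d_dev <- di_lo - st_lo[st_of_di]
  c_dev <- cl_lo - di_lo[di_of_cl]

  var0 <- function(x) if (length(x) < 2) 0 else var(x)
  # binomial sampling variance of a cluster's empirical log-odds
  samp_var <- mean(1 / (cl$y + 0.5) + 1 / (cl$n - cl$y + 0.5))
  sigma2 <- c(cluster = max(var0(c_dev) - samp_var, 1e-4),
              district = max(var0(d_dev), 1e-4),
              state = max(var0(s_dev), 1e-4))

  list(beta0 = beta0,
       sigma2 = sigma2,
       resid_cluster = 0.5 * c_dev,
       resid_district = 0.5 * d_dev,
       resid_state = 0.5 * s_dev,
       cluster_index = cl,
       district_index = di,
       state_index = st)
}

#' Fit the four-level random-intercept Bernoulli-logit model by MCMC
#'
#' Fits, for one outcome in one survey round,
#' \deqn{\mathrm{logit}(P_{ijkl}) = \beta_0 + C_{0jkl} + D_{0kl} + S_{0l}}
#' where woman i sits in cluster j, district k and state l, and the cluster,
#' district and state residuals are Normal with level variances
#' \eqn{\sigma^2_C, \sigma^2_D, \sigma^2_S}. The sampler is
#' Metropolis-within-Gibbs: univariate random-walk Metropolis updates for the
#' intercept and every residual (proposal scales adapted toward 44%
#' acceptance during burn-in only), and conjugate inverse-gamma Gibbs updates
#' for each variance given its residuals. Survey weights deliberately do not
#' enter the likelihood; they are used only in descriptive tabulations.
#'
#' @param records Survey records for a single round (see
#'   [validate_records()]).
#' @param outcome One of [pahc_outcomes()].
#' @param control A [mcmc_control()].
#' @return An object of class `pahc_fit` with monitored chains for the
#'   intercept and the three variances, posterior mean/sd for every cluster,
#'   district and state residual, effective sample sizes, acceptance rates,
#'   the starting values and the control settings. Methods: [tidy()],
#'   [glance()], `print()`, [autoplot.pahc_fit()].
#' @export
#' @examples
#' cfg <- pahc_config(n_states = 3, districts_per_state = 2,
#'                    clusters_per_district = 4, women_per_cluster = 20,
#'                    seed = 11)
#' rec <- simulate_round(cfg)
#' fit <- fit_pahc(rec, "afford",
#'                 mcmc_control(burn_in = 100, n_monitored = 500, seed = 1))
#' tidy(fit)
fit_pahc <- function(records, outcome, control = mcmc_control()) {
  stopifnot(inherits(control, "pahc_control"))
  outcome <- match.arg(outcome, pahc_outcomes())
  start <- fit_initial(records, outcome)
  round_label <- as.character(records$round[1] %||% NA_character_)
  with_seed(control$seed,
            run_sampler(start, outcome, round_label, control,
                        n_records = nrow(records)))
}

run_sampler <- function(start, outcome, round_label, control, n_records) {
  cl <- start$cluster_index
  di <- start$district_index
  st <- start$state_index
  y <- cl$y
  n <- cl$n
  C <- nrow(cl)
  D <- nrow(di)
  S <- nrow(st)
  cl_d <- match(cl$district_id, di$district_id)
  cl_s <- match(cl$state_id, st$state_id)
  d_s <- match(di$state_id, st$state_id)

  b0 <- start$beta0
  rc <- start$resid_cluster
  rd <- start$resid_district
  rs <- start$resid_state
  v <- pmax(start$sigma2, control$variance_floor)
  fixed <- control$fix_variances
  for (lev in names(fixed)) v[lev] <- fixed[[lev]]

  Vb <- control$intercept_prior_var
  pa <- control$variance_prior_shape
  pb <- control$variance_prior_scale
  floor_v <- control$variance_floor

  eta <- b0 + rc + rd[cl_d] + rs[cl_s]
  llc <- y * eta - n * log1pexp(eta)

  sd_b <- control$proposal_sd_init
  sd_c <- rep(control$proposal_sd_init, C)
  sd_d <- rep(control$proposal_sd_init, D)
  sd_s <- rep(control$proposal_sd_init, S)
  acc_b <- 0; acc_c <- numeric(C); acc_d <- numeric(D); acc_s <- numeric(S)
  tot_b <- 0; tot_c <- numeric(C); tot_d <- numeric(D); tot_s <- numeric(S)
  window <- 50L

  n_keep <- control$n_monitored %/% control$thin
  b0_draws <- numeric(n_keep)
  v_draws <- matrix(0, n_keep, 3,
                    dimnames = list(NULL, c("cluster", "district", "state")))
  sum_c <- numeric(C); ssq_c <- numeric(C)
  sum_d <- numeric(D); ssq_d <- numeric(D)
  sum_s <- numeric(S); ssq_s <- numeric(S)
  sum_p <- numeric(C)  # draw-wise posterior mean of expit(eta) per cluster

  n_iter <- control$burn_in + control$n_monitored
  keep_i <- 0L
  win_acc_b <- 0; win_acc_c <- numeric(C)
  win_acc_d <- numeric(D); win_acc_s <- numeric(S)

  for (it in seq_len(n_iter)) {
    in_burn <- it <= control$burn_in

    # intercept: scalar random-walk Metropolis
    delta <- rnorm(1, 0, sd_b)
    eta_new <- eta + delta
    llc_new <- y * eta_new - n * log1pexp(eta_new)
    logr <- sum(llc_new - llc) + (b0^2 - (b0 + delta)^2) / (2 * Vb)
    if (log(runif(1)) < logr) {
      b0 <- b0 + delta; eta <- eta_new; llc <- llc_new
      acc_b <- acc_b + 1; win_acc_b <- win_acc_b + 1
    }
    tot_b <- tot_b + 1

    # cluster residuals: conditionally independent, updated as one vector
    delta <- rnorm(C, 0, sd_c)
    eta_new <- eta + delta
    llc_new <- y * eta_new - n * log1pexp(eta_new)
    logr <- (llc_new - llc) + (rc^2 - (rc + delta)^2) / (2 * v["cluster"])
    acc <- log(runif(C)) < logr
    rc[acc] <- rc[acc] + delta[acc]
    eta[acc] <- eta_new[acc]; llc[acc] <- llc_new[acc]
    acc_c <- acc_c + acc; win_acc_c <- win_acc_c + acc; tot_c <- tot_c + 1

    # district residuals: blockwise via per-district likelihood sums
    deltaD <- rnorm(D, 0, sd_d)
    eta_new <- eta + deltaD[cl_d]
    llc_new <- y * eta_new - n * log1pexp(eta_new)
    dll <- rowsum(llc_new - llc, cl_d, reorder = FALSE)[, 1]
    logr <- dll + (rd^2 - (rd + deltaD)^2) / (2 * v["district"])
    accD <- log(runif(D)) < logr
    rd[accD] <- rd[accD] + deltaD[accD]
    accC <- accD[cl_d]
    eta[accC] <- eta_new[accC]; llc[accC] <- llc_new[accC]
    acc_d <- acc_d + accD; win_acc_d <- win_acc_d + accD; tot_d <- tot_d + 1

    # state residuals
    deltaS <- rnorm(S, 0, sd_s)
    eta_new <- eta + deltaS[cl_s]
    llc_new <- y * eta_new - n * log1pexp(eta_new)
    sll <- rowsum(llc_new - llc, cl_s, reorder = FALSE)[, 1]
    logr <- sll + (rs^2 - (rs + deltaS)^2) / (2 * v["state"])
    accS <- log(runif(S)) < logr
    rs[accS] <- rs[accS] + deltaS[accS]
    accC <- accS[cl_s]
    eta[accC] <- eta_new[accC]; llc[accC] <- llc_new[accC]
    acc_s <- acc_s + accS; win_acc_s <- win_acc_s + accS; tot_s <- tot_s + 1

    # conjugate inverse-gamma Gibbs updates for the level variances
    if (is.null(fixed) || !"cluster" %in% names(fixed)) {
      v["cluster"] <- max(1 / rgamma(1, pa + C / 2, rate = pb + sum(rc^2) / 2),
                          floor_v)
    }
    if (is.null(fixed) || !"district" %in% names(fixed)) {
      v["district"] <- max(1 / rgamma(1, pa + D / 2, rate = pb + sum(rd^2) / 2),
                           floor_v)
    }
    if (is.null(fixed) || !"state" %in% names(fixed)) {
      v["state"] <- max(1 / rgamma(1, pa + S / 2, rate = pb + sum(rs^2) / 2),
                        floor_v)
    }

    # adapt proposal scales toward 44% acceptance, burn-in only
    if (in_burn && control$adapt && it %% window == 0L) {
      f <- function(sdv, accv) {
        rate <- accv / window
        sdv * ifelse(rate > 0.44, 1.2, 1 / 1.2)
      }
      sd_b <- f(sd_b, win_acc_b)
      sd_c <- f(sd_c, win_acc_c)
      sd_d <- f(sd_d, win_acc_d)
      sd_s <- f(sd_s, win_acc_s)
      win_acc_b <- 0; win_acc_c[] <- 0; win_acc_d[] <- 0; win_acc_s[] <- 0
    }

    if (!in_burn && (it - control$burn_in) %% control$thin == 0L) {
      keep_i <- keep_i + 1L
      b0_draws[keep_i] <- b0
      v_draws[keep_i, ] <- v[c("cluster", "district", "state")]
      sum_c <- sum_c + rc; ssq_c <- ssq_c + rc^2
      sum_d <- sum_d + rd; ssq_d <- ssq_d + rd^2
      sum_s <- sum_s + rs; ssq_s <- ssq_s + rs^2
      sum_p <- sum_p + plogis(eta)
    }
  }

  post_sd <- function(s, ss) sqrt(pmax(ss / n_keep - (s / n_keep)^2, 0))
  residuals <- dplyr::bind_rows(
    tibble::tibble(level = "cluster", unit_id = cl$cluster_id,
                   mean = sum_c / n_keep, sd = post_sd(sum_c, ssq_c)),
    tibble::tibble(level = "district", unit_id = di$district_id,
                   mean = sum_d / n_keep, sd = post_sd(sum_d, ssq_d)),
    tibble::tibble(level = "state", unit_id = st$state_id,
                   mean = sum_s / n_keep, sd = post_sd(sum_s, ssq_s)))

  chains <- list(beta0 = b0_draws,
                 sigma2_cluster = v_draws[, "cluster"],
                 sigma2_district = v_draws[, "district"],
                 sigma2_state = v_draws[, "state"])
  ess_tbl <- purrr::map_dfr(names(chains), function(p) {
    e <- ess(chains[[p]])
    tibble::tibble(parameter = p, ess = as.numeric(e),
                   zero_variance = isTRUE(attr(e, "zero_variance")))
  })

  structure(list(
    outcome = outcome,
    round = round_label,
    beta0_draws = b0_draws,
    sigma2_draws = tibble::as_tibble(v_draws),
    residuals = residuals,
    ess = ess_tbl,
    acceptance = tibble::tibble(
      block = c("beta0", "cluster", "district", "state"),
      rate = c(acc_b / tot_b, mean(acc_c / tot_c),
               mean(acc_d / tot_d), mean(acc_s / tot_s))),
    start_values = start[c("beta0", "sigma2")],
    cluster_index = cl |> dplyr::select("cluster_id", "district_id",
                                        "state_id", "y", "n"),
    p_drawwise = sum_p / n_keep,
    control = control,
    n_records = n_records),
    class = "pahc_fit")
}

#' Effective sample size of an MCMC chain
#'
#' Autocorrelation-time ESS using Geyer's initial positive sequence: summed
#' autocorrelations are truncated at the first non-positive pair
#' \eqn{\rho_{2m} + \rho_{2m+1}}. The estimate is capped at the chain length;
#' a constant chain returns the chain length with a `zero_variance`
#' attribute.
#'
#' @param chain Numeric vector of at least 10 monitored draws.
#' @return A single number; attribute `zero_variance` flags degenerate
#'   chains.
#' @export
#' @examples
#' set.seed(1)
#' ess(rnorm(1000))
ess <- function(chain) {
  n_draw <- length(chain)
  if (n_draw < 10) abort("chain must have length >= 10")
  if (!all(is.finite(chain))) abort("chain contains non-finite values")
  if (var(chain) == 0) {
    return(structure(as.numeric(n_draw), zero_variance = TRUE))
  }
  lag_max <- min(n_draw - 1L, 2000L)
  rho <- as.numeric(acf(chain, lag.max = lag_max, plot = FALSE,
                        demean = TRUE)$acf)
  # pair consecutive lags; rho[1] is lag 0
  n_pairs <- (lag_max + 1L) %/% 2L
  gam <- rho[2 * seq_len(n_pairs) - 1] + rho[2 * seq_len(n_pairs)]
  cut <- which(gam <= 0)
  m <- if (length(cut) > 0) cut[1] - 1L else n_pairs
  tau <- -1 + 2 * sum(gam[seq_len(m)])
  tau <- max(tau, 1e-12)
  structure(min(n_draw / tau, n_draw), zero_variance = FALSE)
}

#' @export
print.pahc_fit <- function(x, ...) {
  cat(sprintf("Four-level Bernoulli-logit MCMC fit: outcome '%s', round '%s'\n",
              x$outcome, x$round))
  cat(sprintf("  %d records, %d clusters, %d districts, %d states\n",
              x$n_records, nrow(x$cluster_index),
              dplyr::n_distinct(x$cluster_index$district_id),
              dplyr::n_distinct(x$cluster_index$state_id)))
  cat(sprintf("  chain: burn-in %d, monitored %d (thin %d), seed %d\n",
              x$control$burn_in, x$control$n_monitored, x$control$thin,
              x$control$seed))
  print(tidy(x))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pahc_fit <- function(x, ...) {
  chains <- list(beta0 = x$beta0_draws,
                 sigma2_cluster = x$sigma2_draws$cluster,
                 sigma2_district = x$sigma2_draws$district,
                 sigma2_state = x$sigma2_draws$state)
  tibble::tibble(
    term = names(chains),
    estimate = purrr::map_dbl(chains, mean),
    std.error = purrr::map_dbl(chains, sd),
    conf.low = purrr::map_dbl(chains, ~ quantile(.x, 0.025)),
    conf.high = purrr::map_dbl(chains, ~ quantile(.x, 0.975))) |>
    dplyr::left_join(dplyr::select(x$ess, term = "parameter", "ess"),
                     by = "term")
}

#' @exportS3Method generics::glance
glance.pahc_fit <- function(x, ...) {
  tibble::tibble(
    outcome = x$outcome,
    round = x$round,
    n_records = x$n_records,
    n_clusters = nrow(x$cluster_index),
    n_districts = dplyr::n_distinct(x$cluster_index$district_id),
    n_states = dplyr::n_distinct(x$cluster_index$state_id),
    n_monitored = x$control$n_monitored,
    min_ess = min(x$ess$ess),
    accept_beta0 = x$acceptance$rate[x$acceptance$block == "beta0"])
}
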