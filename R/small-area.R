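#' Precision-weighted cluster probability
#'
#' Plugs the intercept and the cluster/district/state residuals into the
#' inverse logit,
#' \deqn{\hat p = \frac{\exp(\beta_0 + C_{0jkl} + D_{0kl} + S_{0l})}
#'                     {1 + \exp(\beta_0 + C_{0jkl} + D_{0kl} + S_{0l})},}
#' the shrunken ("precision-weighted") share of the outcome in a cluster.
#' Vectorized and strictly increasing in every argument.
#'
#' @param beta0,c_resid,d_resid,s_resid Finite numerics (recycled).
#' @return Probabilities in (0, 1).
#' @export
#' @examples
#' cluster_probability(0.3, 0.1, -0.2, 0.05)  # expit(0.25)
cluster_probability <- function(beta0, c_resid, d_resid, s_resid) {
  args <- list(beta0, c_resid, d_resid, s_resid)
  if (any(!vapply(args, function(a) all(is.finite(a)), logical(1)))) {
    abort("cluster_probability() requires finite inputs")
  }
  plogis(beta0 + c_resid + d_resid + s_resid)
}

#' Cluster-level precision-weighted estimates from a model fit
#'
#' Combines the posterior-mean intercept with each cluster's own residual and
#' those of its district and state via [cluster_probability()].
#'
#' @param fit A [fit_pahc()] result.
#' @param method `"plugin"` (default) evaluates the inverse logit at the
#'   posterior-mean intercept and residuals, matching the printed formula;
#'   `"drawwise"` instead averages the inverse logit over the monitored
#'   draws. The two differ only through the Jensen gap, which is small when
#'   residual posteriors are tight.
#' @return A tibble with one row per cluster: `cluster_id, district_id,
#'   state_id, outcome, round, p_hat, n_women`.
#' @export
cluster_estimates <- function(fit, method = c("plugin", "drawwise")) {
  stopifnot(inherits(fit, "pahc_fit"))
  method <- match.arg(method)
  res <- fit$residuals
  pick <- function(level) {
    r <- res[res$level == level, ]
    setNames(r$mean, r$unit_id)
  }
  rc <- pick("cluster"); rd <- pick("district"); rs <- pick("state")
  idx <- fit$cluster_index
  miss <- setdiff(idx$cluster_id, names(rc))
  if (length(miss) > 0) {
    abort(paste0("missing residual for cluster(s): ",
                 paste(head(miss, 5), collapse = ", ")))
  }
  b0 <- mean(fit$beta0_draws)
  p_hat <- if (method == "plugin") {
    cluster_probability(b0, rc[idx$cluster_id],
                        rd[idx$district_id], rs[idx$state_id])
  } else {
    fit$p_drawwise
  }
  tibble::tibble(
    cluster_id = idx$cluster_id,
    district_id = idx$district_id,
    state_id = idx$state_id,
    outcome = fit$outcome,
    round = fit$round,
    p_hat = p_hat,
    n_women = idx$n)
}

#' Average cluster estimates within districts
#'
#' The district prevalence estimate is the unweighted arithmetic mean of its
#' clusters' precision-weighted estimates; set `weight_by_women = TRUE` for a
#' woman-count-weighted mean instead.
#'
#' @param cluster_est A tibble from [cluster_estimates()] (rows may cover
#'   several outcomes/rounds).
#' @param weight_by_women Weight clusters by their number of women.
#' @return A tibble with one row per district, outcome and round:
#'   `district_id, state_id, outcome, round, p_hat, n_clusters`.
#' @export
district_average <- function(cluster_est, weight_by_women = FALSE) {
  cluster_est <- tibble::as_tibble(cluster_est)
  need <- c("cluster_id", "district_id", "state_id", "outcome", "round",
            "p_hat")
  missing <- setdiff(need, names(cluster_est))
  if (length(missing) > 0) {
    abort(paste0("cluster estimates are missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  w <- if (weight_by_women) {
    if (!"n_women" %in% names(cluster_est)) {
      abort("weight_by_women = TRUE requires an n_women column")
    }
    cluster_est$n_women
  } else {
    rep(1, nrow(cluster_est))
  }
  cluster_est |>
    dplyr::mutate(.w = w) |>
    dplyr::group_by(.data$district_id, .data$state_id, .data$outcome,
                    .data$round) |>
    dplyr::summarise(p_hat = sum(.data$p_hat * .data$.w) / sum(.data$.w),
                     n_clusters = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$outcome, .data$round, .data$district_id)
}

#' District estimates for a set of fitted models
#'
#' Orchestrates [cluster_estimates()] and [district_average()] over a list of
#' fits (typically 4 outcomes x 2 rounds). For a rural- or urban-only
#' analysis, filter the records and refit; districts with no cluster in the
#' stratum are then simply absent from the table (missing, not zero).
#'
#' @param fits A list of [fit_pahc()] objects.
#' @param weight_by_women Passed to [district_average()].
#' @return A district-estimate tibble covering every fit's outcome/round.
#' @export
estimate_districts <- function(fits, weight_by_women = FALSE) {
  if (inherits(fits, "pahc_fit")) fits <- list(fits)
  purrr::map(fits, cluster_estimates) |>
    dplyr::bind_rows() |>
    district_average(weight_by_women = weight_by_women)
}

#' Fit all outcome-by-round models and estimate district prevalence
#'
#' Runs [fit_pahc()] for every requested outcome within every round present
#' in `records` and returns both the fits and the district estimates. Each
#' fit gets a distinct seed derived deterministically from
#' `control$seed`.
#'
#' @param records Survey records, possibly spanning both rounds.
#' @param outcomes Outcomes to fit (default all four).
#' @param control A [mcmc_control()] used for every fit (seed offset per
#'   fit).
#' @return A list with `fits` (named `outcome.round`) and `districts` (the
#'   combined district-estimate tibble).
#' @export
small_area_estimates <- function(records, outcomes = pahc_outcomes(),
                                 control = mcmc_control()) {
  records <- tibble::as_tibble(records)
  rounds <- sort(unique(records$round))
  grid <- tidyr::expand_grid(outcome = outcomes, round = rounds)
  fits <- purrr::pmap(grid, function(outcome, round) {
    ctl <- control
    ctl$seed <- (control$seed +
                   1009L * match(outcome, pahc_outcomes()) +
                   10007L * match(round, rounds)) %% .Machine$integer.max
    fit_pahc(records[records$round == round, ], outcome, ctl)
  })
  names(fits) <- paste(grid$outcome, grid$round, sep = ".")
  list(fits = fits, districts = estimate_districts(fits))
}
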