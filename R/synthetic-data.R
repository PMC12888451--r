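#' Configure a synthetic NFHS-like survey population
#'
#' Describes the generative model behind [simulate_round()]: women nested in
#' clusters (rural villages / urban wards), clusters in districts, districts
#' in states, sampled in two cross-sectional rounds. Each of the four binary
#' problem outcomes follows a Bernoulli-logit law whose linear predictor adds
#' an overall intercept, Normal random intercepts at the state, district and
#' cluster levels, and a shared woman-level latent factor that induces
#' positive dependence between the four outcomes.
#'
#' The defaults sketch the NFHS frame: 36 states, about 650 districts,
#' lognormal survey weights normalized to mean one within a round, and
#' round-specific intercepts placed at the national "any problem" logits
#' (54.75/63.20/40.12/51.38 percent at baseline, 50.57/56.79/34.73/48.17 at
#' endline). Scale the counts down for desk-sized experiments.
#'
#' @param n_states Number of states.
#' @param districts_per_state Districts per state; scalar or length-`n_states`
#'   vector.
#' @param clusters_per_district Clusters sampled per district.
#' @param women_per_cluster Women interviewed per cluster.
#' @param beta0 Log-odds intercept per outcome: a named length-4 vector
#'   (applied to every round) or a named list of such vectors keyed by round
#'   label.
#' @param sigma2_state,sigma2_district,sigma2_cluster Variances (log-odds^2
#'   scale) of the Normal random intercepts at each level; scalar or named
#'   length-4 vector per outcome.
#' @param outcome_coupling Coefficient in \[0, 1\] scaling a shared
#'   standard-normal woman-level factor added to all four linear predictors;
#'   0 makes outcomes conditionally independent.
#' @param weight_sdlog,weight_meanlog Lognormal survey-weight parameters.
#'   `weight_meanlog = NULL` (default) sets `-weight_sdlog^2/2` so raw weights
#'   have mean 1; weights are additionally renormalized to mean 1 within each
#'   generated round.
#' @param urban_fraction Probability that a cluster is urban (residence is a
#'   cluster-level attribute).
#' @param seed Integer RNG seed; mandatory so every generated population is
#'   reproducible.
#' @return An object of class `pahc_config` (a validated list).
#' @seealso [simulate_round()], [simulate_panel()]
#' @export
#' @examples
#' cfg <- pahc_config(n_states = 3, districts_per_state = 2,
#'                    clusters_per_district = 4, women_per_cluster = 20,
#'                    seed = 1)
#' cfg$n_states
pahc_config <- function(n_states = 36,
                        districts_per_state = 18,
                        clusters_per_district = 44,
                        women_per_cluster = 25,
                        beta0 = NULL,
                        sigma2_state = 0.25,
                        sigma2_district = 0.05,
                        sigma2_cluster = 0.25,
                        outcome_coupling = 0.75,
                        weight_sdlog = 0.5,
                        weight_meanlog = NULL,
                        urban_fraction = 0.3,
                        seed) {
  if (missing(seed) || is.null(seed)) abort("pahc_config() requires a seed")
  seed <- as.integer(seed)
  if (is.null(beta0)) {
    beta0 <- list(
      baseline = qlogis(c(afford = 0.5475, prox = 0.6320,
                          perm = 0.4012, support = 0.5138)),
      endline  = qlogis(c(afford = 0.5057, prox = 0.5679,
                          perm = 0.3473, support = 0.4817)))
  }
  cfg <- list(
    n_states = as.integer(n_states),
    districts_per_state = as.integer(districts_per_state),
    clusters_per_district = as.integer(clusters_per_district),
    women_per_cluster = as.integer(women_per_cluster),
    beta0 = beta0,
    sigma2_state = sigma2_state,
    sigma2_district = sigma2_district,
    sigma2_cluster = sigma2_cluster,
    outcome_coupling = outcome_coupling,
    weight_sdlog = weight_sdlog,
    weight_meanlog = weight_meanlog %||% (-weight_sdlog^2 / 2),
    urban_fraction = urban_fraction,
    seed = seed)
  validate_config(cfg)
  structure(cfg, class = "pahc_config")
}

validate_config <- function(cfg) {
  counts <- c(cfg$n_states, cfg$districts_per_state, cfg$clusters_per_district,
              cfg$women_per_cluster)
  if (any(counts < 1)) abort("all population counts must be >= 1")
  if (!length(cfg$districts_per_state) %in% c(1L, cfg$n_states)) {
    abort("districts_per_state must be scalar or one value per state")
  }
  for (nm in c("sigma2_state", "sigma2_district", "sigma2_cluster")) {
    v <- cfg[[nm]]
    if (any(!is.finite(v)) || any(v < 0)) {
      abort(sprintf("%s must be finite and >= 0", nm))
    }
  }
  if (cfg$outcome_coupling < 0 || cfg$outcome_coupling > 1) {
    abort("outcome_coupling must lie in [0, 1]")
  }
  if (cfg$urban_fraction < 0 || cfg$urban_fraction > 1) {
    abort("urban_fraction must lie in [0, 1]")
  }
  if (cfg$weight_sdlog < 0) abort("weight_sdlog must be >= 0")
  invisible(cfg)
}

# beta0 / sigma2 entries may be per-round lists and/or per-outcome vectors
resolve_beta0 <- function(beta0, round) {
  if (is.list(beta0)) {
    if (!round %in% names(beta0)) {
      abort(sprintf("beta0 has no entry for round '%s'", round))
    }
    beta0 <- beta0[[round]]
  }
  resolve_per_outcome(beta0, "beta0")
}

resolve_per_outcome <- function(x, what) {
  outs <- pahc_outcomes()
  if (length(x) == 1) x <- setNames(rep(x, 4), outs)
  if (is.null(names(x))) names(x) <- outs
  if (!all(outs %in% names(x))) {
    abort(sprintf("%s must be named with the four outcomes", what))
  }
  x[outs]
}

round_seed <- function(seed, round) {
  offset <- sum(utf8ToInt(round)) %% 1000L
  (seed + 7919L * offset) %% .Machine$integer.max
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Simulate one survey round of unit records
#'
#' Draws a full cross-section from a [pahc_config()]: state, district and
#' cluster random intercepts for each outcome, a shared woman-level factor,
#' Bernoulli outcomes, lognormal survey weights (renormalized to mean one),
#' and cluster-level urban/rural residence. The result is byte-identical
#' across calls with the same config and round label.
#'
#' @param config A [pahc_config()].
#' @param round Round label, conventionally `"baseline"` or `"endline"`.
#' @return A tibble of survey records (one row per woman) with columns
#'   `woman_id, cluster_id, district_id, state_id, round, residence, weight,
#'   y_afford, y_prox, y_perm, y_support`. The drawn random effects and the
#'   config are attached as the `ground_truth` attribute; retrieve them with
#'   [ground_truth()].
#' @export
#' @examples
#' cfg <- pahc_config(n_states = 2, districts_per_state = 2,
#'                    clusters_per_district = 3, women_per_cluster = 10,
#'                    seed = 42)
#' rec <- simulate_round(cfg, "baseline")
#' dplyr::count(rec, state_id)
simulate_round <- function(config, round = "baseline") {
  stopifnot(inherits(config, "pahc_config"))
  validate_config(config)
  with_seed(round_seed(config$seed, round), simulate_round_impl(config, round))
}

simulate_round_impl <- function(config, round) {
  outs <- pahc_outcomes()
  dps <- config$districts_per_state
  if (length(dps) == 1) dps <- rep(dps, config$n_states)

  state_id <- sprintf("S%02d", seq_len(config$n_states))
  district_state <- rep(seq_len(config$n_states), dps)
  district_id <- sprintf("%sD%02d", state_id[district_state],
                         unlist(lapply(dps, seq_len)))
  n_d <- length(district_id)
  cluster_district <- rep(seq_len(n_d), each = config$clusters_per_district)
  cluster_id <- sprintf("%sC%03d", district_id[cluster_district],
                        rep(seq_len(config$clusters_per_district), times = n_d))
  n_c <- length(cluster_id)
  n_w <- n_c * config$women_per_cluster

  b0 <- resolve_beta0(config$beta0, round)
  v_s <- resolve_per_outcome(config$sigma2_state, "sigma2_state")
  v_d <- resolve_per_outcome(config$sigma2_district, "sigma2_district")
  v_c <- resolve_per_outcome(config$sigma2_cluster, "sigma2_cluster")

  draw_effects <- function(n_units, v) {
    m <- vapply(outs, function(o) rnorm(n_units, 0, sqrt(v[o])),
                numeric(n_units))
    matrix(m, nrow = n_units, ncol = 4, dimnames = list(NULL, outs))
  }
  eff_s <- draw_effects(config$n_states, v_s)
  eff_d <- draw_effects(n_d, v_d)
  eff_c <- draw_effects(n_c, v_c)

  woman_cluster <- rep(seq_len(n_c), each = config$women_per_cluster)
  u <- rnorm(n_w)

  y <- matrix(0L, n_w, 4, dimnames = list(NULL, paste0("y_", outs)))
  for (k in seq_along(outs)) {
    o <- outs[k]
    eta <- b0[o] +
      eff_s[district_state[cluster_district[woman_cluster]], k] +
      eff_d[cluster_district[woman_cluster], k] +
      eff_c[woman_cluster, k] +
      config$outcome_coupling * u
    y[, k] <- rbinom(n_w, 1L, plogis(eta))
  }

  w <- rlnorm(n_w, config$weight_meanlog, config$weight_sdlog)
  w <- w / mean(w)
  urban <- runif(n_c) < config$urban_fraction

  records <- tibble::tibble(
    woman_id = sprintf("%s_%07d", round, seq_len(n_w)),
    cluster_id = cluster_id[woman_cluster],
    district_id = district_id[cluster_district[woman_cluster]],
    state_id = state_id[district_state[cluster_district[woman_cluster]]],
    round = round,
    residence = ifelse(urban[woman_cluster], "urban", "rural"),
    weight = w)
  records <- dplyr::bind_cols(records, tibble::as_tibble(y))

  truth <- list(
    config = config,
    round = round,
    beta0 = b0,
    sigma2 = list(state = v_s, district = v_d, cluster = v_c),
    effects = list(
      state = tibble::as_tibble(eff_s) |>
        dplyr::mutate(state_id = state_id, .before = 1),
      district = tibble::as_tibble(eff_d) |>
        dplyr::mutate(district_id = district_id, .before = 1),
      cluster = tibble::as_tibble(eff_c) |>
        dplyr::mutate(cluster_id = cluster_id, .before = 1)))
  attr(records, "ground_truth") <- truth
  records
}

#' Extract the generative ground truth attached to simulated records
#'
#' @param records A tibble produced by [simulate_round()].
#' @return A list with the config, round label, per-outcome intercepts and
#'   variances, and the drawn state/district/cluster effects.
#' @export
ground_truth <- function(records) {
  gt <- attr(records, "ground_truth", exact = TRUE)
  if (is.null(gt)) abort("records carry no ground_truth attribute")
  gt
}

#' Describe a district-boundary change between survey rounds
#'
#' Captures the refinement-only boundary narrative: some baseline districts
#' split into two endline districts, and a small set of baseline clusters
#' cannot be mapped to any endline district and must be dropped.
#'
#' @param split_districts Character vector of baseline district ids to split
#'   in two.
#' @param drop_clusters Explicit baseline cluster ids to mark unmappable, or
#'   `NULL`.
#' @param drop_fraction Alternatively, the fraction of baseline clusters to
#'   drop at random (ignored when `drop_clusters` is given).
#' @return An object of class `pahc_scenario`.
#' @export
boundary_scenario <- function(split_districts = character(),
                              drop_clusters = NULL,
                              drop_fraction = 0) {
  if (drop_fraction < 0 || drop_fraction > 1) {
    abort("drop_fraction must lie in [0, 1]")
  }
  structure(list(split_districts = as.character(split_districts),
                 drop_clusters = drop_clusters,
                 drop_fraction = drop_fraction),
            class = "pahc_scenario")
}

#' Simulate a two-round panel with a boundary-change scenario
#'
#' Generates a baseline and an endline cross-section on a shared state and
#' district scaffold, applies a [boundary_scenario()] so the endline district
#' set is a refinement of the baseline one (splits only), and builds the
#' cluster-to-district crosswalk that reassigns every baseline cluster to an
#' endline-vintage district or marks it for dropping.
#'
#' @param config_baseline,config_endline [pahc_config()] objects; they must
#'   agree on `n_states` and `districts_per_state` so the two rounds share a
#'   district scaffold. Random effects are drawn independently per round.
#' @param scenario A [boundary_scenario()]; the default changes nothing.
#' @return A list with elements `baseline` and `endline` (record tibbles;
#'   endline districts carry the post-split ids) and `crosswalk` (a tibble
#'   with columns `cluster_id, old_district_id, new_district_id, action`).
#' @export
#' @examples
#' cfg <- pahc_config(n_states = 2, districts_per_state = 2,
#'                    clusters_per_district = 4, women_per_cluster = 10,
#'                    seed = 7)
#' panel <- simulate_panel(cfg, cfg,
#'                         boundary_scenario(split_districts = "S01D01"))
#' dplyr::count(panel$crosswalk, action)
simulate_panel <- function(config_baseline, config_endline,
                           scenario = boundary_scenario()) {
  stopifnot(inherits(scenario, "pahc_scenario"))
  if (config_baseline$n_states != config_endline$n_states ||
      !identical(rep_len(config_baseline$districts_per_state,
                         config_baseline$n_states),
                 rep_len(config_endline$districts_per_state,
                         config_endline$n_states))) {
    abort("baseline and endline configs must share the district scaffold")
  }
  baseline <- simulate_round(config_baseline, "baseline")
  endline <- simulate_round(config_endline, "endline")

  base_districts <- unique(baseline$district_id)
  unknown <- setdiff(scenario$split_districts, base_districts)
  if (length(unknown) > 0) {
    abort(paste0("scenario references unknown district(s): ",
                 paste(unknown, collapse = ", ")))
  }

  base_clusters <- dplyr::distinct(baseline, .data$cluster_id,
                                   .data$district_id)
  drop_ids <- scenario$drop_clusters
  if (is.null(drop_ids) && scenario$drop_fraction > 0) {
    n_drop <- round(scenario$drop_fraction * nrow(base_clusters))
    drop_ids <- with_seed(round_seed(config_baseline$seed, "crosswalk"),
                          sample(base_clusters$cluster_id, n_drop))
  }
  drop_ids <- as.character(drop_ids %||% character())
  unknown_cl <- setdiff(drop_ids, base_clusters$cluster_id)
  if (length(unknown_cl) > 0) {
    abort(paste0("scenario references unknown cluster(s): ",
                 paste(head(unknown_cl, 5), collapse = ", ")))
  }

  # refine geometry: each split district becomes <id>a / <id>b; a cluster goes
  # to the half matching its within-district order (first half -> a)
  split_assign <- function(clusters, district) {
    if (!district %in% scenario$split_districts) {
      return(rep(district, length(clusters)))
    }
    half <- ceiling(length(clusters) / 2)
    ifelse(seq_along(clusters) <= half,
           paste0(district, "a"), paste0(district, "b"))
  }

  crosswalk <- base_clusters |>
    dplyr::arrange(.data$district_id, .data$cluster_id) |>
    dplyr::group_by(.data$district_id) |>
    dplyr::mutate(new_district_id =
                    split_assign(.data$cluster_id, .data$district_id[1])) |>
    dplyr::ungroup() |>
    dplyr::rename(old_district_id = "district_id") |>
    dplyr::mutate(
      action = ifelse(.data$cluster_id %in% drop_ids, "drop", "map"),
      new_district_id = ifelse(.data$action == "drop", "",
                               .data$new_district_id)) |>
    dplyr::select("cluster_id", "old_district_id", "new_district_id",
                  "action")

  endline <- endline |>
    dplyr::group_by(.data$district_id) |>
    dplyr::mutate(new_district_id = split_assign_records(
      .data$cluster_id, .data$district_id[1], scenario)) |>
    dplyr::ungroup() |>
    dplyr::mutate(district_id = .data$new_district_id) |>
    dplyr::select(-"new_district_id")

  list(baseline = baseline, endline = endline, crosswalk = crosswalk)
}

split_assign_records <- function(cluster_id, district, scenario) {
  if (!district %in% scenario$split_districts) {
    return(rep(district, length(cluster_id)))
  }
  ids <- sort(unique(cluster_id))
  half <- ceiling(length(ids) / 2)
  new <- ifelse(match(cluster_id, ids) <= half,
                paste0(district, "a"), paste0(district, "b"))
  new
}
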