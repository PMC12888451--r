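filter_stratum <- function(records, stratum) {
  stratum <- match.arg(stratum, c("all", "rural", "urban"))
  if (stratum != "all") {
    records <- records[records$residence == stratum, , drop = FALSE]
  }
  records
}

wald_ci <- function(pct, n) {
  p <- pct / 100
  half <- 1.96 * 100 * sqrt(pmax(p * (1 - p), 0) / n)
  list(low = pct - half, high = pct + half)
}

#' Survey-weighted prevalence of each problem with Wald intervals
#'
#' For every outcome and round (optionally within a residence stratum),
#' tabulates the weighted percentage of women reporting "any problem" and
#' "no problem": \eqn{100 \sum w_i y_i / \sum w_i}, with a Wald 95% CI using
#' the unweighted count as n. The two category percentages sum to 100 before
#' rounding.
#'
#' @param records Survey records.
#' @param outcomes Outcomes to tabulate (default all four).
#' @param stratum `"all"`, `"rural"` or `"urban"`.
#' @return A tibble with columns `outcome, round, stratum, category,
#'   n_unweighted, pct_weighted, ci_low, ci_high`; zero rows (not NaN) if the
#'   stratum is empty.
#' @export
#' @examples
#' rec <- simulate_round(pahc_config(n_states = 2, districts_per_state = 2,
#'                                   clusters_per_district = 3,
#'                                   women_per_cluster = 20, seed = 5))
#' weighted_prevalence(rec)
weighted_prevalence <- function(records, outcomes = pahc_outcomes(),
                                stratum = "all") {
  records <- filter_stratum(tibble::as_tibble(records), stratum)
  empty <- tibble::tibble(outcome = character(), round = character(),
                          stratum = character(), category = character(),
                          n_unweighted = integer(), pct_weighted = double(),
                          ci_low = double(), ci_high = double())
  if (nrow(records) == 0) return(empty)
  if (any(records$weight <= 0)) abort("weights must be positive")
  purrr::map_dfr(outcomes, function(o) {
    col <- outcome_col(o)
    records |>
      dplyr::group_by(.data$round) |>
      dplyr::summarise(
        n_any = sum(.data[[col]] == 1),
        n_tot = dplyr::n(),
        pct_any = 100 * sum(.data$weight * .data[[col]]) / sum(.data$weight),
        .groups = "drop") |>
      dplyr::reframe(
        outcome = o,
        round = rep(.data$round, each = 2),
        stratum = stratum,
        category = rep(c("no_problem", "any_problem"), dplyr::n()),
        n_unweighted = as.vector(rbind(.data$n_tot - .data$n_any,
                                       .data$n_any)),
        pct_weighted = as.vector(rbind(100 - .data$pct_any, .data$pct_any)),
        n_tot = rep(.data$n_tot, each = 2)) |>
      dplyr::mutate(ci_low = wald_ci(.data$pct_weighted, .data$n_tot)$low,
                    ci_high = wald_ci(.data$pct_weighted, .data$n_tot)$high) |>
      dplyr::select(-"n_tot")
  })
}

combo_labels <- function() {
  keys <- c(afford = "A", prox = "P", perm = "Pe", support = "S")
  masks <- expand.grid(afford = 0:1, prox = 0:1, perm = 0:1, support = 0:1)
  masks <- masks[, pahc_outcomes()]
  combo_id <- apply(masks, 1, paste0, collapse = "")
  label <- apply(masks, 1, function(m) {
    on <- keys[m == 1]
    if (length(on) == 0) "None" else paste(on, collapse = "+")
  })
  tibble::tibble(combo_id = combo_id, label = label,
                 n_problems = rowSums(masks))
}

#' All sixteen problem combinations with weighted shares
#'
#' Assigns every woman to exactly one of the 16 mutually exclusive subsets of
#' the four problems (including "no problem") and reports each subset's
#' weighted percentage with a Wald 95% CI (unweighted round total as n). The
#' 16 percentages sum to 100 within each round and stratum before rounding.
#'
#' @param records Survey records.
#' @param stratum `"all"`, `"rural"` or `"urban"`.
#' @return A tibble with one row per combination per round: `round, stratum,
#'   combo_id` (4-character bitmask in afford/prox/perm/support order),
#'   `label` (e.g. `"A+P+S"`), `n_problems`, `n_unweighted, pct_weighted,
#'   ci_low, ci_high, n_total`. Feed it to [combination_margins()] for the
#'   grouped 4/3/2/1/0-problem margins.
#' @export
combination_table <- function(records, stratum = "all") {
  records <- filter_stratum(validate_records(records), stratum)
  if (nrow(records) == 0) {
    abort("no records in the requested stratum")
  }
  lab <- combo_labels()
  records |>
    dplyr::mutate(combo_id = paste0(.data$y_afford, .data$y_prox,
                                    .data$y_perm, .data$y_support)) |>
    dplyr::group_by(.data$round) |>
    dplyr::mutate(n_total = dplyr::n(), w_total = sum(.data$weight)) |>
    dplyr::group_by(.data$round, .data$combo_id) |>
    dplyr::summarise(n_unweighted = dplyr::n(),
                     pct_weighted = 100 * sum(.data$weight) /
                       .data$w_total[1],
                     n_total = .data$n_total[1], .groups = "drop") |>
    # make absent combinations explicit zero cells
    tidyr::complete(.data$round, combo_id = lab$combo_id,
                    fill = list(n_unweighted = 0L, pct_weighted = 0)) |>
    dplyr::group_by(.data$round) |>
    tidyr::fill("n_total", .direction = "downup") |>
    dplyr::ungroup() |>
    dplyr::left_join(lab, by = "combo_id") |>
    dplyr::mutate(stratum = stratum,
                  ci_low = wald_ci(.data$pct_weighted, .data$n_total)$low,
                  ci_high = wald_ci(.data$pct_weighted, .data$n_total)$high) |>
    dplyr::select("round", "stratum", "combo_id", "label", "n_problems",
                  "n_unweighted", "pct_weighted", "ci_low", "ci_high",
                  "n_total") |>
    dplyr::arrange(.data$round, dplyr::desc(.data$n_problems), .data$combo_id)
}

#' Grouped margins of a combination table
#'
#' Sums the member cells of a [combination_table()] into the exactly-4, -3,
#' -2, -1 and 0-problem margins. Margins are pure sums of their member
#' subsets; the CI, where computable, uses the margin percentage with the
#' round's unweighted total as n.
#'
#' @param cells A tibble with at least `combo_id` (or `n_problems`) and
#'   `pct_weighted`; `round`/`stratum`/`n_total` are carried through when
#'   present.
#' @return A tibble with one row per number of problems (per round/stratum):
#'   `n_problems, pct_weighted` and, when `n_total` is available, `ci_low,
#'   ci_high`.
#' @export
#' @examples
#' # the four printed three-problem cells of a published table sum to the
#' # printed exactly-three margin
#' cells <- tibble::tibble(combo_id = c("1110", "1101", "1011", "0111"),
#'                         pct_weighted = c(3.84, 8.97, 1.09, 1.65))
#' combination_margins(cells)
combination_margins <- function(cells) {
  cells <- tibble::as_tibble(cells)
  if (!"pct_weighted" %in% names(cells)) {
    abort("cells must carry a pct_weighted column")
  }
  if (!"n_problems" %in% names(cells)) {
    if (!"combo_id" %in% names(cells)) {
      abort("cells must carry n_problems or combo_id")
    }
    cells$n_problems <- vapply(strsplit(cells$combo_id, ""),
                               function(b) sum(b == "1"), numeric(1))
  }
  group_cols <- intersect(c("round", "stratum"), names(cells))
  out <- cells |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(group_cols,
                                                  "n_problems")))) |>
    dplyr::summarise(pct_weighted = sum(.data$pct_weighted),
                     n_total = if ("n_total" %in% names(cells))
                       .data$n_total[1] else NA_real_,
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n_problems))
  if (all(is.na(out$n_total))) {
    dplyr::select(out, -"n_total")
  } else {
    dplyr::mutate(out,
                  ci_low = wald_ci(.data$pct_weighted, .data$n_total)$low,
                  ci_high = wald_ci(.data$pct_weighted, .data$n_total)$high)
  }
}

#' Variance partitioning coefficients
#'
#' Shares of the random-intercept variation attributable to states, districts
#' and clusters. By default the individual level is excluded, so the three
#' shares are \eqn{\sigma^2_{level} / (\sigma^2_C + \sigma^2_D + \sigma^2_S)}
#' and sum to one. With `include_individual = TRUE` the latent-variable
#' convention adds \eqn{\pi^2/3} — the variance of the standard logistic —
#' to the denominator and reports the individual share too.
#'
#' For a fitted model the reported share is the posterior mean of the VPC:
#' the share is computed within every monitored draw and then averaged, the
#' proper posterior expectation of the quantity. (Plugging posterior-mean
#' variances into the formula instead inherits the right skew of the
#' variance posteriors when a level has few units; with explicit variances
#' that plug-in arithmetic is available as [vpc_shares()].) Per-draw shares
#' sum to one, so the averages do too.
#'
#' @param fit A [fit_pahc()] object.
#' @param include_individual Include the woman-level logistic variance.
#' @return A one-row tibble: `outcome, round, share_cluster, share_district,
#'   share_state` (and `share_individual` when included); shares sum to 1.
#' @export
vpc <- function(fit, include_individual = FALSE) {
  stopifnot(inherits(fit, "pahc_fit"))
  v <- fit$sigma2_draws
  denom <- v$cluster + v$district + v$state +
    if (include_individual) pi^2 / 3 else 0
  out <- tibble::tibble(
    outcome = fit$outcome, round = fit$round,
    share_cluster = mean(v$cluster / denom),
    share_district = mean(v$district / denom),
    share_state = mean(v$state / denom),
    includes_individual = include_individual)
  if (include_individual) {
    out$share_individual <- mean((pi^2 / 3) / denom)
  }
  out
}

#' @rdname vpc
#' @param sigma2_cluster,sigma2_district,sigma2_state Non-negative level
#'   variances on the log-odds^2 scale.
#' @export
#' @examples
#' vpc_shares(0.40, 0.07, 0.53)
vpc_shares <- function(sigma2_cluster, sigma2_district, sigma2_state,
                       include_individual = FALSE) {
  v <- c(cluster = sigma2_cluster, district = sigma2_district,
         state = sigma2_state)
  if (any(!is.finite(v)) || any(v < 0)) {
    abort("variances must be finite and >= 0")
  }
  denom <- sum(v) + if (include_individual) pi^2 / 3 else 0
  if (denom == 0) abort("all variances are zero; shares undefined")
  out <- tibble::tibble(share_cluster = v[["cluster"]] / denom,
                        share_district = v[["district"]] / denom,
                        share_state = v[["state"]] / denom,
                        includes_individual = include_individual)
  if (include_individual) {
    out$share_individual <- (pi^2 / 3) / denom
  }
  out
}
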