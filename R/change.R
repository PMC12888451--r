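#' Decile cut points of baseline district values
#'
#' The nine 10th–90th percentiles (linear-interpolation quantiles, R type 7)
#' of the baseline district estimates, used to bin both survey rounds on a
#' common scale.
#'
#' @param x Numeric vector of at least 10 district values.
#' @return Nine non-decreasing cut points.
#' @export
#' @examples
#' decile_cuts(1:100)[1]  # 10.9
decile_cuts <- function(x) {
  if (length(x) < 10) abort("need at least 10 districts for decile cuts")
  if (any(!is.finite(x))) abort("district values must be finite")
  unname(quantile(x, probs = seq(0.1, 0.9, by = 0.1), type = 7))
}

#' @rdname decile_cuts
#' @param baseline_districts A district-estimate tibble (see
#'   [district_average()]) for the baseline round, with `outcome` and `p_hat`
#'   columns; `p_hat` probabilities are reported as percentages.
#' @return For the data-frame method: a tibble `outcome, decile, cut` with
#'   nine rows per outcome (cuts in percentage points).
#' @export
decile_thresholds <- function(baseline_districts) {
  baseline_districts <- tibble::as_tibble(baseline_districts)
  baseline_districts |>
    dplyr::group_by(.data$outcome) |>
    dplyr::reframe(decile = 1:9,
                   cut = decile_cuts(100 * .data$p_hat))
}

#' Bin values with fixed decile cuts
#'
#' Intervals take their left cut point from the bin below (a value equal to a
#' cut stays in the lower bin), so fully tied cuts send everything to bin 1;
#' values beyond the baseline range clamp to bins 1 or 10.
#'
#' @param x Numeric values to bin.
#' @param cuts Nine non-decreasing cut points from [decile_cuts()].
#' @return Integer bins in 1..10.
#' @export
bin_by_deciles <- function(x, cuts) {
  if (length(cuts) != 9 || is.unsorted(cuts)) {
    abort("cuts must be 9 non-decreasing values")
  }
  findInterval(x, cuts, left.open = TRUE) + 1L
}

change_categories <- function() {
  c("Worsened", "VeryLow", "Low", "Moderate", "High", "VeryHigh")
}

#' Classify a district's between-round change
#'
#' Bands the absolute percentage-point decline `delta = p_baseline -
#' p_endline` (positive = improvement) into Very Low (< 5), Low (5–10),
#' Moderate (10–15), High (15–20) and Very High (> 20) improvement. Bands are
#' half-open on the left, so exactly 5.0 is Low and exactly 10.0 is Moderate.
#' A negative delta — prevalence rose — gets its own `Worsened` category
#' rather than being folded into Very Low.
#'
#' @param delta Finite numeric percentage-point declines.
#' @return An ordered factor with levels
#'   `Worsened < VeryLow < Low < Moderate < High < VeryHigh`.
#' @export
#' @examples
#' classify_change(c(-2.3, 0, 5, 6.41, 10, 20))
classify_change <- function(delta) {
  if (any(!is.finite(delta))) abort("delta must be finite")
  cut(delta, breaks = c(-Inf, 0, 5, 10, 15, 20, Inf),
      labels = change_categories(),
      right = FALSE, ordered_result = TRUE)
}

#' District-level change records between two rounds
#'
#' Joins baseline and endline district estimates per outcome, computes the
#' percentage-point decline, bins both rounds with the baseline-only decile
#' thresholds, and applies [classify_change()]. Only districts present in
#' both rounds (the harmonized geometry) appear.
#'
#' @param baseline,endline District-estimate tibbles from
#'   [district_average()] or [estimate_districts()]; `p_hat` is a probability
#'   and is reported in percentage points.
#' @return A tibble with one row per district per outcome: `district_id,
#'   state_id, outcome, p_baseline, p_endline, delta, decile_bin_baseline,
#'   decile_bin_endline, category`. The decile thresholds used are attached
#'   as attribute `thresholds`.
#' @export
change_table <- function(baseline, endline) {
  baseline <- tibble::as_tibble(baseline)
  endline <- tibble::as_tibble(endline)
  thresholds <- decile_thresholds(baseline)
  cuts <- split(thresholds$cut, thresholds$outcome)
  out <- dplyr::inner_join(
    dplyr::select(baseline, "district_id", "state_id", "outcome",
                  p_baseline = "p_hat"),
    dplyr::select(endline, "district_id", "outcome", p_endline = "p_hat"),
    by = c("district_id", "outcome")) |>
    dplyr::mutate(p_baseline = 100 * .data$p_baseline,
                  p_endline = 100 * .data$p_endline,
                  delta = .data$p_baseline - .data$p_endline) |>
    dplyr::group_by(.data$outcome) |>
    dplyr::mutate(
      decile_bin_baseline = bin_by_deciles(.data$p_baseline,
                                           cuts[[.data$outcome[1]]]),
      decile_bin_endline = bin_by_deciles(.data$p_endline,
                                          cuts[[.data$outcome[1]]])) |>
    dplyr::ungroup() |>
    dplyr::mutate(category = classify_change(.data$delta)) |>
    dplyr::arrange(.data$outcome, .data$district_id)
  attr(out, "thresholds") <- thresholds
  out
}

#' Count districts whose decline exceeds a threshold
#'
#' Per outcome: the number of districts whose percentage-point decline is
#' strictly greater than `threshold`, alongside the median baseline and
#' endline district prevalence.
#'
#' @param change_records A tibble from [change_table()] (one row per district
#'   per outcome).
#' @param threshold Percentage-point decline that must be strictly exceeded
#'   (default 10).
#' @return A tibble `outcome, n_districts, n_above_threshold,
#'   median_baseline, median_endline`; zero rows for empty input.
#' @export
count_districts <- function(change_records, threshold = 10) {
  change_records <- tibble::as_tibble(change_records)
  if (nrow(change_records) == 0) {
    return(tibble::tibble(outcome = character(), n_districts = integer(),
                          n_above_threshold = integer(),
                          median_baseline = double(),
                          median_endline = double()))
  }
  dup <- change_records |>
    dplyr::count(.data$outcome, .data$district_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("duplicate district rows (e.g. %s / %s)",
                  dup$outcome[1], dup$district_id[1]))
  }
  change_records |>
    dplyr::group_by(.data$outcome) |>
    dplyr::summarise(n_districts = dplyr::n(),
                     n_above_threshold = sum(.data$delta > threshold),
                     median_baseline = median(.data$p_baseline),
                     median_endline = median(.data$p_endline),
                     .groups = "drop")
}
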