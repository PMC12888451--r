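#' Reassign baseline clusters to a harmonized district geometry
#'
#' Applies a cluster-to-district crosswalk table to baseline records so both
#' survey rounds can be analyzed on one district vintage. Every cluster in
#' `records` must have exactly one entry in `table`; clusters whose entry says
#' `drop` have all their records removed (the unmappable clusters), the rest
#' get their `district_id` replaced by the harmonized id. A cluster found in
#' the records but absent from the table is a hard error — silent pass-through
#' would corrupt the district accounting.
#'
#' @param records A tibble of survey records (see [validate_records()] for the
#'   contract; only `cluster_id` and `district_id` are touched).
#' @param table Crosswalk tibble with columns
#'   `cluster_id, old_district_id, new_district_id, action`
#'   (`action` in `map`/`drop`; `new_district_id` empty only for drops).
#' @return The mapped records tibble. The accounting report (a one-row tibble
#'   with `n_input_records, n_dropped_records, n_retained_records,
#'   n_old_districts, n_new_districts`) is attached as the
#'   `crosswalk_report` attribute; retrieve it with [crosswalk_report()].
#' @export
#' @examples
#' rec <- simulate_round(pahc_config(n_states = 2, districts_per_state = 2,
#'                                   clusters_per_district = 3,
#'                                   women_per_cluster = 5, seed = 3))
#' cw <- identity_crosswalk(rec)
#' out <- apply_crosswalk(rec, cw)
#' crosswalk_report(out)
apply_crosswalk <- function(records, table) {
  records <- tibble::as_tibble(records)
  table <- check_crosswalk_columns(table)
  viol <- validate_crosswalk(table)
  if (nrow(viol) > 0) {
    abort(paste0("invalid crosswalk table: ",
                 paste(unique(viol$violation), collapse = "; ")))
  }
  missing <- setdiff(unique(records$cluster_id), table$cluster_id)
  if (length(missing) > 0) {
    abort(paste0("no crosswalk entry for cluster(s): ",
                 paste(head(missing, 5), collapse = ", "),
                 if (length(missing) > 5) sprintf(" (and %d more)",
                                                  length(missing) - 5)))
  }

  joined <- dplyr::left_join(records, table, by = "cluster_id")
  kept <- joined |>
    dplyr::filter(.data$action == "map") |>
    dplyr::mutate(district_id = .data$new_district_id) |>
    dplyr::select(-"old_district_id", -"new_district_id", -"action")

  report <- tibble::tibble(
    n_input_records = nrow(records),
    n_dropped_records = nrow(records) - nrow(kept),
    n_retained_records = nrow(kept),
    n_old_districts = dplyr::n_distinct(records$district_id),
    n_new_districts = dplyr::n_distinct(kept$district_id))
  attr(kept, "crosswalk_report") <- report
  kept
}

#' @rdname apply_crosswalk
#' @param mapped_records The tibble returned by `apply_crosswalk()`.
#' @export
crosswalk_report <- function(mapped_records) {
  rep <- attr(mapped_records, "crosswalk_report", exact = TRUE)
  if (is.null(rep)) abort("records carry no crosswalk_report attribute")
  rep
}

#' Diagnose problems in a crosswalk table
#'
#' Checks the table contract without stopping: duplicated clusters, mapping
#' rows with an empty destination, drop rows carrying a destination, unknown
#' action labels, and (when reference id sets are supplied) source or
#' destination districts outside those sets.
#'
#' @param table A crosswalk tibble (see [apply_crosswalk()]).
#' @param old_district_ids,new_district_ids Optional reference sets of valid
#'   district ids for each vintage.
#' @return A tibble of violations with columns `violation` and `detail`;
#'   zero rows means the table is valid.
#' @export
validate_crosswalk <- function(table, old_district_ids = NULL,
                               new_district_ids = NULL) {
  table <- check_crosswalk_columns(table)
  v <- list()
  note <- function(violation, detail) {
    v[[length(v) + 1]] <<- tibble::tibble(violation = violation,
                                          detail = as.character(detail))
  }
  dup <- unique(table$cluster_id[duplicated(table$cluster_id)])
  for (d in dup) note("duplicate cluster", d)
  bad_action <- unique(table$action[!table$action %in% c("map", "drop")])
  for (a in bad_action) note("unknown action", a)
  empty_map <- table$cluster_id[table$action == "map" &
                                  (is.na(table$new_district_id) |
                                     table$new_district_id == "")]
  for (cl in empty_map) note("empty mapping", cl)
  full_drop <- table$cluster_id[table$action == "drop" &
                                  !is.na(table$new_district_id) &
                                  table$new_district_id != ""]
  for (cl in full_drop) note("drop with destination", cl)
  if (!is.null(old_district_ids)) {
    bad <- setdiff(unique(table$old_district_id), old_district_ids)
    for (d in bad) note("unknown old district", d)
  }
  if (!is.null(new_district_ids)) {
    used <- table$new_district_id[table$action == "map"]
    bad <- setdiff(unique(used), new_district_ids)
    for (d in bad) note("unknown new district", d)
  }
  if (length(v) == 0) {
    return(tibble::tibble(violation = character(), detail = character()))
  }
  dplyr::bind_rows(v)
}

#' Build the identity crosswalk for a set of records
#'
#' Every cluster maps to its current district; applying it is a no-op. Useful
#' as a starting point when only a few districts changed between vintages.
#'
#' @param records A tibble of survey records.
#' @return A crosswalk tibble mapping each cluster to its own district.
#' @export
identity_crosswalk <- function(records) {
  dplyr::distinct(tibble::as_tibble(records), .data$cluster_id,
                  .data$district_id) |>
    dplyr::transmute(cluster_id = .data$cluster_id,
                     old_district_id = .data$district_id,
                     new_district_id = .data$district_id,
                     action = "map")
}

check_crosswalk_columns <- function(table) {
  table <- tibble::as_tibble(table)
  need <- c("cluster_id", "old_district_id", "new_district_id", "action")
  missing <- setdiff(need, names(table))
  if (length(missing) > 0) {
    abort(paste0("crosswalk table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  table
}
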