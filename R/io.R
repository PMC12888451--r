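#' Read and write unit-record CSV files
#'
#' The on-disk contract is a plain CSV with header `woman_id, cluster_id,
#' district_id, state_id, round, residence, weight, y_afford, y_prox, y_perm,
#' y_support`. Reading validates every row and reports the first offending
#' CSV line number (header = line 1): outcomes must be 0/1, weights strictly
#' positive, nesting consistent. Writing then reading is lossless.
#'
#' @param path CSV file path.
#' @return `read_records()` returns a validated tibble of records;
#'   `write_records()` returns `path` invisibly.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE)
  missing <- setdiff(record_columns(), names(df))
  if (length(missing) > 0) {
    abort(paste0("records file is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  line <- function(i) i + 1L  # header occupies line 1
  w <- suppressWarnings(as.numeric(df$weight))
  bad <- which(is.na(w) | w <= 0)
  if (length(bad) > 0) {
    abort(sprintf("line %d: weight '%s' is not a positive number",
                  line(bad[1]), df$weight[bad[1]]))
  }
  df$weight <- w
  for (oc in paste0("y_", pahc_outcomes())) {
    v <- df[[oc]]
    bad <- which(!v %in% c("0", "1"))
    if (length(bad) > 0) {
      abort(sprintf("line %d: %s value '%s' is not 0/1",
                    line(bad[1]), oc, v[bad[1]]))
    }
    df[[oc]] <- as.integer(v)
  }
  validate_records(tibble::as_tibble(df))
}

#' @rdname read_records
#' @param records A tibble of survey records.
#' @export
write_records <- function(records, path) {
  records <- validate_records(records)
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write crosswalk CSV files
#'
#' Columns `cluster_id, old_district_id, new_district_id, action` with
#' `action` in `map`/`drop`; an empty `new_district_id` is permitted only on
#' drop rows. Reading validates via [validate_crosswalk()].
#'
#' @param path CSV file path.
#' @return `read_crosswalk()` returns a validated crosswalk tibble.
#' @export
read_crosswalk <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  df <- check_crosswalk_columns(df)
  df$new_district_id[is.na(df$new_district_id)] <- ""
  viol <- validate_crosswalk(df)
  if (nrow(viol) > 0) {
    abort(paste0("invalid crosswalk file: ",
                 paste(unique(viol$violation), collapse = "; ")))
  }
  df
}

#' @rdname read_crosswalk
#' @param table A crosswalk tibble.
#' @export
write_crosswalk <- function(table, path) {
  table <- check_crosswalk_columns(table)
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
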