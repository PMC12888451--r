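#' Canonical outcome names
#'
#' The four self-reported problems in accessing healthcare tracked by the
#' package: getting money for treatment (`afford`), distance to a facility
#' (`prox`), getting permission to go (`perm`), and not wanting to go alone
#' (`support`). Record tables carry them as binary columns `y_afford`,
#' `y_prox`, `y_perm`, `y_support` where 1 codes "any problem" (the survey's
#' "big problem" and "not a big problem" responses pooled).
#'
#' @return Character vector of the four outcome keys.
#' @export
#' @examples
#' pahc_outcomes()
pahc_outcomes <- function() c("afford", "prox", "perm", "support")

#' @rdname pahc_outcomes
#' @export
pahc_outcome_labels <- function() {
  c(afford = "Affordability", prox = "Proximity",
    perm = "Permission", support = "Support/Companionship")
}

outcome_col <- function(outcome) {
  outcome <- match.arg(outcome, pahc_outcomes())
  paste0("y_", outcome)
}

record_columns <- function() {
  c("woman_id", "cluster_id", "district_id", "state_id", "round",
    "residence", "weight", paste0("y_", pahc_outcomes()))
}

#' Validate a table of survey records
#'
#' Checks the unit-record contract: required columns present, outcomes binary,
#' weights strictly positive, and the nesting consistent within each round
#' (every cluster in exactly one district, every district in exactly one
#' state).
#'
#' @param records A data frame of survey records.
#' @param require_rounds Optional character vector of round labels that must
#'   all be present.
#' @return `records` as a tibble, invisibly usable in a pipe.
#' @export
validate_records <- function(records, require_rounds = NULL) {
  records <- tibble::as_tibble(records)
  missing <- setdiff(record_columns(), names(records))
  if (length(missing) > 0) {
    abort(paste0("records are missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  for (oc in paste0("y_", pahc_outcomes())) {
    v <- records[[oc]]
    if (!all(v %in% c(0, 1))) {
      bad <- which(!v %in% c(0, 1))[1]
      abort(sprintf("column %s has non-binary value %s at row %d",
                    oc, as.character(v[bad]), bad))
    }
  }
  if (any(!is.finite(records$weight)) || any(records$weight <= 0)) {
    bad <- which(!is.finite(records$weight) | records$weight <= 0)[1]
    abort(sprintf("non-positive or non-finite weight at row %d", bad))
  }
  check_nesting(records)
  records
}

check_nesting <- function(records) {
  by_round <- split(records, records$round)
  for (rr in names(by_round)) {
    r <- by_round[[rr]]
    cd <- dplyr::distinct(r, .data$cluster_id, .data$district_id)
    if (anyDuplicated(cd$cluster_id)) {
      dup <- cd$cluster_id[duplicated(cd$cluster_id)][1]
      abort(sprintf("cluster %s maps to multiple districts in round %s",
                    as.character(dup), rr))
    }
    ds <- dplyr::distinct(r, .data$district_id, .data$state_id)
    if (anyDuplicated(ds$district_id)) {
      dup <- ds$district_id[duplicated(ds$district_id)][1]
      abort(sprintf("district %s maps to multiple states in round %s",
                    as.character(dup), rr))
    }
  }
  invisible(records)
}

# numerically stable log(1 + exp(x))
log1pexp <- function(x) {
  out <- x
  lo <- x <= 18
  out[lo] <- log1p(exp(x[lo]))
  mid <- x > 18 & x <= 33.3
  out[mid] <- x[mid] + exp(-x[mid])
  out
}

round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
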