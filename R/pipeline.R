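#' Configure an end-to-end pipeline run
#'
#' Collects everything [run_pipeline()] needs: the data source (either a
#' synthetic-population description or paths to record/crosswalk CSVs), the
#' MCMC settings, the strata to analyze, the output directory and the global
#' seed. Can also be loaded from a YAML file with the same field names via
#' `read_pipeline_config()`.
#'
#' @param outdir Output directory (created if absent).
#' @param seed Global integer seed; every stochastic stage derives its seed
#'   from it.
#' @param synthetic `NULL`, or a list describing the synthetic population:
#'   any [pahc_config()] arguments (shared by both rounds, or under
#'   `baseline`/`endline` sublists for round-specific values) plus an
#'   optional `scenario` list with [boundary_scenario()] arguments.
#' @param records_path,crosswalk_path Alternatively, CSV paths for real
#'   (pre-flattened) records containing both rounds, and the cluster
#'   crosswalk.
#' @param model A list of [mcmc_control()] arguments applied to every fit.
#' @param outcomes Outcomes to analyze.
#' @param strata Subset of `all`, `rural`, `urban`.
#' @param verbose Print stage-level progress.
#' @return A `pahc_run_config` list.
#' @export
pipeline_config <- function(outdir, seed,
                            synthetic = NULL,
                            records_path = NULL, crosswalk_path = NULL,
                            model = list(),
                            outcomes = pahc_outcomes(),
                            strata = "all",
                            verbose = TRUE) {
  if (is.null(synthetic) && is.null(records_path)) {
    abort("config needs either a synthetic population or a records_path")
  }
  bad <- setdiff(strata, c("all", "rural", "urban"))
  if (length(bad) > 0) abort("strata must be among all/rural/urban")
  bad <- setdiff(outcomes, pahc_outcomes())
  if (length(bad) > 0) {
    abort(paste0("unknown outcome(s): ", paste(bad, collapse = ", ")))
  }
  structure(list(outdir = outdir, seed = as.integer(seed),
                 synthetic = synthetic, records_path = records_path,
                 crosswalk_path = crosswalk_path, model = model,
                 outcomes = outcomes, strata = strata, verbose = verbose),
            class = "pahc_run_config")
}

#' @rdname pipeline_config
#' @param path YAML file whose top-level keys are `pipeline_config()`
#'   arguments.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  args <- yaml::read_yaml(path)
  do.call(pipeline_config, args)
}

stage <- function(name, verbose, code) {
  if (verbose) message(sprintf("[pahc] stage %s", name))
  tryCatch(force(code), error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)))
  })
}

synthetic_panel_from_config <- function(config) {
  syn <- config$synthetic
  scenario_args <- syn$scenario %||% list()
  shared <- syn[setdiff(names(syn), c("scenario", "baseline", "endline"))]
  round_cfg <- function(round) {
    args <- utils::modifyList(shared, syn[[round]] %||% list())
    if (is.null(args$seed)) args$seed <- config$seed
    do.call(pahc_config, args)
  }
  simulate_panel(round_cfg("baseline"), round_cfg("endline"),
                 do.call(boundary_scenario, scenario_args))
}

#' Run the full district-change analysis pipeline
#'
#' Sequences every stage: obtain records (simulate or read), harmonize the
#' baseline round through the crosswalk, fit the four-level MCMC model for
#' every outcome in both rounds (per stratum), derive precision-weighted
#' district estimates, tabulate weighted prevalence, problem combinations
#' and variance partitioning, classify district change against baseline
#' decile thresholds, and write every artifact as CSV/JSON plus a manifest.
#' Re-running with the same config and seed reproduces identical files.
#'
#' @param config A [pipeline_config()], or the path to a YAML file for
#'   [read_pipeline_config()].
#' @return The manifest (a list: artifact paths, seed, config hash, ESS
#'   summary), invisibly; also written as `manifest.json` in `outdir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pahc_run_config"))
  verbose <- isTRUE(config$verbose)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character()
  add <- function(name, write_fn) {
    path <- file.path(outdir, name)
    write_fn(path)
    artifacts <<- c(artifacts, name)
    path
  }

  data <- stage("data", verbose, {
    if (!is.null(config$synthetic)) {
      panel <- synthetic_panel_from_config(config)
      list(baseline = panel$baseline, endline = panel$endline,
           crosswalk = panel$crosswalk)
    } else {
      rec <- read_records(config$records_path)
      rounds <- sort(unique(rec$round))
      if (length(rounds) != 2) {
        abort(sprintf("records must contain exactly 2 rounds, found %d",
                      length(rounds)))
      }
      cw <- if (!is.null(config$crosswalk_path)) {
        read_crosswalk(config$crosswalk_path)
      }
      list(baseline = rec[rec$round == rounds[1], ],
           endline = rec[rec$round == rounds[2], ],
           crosswalk = cw)
    }
  })

  stage("validate", verbose, {
    if (is.null(data$crosswalk)) {
      mismatch <- setdiff(unique(data$baseline$district_id),
                          unique(data$endline$district_id))
      if (length(mismatch) > 0) {
        abort(paste0("district vintages differ and no crosswalk given; ",
                     "unmatched baseline district(s): ",
                     paste(head(mismatch, 5), collapse = ", ")))
      }
    }
  })

  harmonized <- stage("crosswalk", verbose, {
    if (is.null(data$crosswalk)) {
      data$baseline
    } else {
      mapped <- apply_crosswalk(data$baseline, data$crosswalk)
      add("crosswalk_report.csv", function(p)
        utils::write.csv(crosswalk_report(mapped), p, row.names = FALSE))
      add("crosswalk.csv", function(p) write_crosswalk(data$crosswalk, p))
      mapped
    }
  })
  records <- dplyr::bind_rows(harmonized, data$endline)

  model_args <- utils::modifyList(list(seed = config$seed), config$model)
  control <- do.call(mcmc_control, model_args)

  all_fits <- list()
  estimates <- list()
  for (str in config$strata) {
    res <- stage(paste0("fit_", str), verbose, {
      rec_s <- filter_stratum(records, str)
      ctl <- control
      ctl$seed <- (control$seed +
                     101L * match(str, c("all", "rural", "urban"))) %%
        .Machine$integer.max
      small_area_estimates(rec_s, config$outcomes, ctl)
    })
    names(res$fits) <- paste(str, names(res$fits), sep = ".")
    all_fits <- c(all_fits, res$fits)
    estimates[[str]] <- dplyr::mutate(res$districts, stratum = str)
  }
  districts <- dplyr::bind_rows(estimates)

  stage("estimate", verbose, {
    add("district_estimates.csv", function(p)
      districts |>
        dplyr::mutate(pct = round_half_up(100 * .data$p_hat, 2)) |>
        utils::write.csv(p, row.names = FALSE))
  })

  stage("summarize", verbose, {
    prev <- purrr::map_dfr(config$strata, function(str)
      weighted_prevalence(records, config$outcomes, stratum = str))
    add("prevalence.csv", function(p)
      utils::write.csv(prev, p, row.names = FALSE))
    cells <- purrr::map_dfr(config$strata, function(str)
      combination_table(records, stratum = str))
    add("combinations.csv", function(p)
      utils::write.csv(cells, p, row.names = FALSE))
    add("combination_margins.csv", function(p)
      utils::write.csv(combination_margins(cells), p, row.names = FALSE))
    vpcs <- purrr::imap_dfr(all_fits, function(f, nm)
      dplyr::mutate(vpc(f), stratum = sub("\\..*$", "", nm), .before = 1))
    add("vpc.csv", function(p) utils::write.csv(vpcs, p, row.names = FALSE))
  })

  stage("classify", verbose, {
    base_all <- districts[districts$stratum == "all" &
                            districts$round == unique(data$baseline$round), ]
    end_all <- districts[districts$stratum == "all" &
                           districts$round == unique(data$endline$round), ]
    chg <- change_table(base_all, end_all)
    add("change.csv", function(p)
      utils::write.csv(chg, p, row.names = FALSE))
    add("decile_thresholds.json", function(p) {
      th <- attr(chg, "thresholds")
      jsonlite::write_json(split(th$cut, th$outcome), p, digits = NA)
    })
    add("change_counts.csv", function(p)
      utils::write.csv(count_districts(chg), p, row.names = FALSE))
  })

  manifest <- stage("manifest", verbose, {
    ess_summary <- purrr::imap_dfr(all_fits, function(f, nm)
      dplyr::mutate(f$ess, fit = nm, .before = 1))
    # the hash covers the analysis-defining content, not where it is written
    cfg_for_hash <- unclass(config)
    cfg_for_hash$verbose <- NULL
    cfg_for_hash$outdir <- NULL
    m <- list(artifacts = sort(artifacts),
              seed = config$seed,
              config_hash = rlang::hash(cfg_for_hash),
              n_records = nrow(records),
              ess = ess_summary)
    add("manifest.json", function(p)
      jsonlite::write_json(m, p, auto_unbox = TRUE, digits = NA,
                           dataframe = "rows"))
    m
  })
  invisible(manifest)
}
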