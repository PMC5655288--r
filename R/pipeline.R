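#' Assemble a pipeline run configuration
#'
#' Exactly one cohort source must be given: a cohort tibble, a cohort file
#' path, or synthetic-cohort parameters.
#'
#' @param cohort A cohort tibble (as from [read_cohort()]).
#' @param cohort_file Path to a delimited cohort table.
#' @param synthetic A [cohort_params()] object (or plain list of its
#'   fields) for synthetic generation.
#' @param scenarios Scenarios to evaluate, a non-empty subset of `1:3`.
#' @param schedule,costs The [dose_schedule()] and [unit_costs()] to use.
#' @param seed Integer seed; overrides the seed inside `synthetic`.
#' @param breakeven Fit the scenario-1 vs scenario-2 break-even model
#'   (requires both scenarios).
#' @param stats_metrics Per-patient metrics compared across scenarios.
#' @return A `run_config` list.
#' @export
run_config <- function(cohort = NULL, cohort_file = NULL, synthetic = NULL,
                       scenarios = 1:3, schedule = dose_schedule(),
                       costs = unit_costs(), seed = NULL,
                       breakeven = TRUE,
                       stats_metrics = c("global_eur", "prep_hours",
                                         "admin_hours")) {
  sources <- !vapply(list(cohort, cohort_file, synthetic), is.null, TRUE)
  if (sum(sources) != 1) {
    rlang::abort("exactly one of cohort, cohort_file or synthetic must be given",
                 class = "trastucost_config_error")
  }
  scenarios <- unique(as.integer(scenarios))
  if (length(scenarios) == 0 || !all(scenarios %in% 1:3)) {
    rlang::abort("scenarios must be a non-empty subset of 1:3",
                 class = "trastucost_config_error")
  }
  if (!is.null(synthetic) && !inherits(synthetic, "cohort_params")) {
    synthetic <- do.call(cohort_params, synthetic)
  }
  if (!is.null(seed) && !is.null(synthetic)) synthetic$seed <- as.integer(seed)
  structure(list(cohort = cohort, cohort_file = cohort_file,
                 synthetic = synthetic, scenarios = scenarios,
                 schedule = schedule, costs = costs, seed = seed,
                 breakeven = breakeven, stats_metrics = stats_metrics),
            class = "run_config")
}

#' Run the full cost-minimization pipeline
#'
#' Acquires the cohort, evaluates the requested scenarios, builds the
#' report tables, fits the break-even model (when scenarios 1 and 2 are both
#' evaluated) and runs the scenario comparisons. One `message()` log line
#' is emitted per stage; suppress with [suppressMessages()].
#'
#' @param config A [run_config()].
#' @return A `run_report` list: `schema_version`, `cohort_summary`,
#'   `scenarios` (named list of `scenario_result`), `tables`, `breakeven`
#'   (a `breakeven_model` or `NULL`), `stats` (one comparison per metric),
#'   `curve_table`.
#' @export
#' @examples
#' cfg <- run_config(cohort = example_cohort(), scenarios = c(1, 2))
#' report <- suppressMessages(run_pipeline(cfg))
#' glance(report$scenarios[["2"]])
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cohort <- if (!is.null(config$cohort)) {
    validate_cohort(config$cohort)
  } else if (!is.null(config$cohort_file)) {
    read_cohort(config$cohort_file)
  } else {
    generate_cohort(config$synthetic)
  }
  summary <- summarize_cohort(cohort)
  message(sprintf("cohort: %d patients, %d IV cycles",
                  summary$n_patients, summary$total_iv_cycles))

  results <- lapply(config$scenarios, function(s) {
    r <- evaluate_scenario(cohort, s, config$schedule, config$costs)
    message(sprintf(
      "scenario %d: %d cycles, global %.2f EUR, %.1f prep h, %.1f chair h",
      s, r$drug_totals$iv_cycles + r$drug_totals$sc_cycles,
      r$totals$global_eur, r$time_profile$overall_prep_hours,
      r$time_profile$overall_admin_hours))
    r
  })
  names(results) <- as.character(config$scenarios)

  tables <- scenario_tables(results, cohort, config$schedule, config$costs)

  bkv <- NULL
  crv <- NULL
  if (config$breakeven && all(c(1, 2) %in% config$scenarios)) {
    bkv <- fit_breakeven_cohort(cohort, config$schedule, config$costs)
    grid <- seq(bkv$curves[[1]]$validity_range_kg[1],
                bkv$curves[[1]]$validity_range_kg[2], by = 1)
    crv <- curve_table(bkv$curves, grid)
    message(sprintf("break-even at %.2f kg", bkv$breakeven_kg[1]))
  }

  stats_out <- NULL
  if (length(results) >= 2 && length(config$stats_metrics) > 0) {
    stats_out <- lapply(stats::setNames(nm = config$stats_metrics),
                        function(m) compare_scenarios(results, m))
    message(sprintf("scenario comparison on %s: omnibus p = %.3g",
                    config$stats_metrics[1],
                    stats_out[[1]]$omnibus$p_value))
  }

  structure(list(schema_version = "1.0",
                 seed = config$seed,
                 scenarios_requested = config$scenarios,
                 cohort_summary = summary,
                 scenarios = results,
                 tables = tables,
                 breakeven = bkv,
                 curve_table = crv,
                 stats = stats_out),
            class = "run_report")
}

#' Serialize a run report to JSON
#'
#' All numeric fields are written at full precision so that
#' `read_report(write_report(x, f))` restores them losslessly (non-finite
#' values are carried through a string encoding). The file is written to a
#' temporary sibling and renamed into place, so a failed write never leaves
#' a truncated report.
#'
#' @param report A `run_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "run_report"))
  payload <- report_to_list(report)
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(payload, tmp, auto_unbox = TRUE, digits = NA,
                       na = "string", null = "null", pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

report_to_list <- function(report) {
  scen <- lapply(report$scenarios, function(r) {
    list(scenario = r$scenario, n_patients = r$n_patients,
         totals = as.list(r$totals),
         per_patient = r$per_patient,
         time_profile = r$time_profile,
         drug_totals = as.list(r$drug_totals))
  })
  list(schema_version = report$schema_version,
       seed = report$seed,
       scenarios_requested = report$scenarios_requested,
       cohort_summary = as.list(report$cohort_summary),
       scenarios = scen,
       tables = report$tables,
       breakeven = if (!is.null(report$breakeven)) {
         list(curves = tidy(report$breakeven),
              calibration = report$breakeven$calibration,
              breakeven_kg = report$breakeven$breakeven_kg)
       },
       curve_table = report$curve_table,
       stats = lapply(report$stats, function(s) {
         list(metric = s$metric, method = s$method,
              omnibus = glance(s$omnibus),
              groups = s$omnibus$groups,
              pairwise = s$pairwise)
       }))
}

#' Read a serialized run report
#'
#' @param path Path written by [write_report()].
#' @return A `run_report_data` list mirroring the report structure with
#'   tibbles restored; numeric fields equal the originals at full precision
#'   (`"NA"`/`"NaN"` strings restored to missing values).
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$schema_version) || !identical(x$schema_version, "1.0")) {
    rlang::abort(paste0("unsupported report schema version: ",
                        x$schema_version %||% "<missing>"),
                 class = "trastucost_schema_error")
  }
  restore_num <- function(df) {
    df[] <- lapply(df, function(col) {
      if (is.character(col) && all(col %in% c("NA", "NaN", "Inf", "-Inf") |
                                     !is.na(suppressWarnings(as.numeric(col))))) {
        as.numeric(ifelse(col == "NA", NA, col))
      } else col
    })
    tibble::as_tibble(df)
  }
  x$cohort_summary <- tibble::as_tibble(x$cohort_summary)
  x$scenarios <- lapply(x$scenarios, function(s) {
    s$per_patient <- restore_num(s$per_patient)
    s
  })
  x$tables <- lapply(x$tables, restore_num)
  if (!is.null(x$curve_table)) x$curve_table <- tibble::as_tibble(x$curve_table)
  if (!is.null(x$stats)) {
    x$stats <- lapply(x$stats, function(s) {
      s$pairwise <- restore_num(s$pairwise)
      s
    })
  }
  structure(x, class = "run_report_data")
}
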