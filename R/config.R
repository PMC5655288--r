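#' Build a run configuration from a YAML file
#'
#' The file has up to four sections. `cohort` selects the source: either
#' `source: file` with a `path`, or `source: synthetic` with an optional
#' `params` block of [cohort_params()] fields (the `weight` sub-block maps
#' to the truncated log-normal model). `dosing` and `costs` override
#' [dose_schedule()] and [unit_costs()] fields one-for-one. `run` holds
#' `scenarios`, `seed`, `breakeven` and `stats_metrics`.
#'
#' @param path Path to the YAML configuration.
#' @return A [run_config()].
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("config file not found: ", path),
                 class = "trastucost_config_error")
  }
  cfg <- yaml::read_yaml(path)
  cohort_cfg <- cfg$cohort %||% list(source = "synthetic")
  src <- cohort_cfg$source %||% "synthetic"
  cohort_file <- NULL
  synthetic <- NULL
  if (identical(src, "file")) {
    if (is.null(cohort_cfg$path)) {
      rlang::abort("cohort source 'file' needs a path",
                   class = "trastucost_config_error")
    }
    cohort_file <- cohort_cfg$path
  } else if (identical(src, "synthetic")) {
    synthetic <- do.call(cohort_params, cohort_cfg$params %||% list())
  } else {
    rlang::abort("cohort source must be 'file' or 'synthetic'",
                 class = "trastucost_config_error")
  }
  schedule <- do.call(dose_schedule, cfg$dosing %||% list())
  costs_cfg <- cfg$costs %||% list()
  if (!is.null(costs_cfg$admin_minutes)) {
    costs_cfg$admin_minutes <- unlist(costs_cfg$admin_minutes)
  }
  costs <- do.call(unit_costs, costs_cfg)
  run <- cfg$run %||% list()
  run_config(cohort_file = cohort_file, synthetic = synthetic,
             scenarios = run$scenarios %||% 1:3,
             schedule = schedule, costs = costs,
             seed = run$seed,
             breakeven = run$breakeven %||% TRUE,
             stats_metrics = unlist(run$stats_metrics %||%
                                      c("global_eur", "prep_hours",
                                        "admin_hours")))
}
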