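#' Read a patient-phase cohort table
#'
#' A cohort is a tidy table with one row per patient treatment phase. A phase
#' is a contiguous run of trastuzumab cycles at one cadence: `weekly` cycles
#' given concurrently with chemotherapy, or `q3w` (every-three-weeks) cycles
#' given after chemotherapy. Each phase carries at most one loading cycle
#' (the larger first dose) and any number of maintenance cycles.
#'
#' @param path Path to a delimited text file with columns `id`,
#'   `phase_index`, `cadence` (`"weekly"` or `"q3w"`), `n_loading` (0 or 1),
#'   `n_maintenance` and `weight_kg`.
#' @param delim Field delimiter, comma by default.
#' @return A validated cohort tibble with one row per patient-phase, phases
#'   ordered within patient.
#' @export
#' @examples
#' path <- system.file("extdata", "cohort_2014_synthetic.csv",
#'                     package = "trastucost")
#' cohort <- read_cohort(path)
#' summarize_cohort(cohort)
read_cohort <- function(path, delim = ",") {
  tab <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    id = readr::col_character(),
    phase_index = readr::col_integer(),
    cadence = readr::col_character(),
    n_loading = readr::col_double(),
    n_maintenance = readr::col_double(),
    weight_kg = readr::col_double()
  ), progress = FALSE)
  validate_cohort(tab)
}

#' Write a cohort table to delimited text
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(x, f))` reproduces
#' `x` up to numeric printing precision.
#'
#' @param cohort A cohort tibble.
#' @param path Output file path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, delim = ",") {
  cohort <- validate_cohort(cohort)
  readr::write_delim(cohort, path, delim = delim)
  invisible(path)
}

#' Validate a cohort table
#'
#' Checks the patient-phase contract: required columns present, weights in
#' the plausible 30-200 kg adult range and constant within patient, cadence
#' one of `weekly`/`q3w`, at most one loading cycle per phase, non-negative
#' integer cycle counts, no duplicated (id, phase_index) pair, and at least
#' one patient with at least one cycle each.
#'
#' @param cohort A data frame in the [read_cohort()] layout.
#' @return The cohort as a tibble, with phases ordered within patient.
#' @export
validate_cohort <- function(cohort) {
  required <- c("id", "phase_index", "cadence", "n_loading",
                "n_maintenance", "weight_kg")
  missing <- setdiff(required, names(cohort))
  if (length(missing) > 0) {
    rlang::abort(
      paste0("cohort table is missing column(s): ",
             paste(missing, collapse = ", ")),
      class = "trastucost_format_error"
    )
  }
  cohort <- tibble::as_tibble(cohort)
  if (nrow(cohort) == 0) {
    rlang::abort("cohort has no patients", class = "trastucost_validation_error")
  }
  bad_row <- function(what, rows) {
    rlang::abort(
      paste0(what, " (row ", paste(utils::head(rows, 5), collapse = ", "), ")"),
      class = "trastucost_validation_error"
    )
  }
  if (anyNA(cohort$weight_kg) || !is.numeric(cohort$weight_kg)) {
    bad_row("non-numeric or missing weight_kg", which(is.na(cohort$weight_kg)))
  }
  out_of_range <- which(cohort$weight_kg < 30 | cohort$weight_kg > 200)
  if (length(out_of_range) > 0) {
    bad_row("weight_kg outside the 30-200 kg range", out_of_range)
  }
  bad_cad <- which(!cohort$cadence %in% c("weekly", "q3w"))
  if (length(bad_cad) > 0) bad_row("cadence must be 'weekly' or 'q3w'", bad_cad)
  counts_ok <- function(x) !is.na(x) & x >= 0 & x == round(x)
  bad_n <- which(!counts_ok(cohort$n_loading) | !counts_ok(cohort$n_maintenance))
  if (length(bad_n) > 0) bad_row("cycle counts must be non-negative integers", bad_n)
  bad_load <- which(cohort$n_loading > 1)
  if (length(bad_load) > 0) bad_row("at most one loading cycle per phase", bad_load)
  dup <- which(duplicated(cohort[c("id", "phase_index")]))
  if (length(dup) > 0) bad_row("duplicated (id, phase_index)", dup)
  multi_w <- cohort |>
    dplyr::summarise(n_w = dplyr::n_distinct(.data$weight_kg), .by = "id") |>
    dplyr::filter(.data$n_w > 1)
  if (nrow(multi_w) > 0) {
    rlang::abort(
      paste0("inconsistent weight_kg within patient(s): ",
             paste(utils::head(multi_w$id, 5), collapse = ", ")),
      class = "trastucost_validation_error"
    )
  }
  no_cycles <- cohort |>
    dplyr::summarise(n = sum(.data$n_loading + .data$n_maintenance), .by = "id") |>
    dplyr::filter(.data$n == 0)
  if (nrow(no_cycles) > 0) {
    rlang::abort(
      paste0("patient(s) with zero cycles: ",
             paste(utils::head(no_cycles$id, 5), collapse = ", ")),
      class = "trastucost_validation_error"
    )
  }
  dplyr::arrange(cohort, .data$id, .data$phase_index)
}

#' Summarize a cohort
#'
#' One-row tibble of the aggregate structure used throughout the cost model:
#' patient count, weight median/range and quartile bounds (25th/50th/75th
#' percentiles by linear interpolation), and intravenous cycle tallies by
#' role (loading vs maintenance) and cadence (weekly vs q3w).
#'
#' @param cohort A cohort tibble.
#' @return A one-row tibble with columns `n_patients`, `median_weight_kg`,
#'   `weight_min`, `weight_max`, `weight_q1`, `weight_q2`, `weight_q3`,
#'   `total_iv_cycles`, `loading_cycles`, `maintenance_cycles`,
#'   `weekly_cycles`, `q3w_cycles`.
#' @export
summarize_cohort <- function(cohort) {
  cohort <- validate_cohort(cohort)
  patients <- dplyr::distinct(cohort, .data$id, .data$weight_kg)
  w <- patients$weight_kg
  q <- stats::quantile(w, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  tallies <- cohort |>
    dplyr::summarise(
      loading_cycles = sum(.data$n_loading),
      maintenance_cycles = sum(.data$n_maintenance),
      weekly_cycles = sum((.data$n_loading + .data$n_maintenance) *
                            (.data$cadence == "weekly")),
      q3w_cycles = sum((.data$n_loading + .data$n_maintenance) *
                         (.data$cadence == "q3w"))
    )
  tibble::tibble(
    n_patients = nrow(patients),
    median_weight_kg = stats::median(w),
    weight_min = min(w),
    weight_max = max(w),
    weight_q1 = q[1], weight_q2 = q[2], weight_q3 = q[3],
    total_iv_cycles = tallies$loading_cycles + tallies$maintenance_cycles,
    loading_cycles = tallies$loading_cycles,
    maintenance_cycles = tallies$maintenance_cycles,
    weekly_cycles = tallies$weekly_cycles,
    q3w_cycles = tallies$q3w_cycles
  )
}

#' The bundled reference cohort
#'
#' A constructed (synthetic) 114-patient cohort whose aggregate structure
#' matches the published 2014 institutional figures this package models:
#' 85 loading and 1,207 maintenance intravenous cycles (1,292 total), split
#' into 53 + 490 chemo-concurrent weekly cycles and 32 + 717 post-chemo q3w
#' cycles, with body weights solved so that total intravenous drug mass is
#' 372,214 mg and the weekly-phase (scenario 3 intravenous) portion is
#' 77,710 mg. Patient-level records of the original cohort were never
#' published; this table reproduces only its printed aggregates.
#'
#' @return A cohort tibble (167 patient-phase rows, 114 patients).
#' @export
example_cohort <- function() {
  read_cohort(system.file("extdata", "cohort_2014_synthetic.csv",
                          package = "trastucost", mustWork = TRUE))
}
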