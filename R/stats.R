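#' One-way analysis of variance
#'
#' Classical independent-groups between/within sum-of-squares decomposition:
#' `F = MSB / MSW` with `k - 1` and `N - k` degrees of freedom and the
#' p-value from the upper tail of the F distribution. When both the between-
#' and within-group sums of squares are zero (all observations identical),
#' F is defined as 0 with p = 1; zero within-variance with non-zero
#' between-variance gives `F = Inf`, p = 0.
#'
#' @param data A data frame with one observation per row, or a named list of
#'   numeric vectors (one per group).
#' @param value,group Columns holding the observation and the group label
#'   (tidy evaluation); ignored for list input.
#' @return An `anova_result`: `f_statistic`, `df_between`, `df_within`,
#'   `p_value`, and per-group `n`, `mean`, `sd` in `$groups`. Has `tidy()`
#'   and `glance()` methods.
#' @export
#' @examples
#' d <- data.frame(y = c(6, 8, 4, 5, 3, 4, 8, 12, 9, 11, 6, 8),
#'                 g = rep(c("a", "b"), each = 6))
#' one_way_anova(d, y, g)
one_way_anova <- function(data, value = value, group = group) {
  if (is.list(data) && !is.data.frame(data)) {
    groups <- data
    if (is.null(names(groups))) {
      names(groups) <- paste0("g", seq_along(groups))
    }
  } else {
    value <- rlang::enquo(value)
    group <- rlang::enquo(group)
    groups <- split(dplyr::pull(data, !!value),
                    dplyr::pull(data, !!group))
  }
  if (length(groups) < 2) {
    rlang::abort("need at least two groups", class = "trastucost_input_error")
  }
  if (any(vapply(groups, length, 1L) < 2)) {
    rlang::abort("every group needs at least two observations",
                 class = "trastucost_input_error")
  }
  n_i <- vapply(groups, length, 1L)
  m_i <- vapply(groups, mean, 1)
  grand <- sum(n_i * m_i) / sum(n_i)
  ssb <- sum(n_i * (m_i - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  df_b <- length(groups) - 1L
  df_w <- sum(n_i) - length(groups)
  if (ssw == 0 && ssb == 0) {
    f <- 0; p <- 1
  } else if (ssw == 0) {
    f <- Inf; p <- 0
  } else {
    f <- (ssb / df_b) / (ssw / df_w)
    p <- stats::pf(f, df_b, df_w, lower.tail = FALSE)
  }
  structure(list(
    f_statistic = f, df_between = df_b, df_within = df_w, p_value = p,
    ss_between = ssb, ss_within = ssw,
    groups = tibble::tibble(group = names(groups), n = n_i,
                            mean = m_i,
                            sd = vapply(groups, stats::sd, 1))
  ), class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$f_statistic, x$p_value))
  invisible(x)
}

#' Per-group summary of an ANOVA result
#' @param x An `anova_result`.
#' @param ... Unused.
#' @return The per-group tibble (`group`, `n`, `mean`, `sd`).
#' @method tidy anova_result
#' @export
tidy.anova_result <- function(x, ...) x$groups

#' One-row summary of an ANOVA result
#' @param x An `anova_result`.
#' @param ... Unused.
#' @return One-row tibble with the F statistic, degrees of freedom and
#'   p-value.
#' @method glance anova_result
#' @export
glance.anova_result <- function(x, ...) {
  tibble::tibble(f_statistic = x$f_statistic, df_between = x$df_between,
                 df_within = x$df_within, p_value = x$p_value)
}

#' Bonferroni-adjusted pairwise comparisons
#'
#' Two-sided two-sample t-tests for every pair of groups, with pooled
#' (equal-variance) standard errors by default, and Bonferroni adjustment
#' `min(1, m p)` over the `m` pairs. Mirrors the gatekeeping convention of
#' running post-hoc tests only after a significant omnibus F-test: when an
#' omnibus result is supplied and its p-value is at or above `alpha`, the
#' pairwise table is still returned but flagged `gate_passed = FALSE`.
#'
#' @param data Data frame or named list of numeric vectors, as in
#'   [one_way_anova()].
#' @param value,group Tidy-eval columns for data-frame input.
#' @param omnibus Optional `anova_result` used for gatekeeping.
#' @param var_equal Pooled-variance t-tests (`TRUE`, default) or Welch.
#' @param alpha Two-sided significance threshold.
#' @return A tibble with one row per pair: `group_a`, `group_b`,
#'   `estimate` (mean difference a - b), `statistic`, `df`, `p_value`,
#'   `p_adjusted`, `significant`, `gate_passed`.
#' @export
bonferroni_pairwise <- function(data, value = value, group = group,
                                omnibus = NULL, var_equal = TRUE,
                                alpha = 0.05) {
  if (is.list(data) && !is.data.frame(data)) {
    groups <- data
    if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  } else {
    value <- rlang::enquo(value)
    group <- rlang::enquo(group)
    groups <- split(dplyr::pull(data, !!value), dplyr::pull(data, !!group))
  }
  if (length(groups) < 2) {
    rlang::abort("need at least two groups", class = "trastucost_input_error")
  }
  if (any(vapply(groups, length, 1L) < 2)) {
    rlang::abort("every group needs at least two observations",
                 class = "trastucost_input_error")
  }
  pairs <- utils::combn(names(groups), 2)
  m <- ncol(pairs)
  res <- purrr::map_dfr(seq_len(m), function(j) {
    a <- groups[[pairs[1, j]]]
    b <- groups[[pairs[2, j]]]
    est <- mean(a) - mean(b)
    if (var_equal) {
      df <- length(a) + length(b) - 2
      sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / df
      se <- sqrt(sp2 * (1 / length(a) + 1 / length(b)))
    } else {
      va <- stats::var(a) / length(a)
      vb <- stats::var(b) / length(b)
      se <- sqrt(va + vb)
      df <- (va + vb)^2 /
        (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
    }
    tstat <- if (se == 0) {
      if (est == 0) 0 else sign(est) * Inf
    } else est / se
    p <- if (is.infinite(tstat)) 0 else
      2 * stats::pt(-abs(tstat), df)
    tibble::tibble(group_a = pairs[1, j], group_b = pairs[2, j],
                   estimate = est, statistic = tstat, df = df, p_value = p)
  })
  gate <- if (is.null(omnibus)) TRUE else omnibus$p_value < alpha
  res |>
    dplyr::mutate(p_adjusted = pmin(1, m * .data$p_value),
                  significant = .data$p_adjusted < alpha & gate,
                  gate_passed = gate)
}

#' Compare scenarios on a per-patient metric
#'
#' Assembles the per-patient vectors of several scenario results and runs
#' the omnibus one-way ANOVA followed by Bonferroni-adjusted pairwise
#' comparisons. The scenarios are counterfactual treatments of the same
#' cohort, i.e. correlated samples; the source analysis nevertheless used
#' independent-groups ANOVA, which is the default here. `method =
#' "repeated"` instead removes the per-patient mean (one-way
#' repeated-measures decomposition with `(n - 1)(k - 1)` error degrees of
#' freedom) for the omnibus test.
#'
#' @param results List of `scenario_result` objects.
#' @param metric Per-patient column to compare: one of `"global_eur"`,
#'   `"drug_eur"`, `"waste_eur"`, `"prep_eur"`, `"clinic_eur"`,
#'   `"prep_hours"`, `"admin_hours"`.
#' @param method `"independent"` (as published) or `"repeated"`.
#' @param var_equal Passed to [bonferroni_pairwise()].
#' @return List with `metric`, `method`, `omnibus` (`anova_result`) and
#'   `pairwise` (tibble).
#' @export
compare_scenarios <- function(results, metric = "global_eur",
                              method = c("independent", "repeated"),
                              var_equal = TRUE) {
  method <- match.arg(method)
  long <- purrr::map_dfr(results, function(r) {
    tibble::tibble(scenario = paste0("scenario_", r$scenario),
                   patient_id = r$per_patient$patient_id,
                   value = r$per_patient[[metric]])
  })
  omnibus <- if (method == "independent") {
    one_way_anova(long, value, scenario)
  } else {
    repeated_anova(long)
  }
  pairwise <- bonferroni_pairwise(long, value, scenario,
                                  omnibus = omnibus, var_equal = var_equal)
  list(metric = metric, method = method, omnibus = omnibus,
       pairwise = pairwise)
}

# one-way repeated-measures decomposition: treatment SS as in the
# independent case, error SS = within SS minus subject SS
repeated_anova <- function(long) {
  wide <- tidyr::pivot_wider(long, names_from = "scenario",
                             values_from = "value")
  mat <- as.matrix(wide[, setdiff(names(wide), "patient_id")])
  if (anyNA(mat)) {
    rlang::abort("repeated-measures comparison needs every patient in every scenario",
                 class = "trastucost_input_error")
  }
  n <- nrow(mat); k <- ncol(mat)
  grand <- mean(mat)
  ss_treat <- n * sum((colMeans(mat) - grand)^2)
  ss_subj <- k * sum((rowMeans(mat) - grand)^2)
  ss_tot <- sum((mat - grand)^2)
  ss_err <- ss_tot - ss_treat - ss_subj
  df_t <- k - 1L; df_e <- (n - 1L) * (k - 1L)
  f <- (ss_treat / df_t) / (ss_err / df_e)
  structure(list(
    f_statistic = f, df_between = df_t, df_within = df_e,
    p_value = stats::pf(f, df_t, df_e, lower.tail = FALSE),
    ss_between = ss_treat, ss_within = ss_err,
    groups = tibble::tibble(group = colnames(mat), n = n,
                            mean = colMeans(mat),
                            sd = apply(mat, 2, stats::sd))
  ), class = "anova_result")
}
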