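# Cohort-level comparisons: best response by group (rank-sum) and
# progression-free survival by group (Kaplan-Meier / log-rank),
# honoring censoring flags.

#' Compare patient groups on best response and survival
#'
#' Summarises RECIST best response (mean percent change of the
#' target-lesion sum) per group and tests the difference with the
#' Wilcoxon rank-sum test; fits Kaplan-Meier curves on
#' progression-free survival, honoring censoring
#' (`progression_event = FALSE` means censored at `pfs_days`), and
#' tests with the log-rank test. Groups with a single member are
#' reported but tests are flagged underpowered.
#'
#' @param patients Patient tibble with `pfs_days`, `progression_event`,
#'   `best_response_pct` and the grouping column.
#' @param group Name of the grouping column.
#' @return List: `summary` (per-group tibble), `response_p`
#'   (rank-sum), `logrank_p`, `survfit` (the fitted KM object) and
#'   `underpowered`.
#' @export
cohort_compare <- function(patients, group) {
  check_columns(
    patients,
    c(group, "pfs_days", "progression_event", "best_response_pct"),
    "patients"
  )
  g <- factor(patients[[group]])
  if (nlevels(g) < 2 || any(table(g) < 1)) {
    abort_validation("need >= 2 non-empty groups")
  }
  summary_tbl <- patients %>%
    group_by(.data[[group]]) %>%
    summarise(
      n = dplyr::n(),
      mean_best_response_pct = mean(.data$best_response_pct, na.rm = TRUE),
      median_pfs_days = median(.data$pfs_days, na.rm = TRUE),
      n_events = sum(.data$progression_event, na.rm = TRUE),
      .groups = "drop"
    )
  underpowered <- any(table(g) < 2) || nlevels(g) != 2
  response_p <- if (!underpowered) {
    wilcox.test(best_response_pct ~ g,
      data = patients, exact = FALSE
    )$p.value
  } else {
    NA_real_
  }
  surv <- survival::Surv(patients$pfs_days, patients$progression_event)
  km <- survival::survfit(surv ~ g)
  logrank_p <- if (!underpowered) {
    sd <- survival::survdiff(surv ~ g)
    stats::pchisq(sd$chisq, df = length(sd$n) - 1, lower.tail = FALSE)
  } else {
    NA_real_
  }
  list(
    summary = summary_tbl, response_p = response_p, logrank_p = logrank_p,
    survfit = km, underpowered = underpowered
  )
}
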