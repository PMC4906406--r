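# ggplot2 displays for the main result types.

#' @describeIn run_spike_grid Detection rate versus ctDNA fraction per
#'   gene.
#' @param object A `spike_result` tibble.
#' @param ... Unused.
#' @export
autoplot.spike_result <- function(object, ...) {
  df <- object %>%
    group_by(.data$gene, .data$fraction_pct) %>%
    summarise(detection_rate = mean(.data$detected), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$fraction_pct, y = 100 * .data$detection_rate,
    colour = .data$gene
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "ctDNA fraction (%)", y = "Detection rate (%)", colour = "Gene",
      title = "Copy-number detection sensitivity by spiked ctDNA fraction"
    )
}

#' @describeIn fit_control_model Per-region control means with +/- 2
#'   sigma ribbons, faceted by gene.
#' @param object A `control_model`.
#' @export
autoplot.control_model <- function(object, ...) {
  df <- object$regions %>%
    filter(!.data$excluded) %>%
    group_by(.data$gene) %>%
    mutate(region_index = dplyr::row_number()) %>%
    ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region_index, y = .data$mu)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = .data$mu - 2 * .data$sigma,
        ymax = .data$mu + 2 * .data$sigma
      ),
      fill = "grey80"
    ) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~gene, scales = "free_x") +
    ggplot2::labs(
      x = "Region (within gene)", y = "log2 normalized depth",
      title = "Healthy-control depth model (mean +/- 2 sd per region)"
    )
}

#' Plot T790M:activating ratio trajectories
#'
#' One line per patient across timepoints; censored ratios are drawn as
#' open points (they are upper bounds).
#'
#' @param ratio_tbl Tibble with `patient_id`, `timepoint`, `ratio`,
#'   `censored` (e.g. rows of [ratio_trajectory()]'s `per_timepoint`
#'   bound over patients).
#' @return A ggplot object.
#' @export
plot_ratio_trajectory <- function(ratio_tbl) {
  ratio_tbl <- ratio_tbl %>%
    mutate(timepoint = factor(.data$timepoint, levels = .timepoint_levels))
  ggplot2::ggplot(ratio_tbl, ggplot2::aes(
    x = .data$timepoint, y = .data$ratio, group = .data$patient_id
  )) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$censored)) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1)) +
    ggplot2::labs(
      x = NULL, y = "T790M : activating mutation ratio",
      shape = "Censored",
      title = "Clonal ratio trajectories under therapy"
    )
}
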