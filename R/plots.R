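#' Plot concentration-time profiles
#'
#' Semi-log (default) spaghetti plot of per-subject profiles, coloured by
#' route. Zero concentrations are dropped on the log scale.
#'
#' @param concentrations Tibble with `subject_id`, `route`, `time_h`,
#'   `conc_mg_per_L` (as produced by [simulate_study()] or read from CSV).
#' @param log_y Use a log10 concentration axis?
#' @return A ggplot object.
#' @export
plot_profiles <- function(concentrations, log_y = TRUE) {
  stopifnot(is.data.frame(concentrations))
  df <- concentrations
  if (log_y) df <- df[df$conc_mg_per_L > 0, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$time_h, y = .data$conc_mg_per_L,
    group = interaction(.data$subject_id, .data$route),
    colour = .data$route)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(x = "Time (h)", y = "Concentration (mg/L)",
                  colour = "Route") +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' @export
autoplot.kirch_study <- function(object, ...) {
  plot_profiles(object$concentrations, ...)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot gut-to-iv clearance ratios
#'
#' Dot plot of the estimated gut-to-iv clearance ratio per drug on a log
#' scale. Ratios near or below ~3 indicate studies where clearance from the
#' absorption site limited the measured oral clearance (the regime in which
#' AUC-based bioavailability overestimates the urinary value); large ratios
#' recover the textbook behaviour in which input has no effect on measured
#' clearance.
#'
#' @param table A tibble from [build_gut_clearance_table()].
#' @return A ggplot object.
#' @export
plot_gut_clearance <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("drug", "ratio_gut_over_iv") %in% names(table)))
  df <- table[table$feasible, ]
  df$drug <- stats::reorder(df$drug, df$ratio_gut_over_iv)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ratio_gut_over_iv,
                                   y = .data$drug)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "CL(gut) / CL(iv)", y = NULL) +
    ggplot2::theme_minimal()
}
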