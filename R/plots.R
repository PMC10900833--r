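#' Plot a concentration-time profile
#'
#' @param object A [simulate_profile()] result.
#' @param by Sampling resolution in hours.
#' @param thresholds Optional named numeric vector of horizontal reference
#'   lines (mg/L), e.g. `c(MIC = 8, toxicity = 20)`.
#' @param ... Unused.
#' @return A ggplot object: total and free concentration vs time, with KRT
#'   sessions shaded.
#' @method autoplot conc_profile
#' @export
autoplot.conc_profile <- function(object, by = 0.05, thresholds = NULL, ...) {
  df <- tidy.conc_profile(object, by = by) |>
    tidyr::pivot_longer(c("total", "free"), names_to = "scale",
                        values_to = "conc")
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$conc,
                                        colour = .data$scale)) +
    ggplot2::geom_rect(
      data = object$schedule$sessions,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf, inherit.aes = FALSE,
      fill = "grey85", alpha = 0.6) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time since simulation origin (h)",
                  y = "plasma concentration (mg/L)",
                  colour = NULL,
                  title = paste(object$drug %||% "drug", "-",
                                object$regimen$label),
                  subtitle = object$schedule$name) +
    ggplot2::theme_minimal()
  if (!is.null(thresholds))
    p <- p + ggplot2::geom_hline(yintercept = thresholds, linetype = "dashed")
  p
}

#' Plot per-day probability of target attainment
#'
#' @param object A [pta()] table.
#' @param floor Reference PTA floor in percent (drawn as a dashed line).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pta_table
#' @export
autoplot.pta_table <- function(object, floor = 90, ...) {
  ggplot2::ggplot(object, ggplot2::aes(factor(.data$day), .data$pta)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = floor, linetype = "dashed") +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::labs(x = "day of therapy", y = "PTA (%)") +
    ggplot2::theme_minimal()
}

#' Plot a regimen report: PTA and toxicity by day
#'
#' @param object A [evaluate_regimen()] report.
#' @param ... Unused.
#' @return A ggplot object faceted by PIKRT variant where applicable.
#' @method autoplot regimen_report
#' @export
autoplot.regimen_report <- function(object, ...) {
  df <- tidyr::pivot_longer(object$by_day, c("pta", "toxicity"),
                            names_to = "metric", values_to = "percent")
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$day, .data$percent,
                                        colour = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 90, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::scale_x_continuous(breaks = 1:7) +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::labs(title = paste(object$drug, "-", object$regimen$label),
                  subtitle = paste("setting", object$setting, "-",
                                   object$target$label),
                  x = "day of therapy", y = "% of cohort", colour = NULL) +
    ggplot2::theme_minimal()
  if (length(unique(df$variant)) > 1)
    p <- p + ggplot2::facet_wrap(~variant)
  p
}
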