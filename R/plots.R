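# ggplot2 views of the main result types.

#' Plot a one-day trajectory
#'
#' Biological requirements, investment, and debt over one day, with the
#' sleep phase shaded.
#'
#' @param object An `ea_trajectory` from [integrate_day()].
#' @param vars Which state variables to draw (subset of `BR`, `BI`, `BD`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ea_trajectory <- function(object, vars = c("BR", "BI", "BD"), ...) {
  params <- attr(object, "params")
  long <- tidyr::pivot_longer(as_tibble(object), dplyr::all_of(vars),
                              names_to = "variable", values_to = "value")
  gg <- ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$value,
                                           colour = .data$variable))
  if (!is.null(params) && params$TST_h > 0) {
    gg <- gg + ggplot2::annotate("rect", xmin = switch_time(params), xmax = 1,
                                 ymin = -Inf, ymax = Inf, alpha = 0.12)
  }
  gg +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "time (days)", y = "arbitrary units", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a parameter sweep
#'
#' One-dimensional sweeps are drawn as the three energy-savings curves
#' (rho, MAI, total) against the swept variable; the two-dimensional
#' MAI-by-amplitude sweep as a tile map of total savings.
#'
#' @param object An `ea_sweep` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ea_sweep <- function(object, ...) {
  swept <- attr(object, "swept")
  tbl <- as_tibble(object)
  if (length(swept) == 2) {
    return(
      ggplot2::ggplot(tbl, ggplot2::aes(.data[[swept[1]]], .data[[swept[2]]],
                                        fill = .data$es_total)) +
        ggplot2::geom_tile() +
        ggplot2::labs(fill = "ES total (%)") +
        ggplot2::theme_minimal()
    )
  }
  if (length(swept) == 3) {
    return(
      ggplot2::ggplot(tbl[tbl$exists %in% TRUE, ],
                      ggplot2::aes(factor(.data$m_C), .data$es_total)) +
        ggplot2::geom_boxplot() +
        ggplot2::labs(x = "circadian mean level m_C",
                      y = "ES total (%)") +
        ggplot2::theme_minimal()
    )
  }
  long <- tidyr::pivot_longer(tbl, c("es_rho", "es_mai", "es_total"),
                              names_to = "component", values_to = "es")
  ggplot2::ggplot(long, ggplot2::aes(.data[[swept]], .data$es,
                                     colour = .data$component)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(y = "energy savings (%)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a multi-day run
#'
#' The continuous debt series with dashed daily-mean markers, the view
#' used to diagnose steady state versus escalating debt under sleep
#' restriction.
#'
#' @param object An `ea_multiday` from [multiday_run()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ea_multiday <- function(object, ...) {
  series <- attr(object, "series")
  means <- as_tibble(object)
  ggplot2::ggplot(series, ggplot2::aes(.data$t, .data$BD)) +
    ggplot2::geom_line(linewidth = 0.5) +
    ggplot2::geom_segment(
      data = means,
      ggplot2::aes(x = .data$day - 1, xend = .data$day,
                   y = .data$mean_bd, yend = .data$mean_bd),
      linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::labs(x = "time (days)", y = "biological debt") +
    ggplot2::theme_minimal()
}

#' Plot the daily Poincare map
#'
#' The return map `P(BD0)` against the identity line; intersections are
#' the daily limit cycles.
#'
#' @param params An [ea_params()] object.
#' @param interval Range of start-of-day debt to draw.
#' @param n Number of map evaluations.
#' @return A ggplot object.
#' @export
plot_poincare <- function(params, interval = c(0.05, 3), n = 60) {
  bd0 <- exp(seq(log(interval[1]), log(interval[2]), length.out = n))
  tbl <- tibble(bd0 = bd0, P = poincare_map(params, bd0))
  ggplot2::ggplot(tbl, ggplot2::aes(.data$bd0, .data$P)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey50") +
    ggplot2::geom_line(colour = "steelblue", linewidth = 0.7) +
    ggplot2::labs(x = "BD at start of day", y = "BD at end of day") +
    ggplot2::theme_minimal()
}
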