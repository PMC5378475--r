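#' Plot Kaplan-Meier survival curves
#'
#' Step-function survival curves per group, drawn from a [km_estimate()]
#' table.
#'
#' @param object A `km_curve` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.km_curve <- function(object, ...) {
  start <- object |>
    distinct(.data$group) |>
    mutate(time = 0, survival = 1)
  dat <- bind_rows(start, object[, c("group", "time", "survival")]) |>
    arrange(.data$group, .data$time)
  ggplot2::ggplot(dat, ggplot2::aes(.data$time, .data$survival,
                                    colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Day of adulthood", y = "Fraction alive",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a male-fraction trajectory
#'
#' Male fraction per generation for one or more trajectories (deterministic
#' recursion or stochastic simulation). If the table carries an `r` column
#' (as produced by the pipeline's demography stage) each factor gets its own
#' curve.
#'
#' @param object A `sex_ratio_trajectory` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sex_ratio_trajectory <- function(object, ...) {
  p <- if ("r" %in% names(object)) {
    ggplot2::ggplot(object, ggplot2::aes(.data$generation, .data$male_fraction,
                                         colour = factor(.data$r))) +
      ggplot2::labs(colour = "r")
  } else {
    ggplot2::ggplot(object, ggplot2::aes(.data$generation, .data$male_fraction))
  }
  p +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = "Generation", y = "Males in population") +
    ggplot2::theme_minimal()
}
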