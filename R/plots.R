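#' Plot a trajectory of the signaling model
#'
#' Faceted time series of the state variables (and the influx f) of an
#' integrated trajectory.
#'
#' @param object an `imd_trajectory` from [integrate_model()].
#' @param components which columns to show; defaults to every state
#'   variable plus the influx.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot imd_trajectory
#' @export
autoplot.imd_trajectory <- function(object,
                                    components = setdiff(names(object),
                                                         "time"),
                                    ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(as_tibble(object), "time",
                  dplyr::all_of(components)),
    -"time", names_to = "component", values_to = "value") |>
    dplyr::mutate(component = factor(.data$component,
                                     levels = c("f", state_names())))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(x = "time", y = "concentration") +
    ggplot2::theme_minimal()
}

#' Heat map of the relative fitness of the two strategies
#'
#' Density-by-patchiness heat map of `delta_F = F_constitutive -
#' F_induced`: red cells favor the induced strategy, blue cells the
#' constitutive one.
#'
#' @param object a `fitness_grid` from [run_fitness_grid()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot fitness_grid
#' @export
autoplot.fitness_grid <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = factor(.data$patchiness),
                               y = factor(.data$density),
                               fill = .data$delta_F)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", midpoint = 0,
                                  name = expression(Delta * F)) +
    ggplot2::labs(x = "patchiness (p)", y = "density (d)") +
    ggplot2::theme_minimal()
}

#' Proportion-of-induced-wins curve
#'
#' Line plot of PIW against the number of sampled environments (or the
#' two-environment weight q), as produced by repeated calls to
#' [sample_multi_environment()].
#'
#' @param data a data frame with a `piw` column and either `j` or `q`.
#' @param x which column to put on the x axis (default `"j"`).
#' @return A ggplot object.
#' @export
plot_piw_curve <- function(data, x = c("j", "q")) {
  x <- match.arg(x)
  ggplot2::ggplot(data, ggplot2::aes(x = .data[[x]], y = .data$piw)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        color = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = if (x == "j") "number of environments" else
      "weight of environment 1 (q)", y = "proportion of induced wins") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
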