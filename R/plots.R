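#' @method autoplot terrain_params
#' @export
autoplot.terrain_params <- function(object, n = 151, critical_points = FALSE, ...) {
  g <- terrain_grid(object, n = n)
  p <- ggplot2::ggplot(g, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$concentration)) +
    ggplot2::scale_fill_viridis_c(name = "C(x, y)") +
    ggplot2::annotate("point", x = object$target[1], y = object$target[2],
                      shape = 4, size = 3, colour = "white") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Concentration terrain",
                  subtitle = "x marks the target (global maximum)")
  if (critical_points) {
    cp <- find_critical_points(object)
    if (nrow(cp))
      p <- p + ggplot2::geom_point(
        data = cp, ggplot2::aes(shape = .data$class), colour = "red", size = 2)
  }
  p
}

#' @method autoplot swarm_trajectory
#' @export
autoplot.swarm_trajectory <- function(object, ...) {
  df <- tidy(object)
  terrain <- object$config$terrain
  g <- terrain_grid(terrain, n = 121)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(data = g, ggplot2::aes(fill = .data$concentration)) +
    ggplot2::scale_fill_viridis_c(name = "C") +
    ggplot2::geom_path(ggplot2::aes(group = .data$agent), colour = "white",
                       linewidth = 0.2, alpha = 0.7) +
    ggplot2::annotate("point", x = terrain$target[1], y = terrain$target[2],
                      shape = 4, size = 3, colour = "red") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Swarm trajectories (%s policy)",
                                  object$config$policy$mode))
}

#' @method autoplot swarm_sweep
#' @export
autoplot.swarm_sweep <- function(object, metric = "median_path_length", ...) {
  gl <- object$runs %>%
    group_by(.data$value) %>%
    summarise(mean = mean(.data[[metric]], na.rm = TRUE),
              se = sd(.data[[metric]], na.rm = TRUE) /
                sqrt(sum(!is.na(.data[[metric]]))))
  ggplot2::ggplot(gl, ggplot2::aes(.data$value, .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$se,
                                          ymax = .data$mean + .data$se)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = object$parameter, y = paste("mean", metric),
                  title = sprintf("Sweep of %s", object$parameter),
                  subtitle = "error bars: standard error over rounds")
}

#' @method autoplot mechanism_comparison
#' @export
autoplot.mechanism_comparison <- function(object, ...) {
  df <- mutate(object$runs,
               path = ifelse(.data$censored, NA, .data$median_path_length))
  ggplot2::ggplot(df, ggplot2::aes(.data$mechanism, .data$path)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.4) +
    ggplot2::labs(y = "median path length (censored runs dropped)",
                  title = "Navigation path length by interaction mechanism")
}
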