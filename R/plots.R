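finite_cells <- function(cells) {
  cells |> filter(is.finite(.data$chi_mid), is.finite(.data$theta_mid))
}

#' Plot a two-axis displacement density map
#'
#' Tilt magnitude (log bins) on the vertical axis, signed twist displacement
#' on the horizontal; overflow cells are omitted from the plot (they remain
#' in the object's normalisation).
#'
#' @param object A `two_axis_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.two_axis_map <- function(object, ...) {
  cells <- finite_cells(tidy(object))
  ggplot(cells, aes(x = .data$chi_mid, y = factor(signif(.data$theta_mid, 3)),
                    fill = .data$density)) +
    geom_tile() +
    labs(x = expression(Delta * chi ~ "(mrad)"),
         y = expression("|" * Delta * theta * "| (mrad, log bins)"),
         fill = "density", title = object$label) +
    theme_minimal()
}

#' Plot a two-axis subtraction map
#'
#' Diverging fill: positive cells are dominated by the first condition,
#' negative by the second.
#'
#' @param object A `subtraction_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.subtraction_map <- function(object, ...) {
  cells <- finite_cells(tidy(object))
  ggplot(cells, aes(x = .data$chi_mid, y = factor(signif(.data$theta_mid, 3)),
                    fill = .data$difference)) +
    geom_tile() +
    scale_fill_gradient2() +
    labs(x = expression(Delta * chi ~ "(mrad)"),
         y = expression("|" * Delta * theta * "| (mrad, log bins)"),
         fill = sprintf("%s - %s", object$labels[1], object$labels[2])) +
    theme_minimal()
}

#' Plot a mixture fit over its displacement histogram
#'
#' @param object A `mixture_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mixture_fit <- function(object, ...) {
  h <- object$histogram
  grid <- seq(min(h$mid), max(h$mid), length.out = 300)
  comp <- object$components
  curves <- bind_rows(lapply(seq_len(nrow(comp)), function(j) {
    tibble(component = factor(j), x = grid,
           y = comp$area_fraction[j] * object$n_values * object$bin_width *
             dnorm(grid, comp$mean[j], comp$sd[j]))
  }))
  ggplot(h, aes(x = .data$mid, y = .data$count)) +
    geom_col(fill = "grey80", width = object$bin_width) +
    geom_line(data = curves,
              aes(x = .data$x, y = .data$y, colour = .data$component)) +
    labs(x = expression(Delta * chi ~ "(mrad)"), y = "count") +
    theme_minimal()
}

#' Plot MSD curves with optional anomalous-diffusion fits
#'
#' @param curves An ensemble (or per-track) MSD tibble.
#' @param fits Optional named list of `anomalous_fit` objects to overlay.
#' @return A ggplot object.
#' @export
plot_msd <- function(curves, fits = NULL) {
  p <- ggplot(curves, aes(x = .data$lag_ms, y = .data$msd,
                          colour = .data$axis)) +
    geom_point() +
    labs(x = "lag (ms)", y = expression("MSD (mrad"^2 * ")")) +
    theme_minimal()
  if (!is.null(fits)) {
    lines <- bind_rows(lapply(names(fits), function(nm) {
      f <- fits[[nm]]
      tibble(axis = nm, lag_ms = f$fitted$lag_ms,
             msd = f$fitted$fitted)
    }))
    p <- p + geom_line(data = lines)
  }
  p
}
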