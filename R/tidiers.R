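#' Tidy an anomalous-diffusion fit
#'
#' @param x An `anomalous_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per parameter; `glance()`: a one-row model
#'   summary.
#' @export
tidy.anomalous_fit <- function(x, ...) {
  tibble(term = c("D_alpha", "alpha", "beta"),
         estimate = c(x$D_alpha, x$alpha, x$beta))
}

#' @rdname tidy.anomalous_fit
#' @export
glance.anomalous_fit <- function(x, ...) {
  tibble(D_alpha = x$D_alpha, alpha = x$alpha, beta = x$beta,
         regime = x$regime, n_lags = x$n_lags,
         residual_norm = x$residual_norm)
}

#' Tidy a Gaussian mixture fit
#'
#' @param x A `mixture_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per component (mean, variance, area fraction,
#'   role); `glance()`: a one-row fit summary.
#' @export
tidy.mixture_fit <- function(x, ...) {
  x$components |> mutate(component = row_number()) |>
    select("component", "mean", "variance", "sd", "area_fraction", "role")
}

#' @rdname tidy.mixture_fit
#' @export
glance.mixture_fit <- function(x, ...) {
  tibble(n_components = x$n_components, n_values = x$n_values,
         rss = x$rss, bin_width = x$bin_width)
}

#' Tidy a lifetime-filter result
#'
#' @param x A `lifetime_filter`.
#' @param ... Unused.
#' @return `tidy()`: per-track lifetimes with their class; `glance()`: counts
#'   and the short:long ratio.
#' @export
tidy.lifetime_filter <- function(x, ...) {
  x$lifetimes
}

#' @rdname tidy.lifetime_filter
#' @export
glance.lifetime_filter <- function(x, ...) {
  tibble(short_count = x$short_count, long_count = x$long_count,
         other_count = x$other_count,
         ratio_short_to_long = x$ratio_short_to_long)
}

map_cells <- function(density, chi_edges, theta_edges) {
  cm <- (head(chi_edges, -1) + tail(chi_edges, -1)) / 2
  tm <- (head(theta_edges, -1) + tail(theta_edges, -1)) / 2
  tibble(
    theta_bin = rep(seq_along(tm), times = length(cm)),
    chi_bin = rep(seq_along(cm), each = length(tm)),
    theta_mid = rep(tm, times = length(cm)),
    chi_mid = rep(cm, each = length(tm)),
    value = as.vector(density))
}

#' Tidy a two-axis map or subtraction map into long cell form
#'
#' @param x A `two_axis_map` or `subtraction_map`.
#' @param ... Unused.
#' @return A tibble with bin indices, bin midpoints (overflow cells get
#'   infinite midpoints) and the cell value (`density` or `difference`).
#' @export
tidy.two_axis_map <- function(x, ...) {
  map_cells(x$density, x$chi_edges, x$theta_edges) |>
    rename(density = "value")
}

#' @rdname tidy.two_axis_map
#' @export
tidy.subtraction_map <- function(x, ...) {
  map_cells(x$difference, x$chi_edges, x$theta_edges) |>
    rename(difference = "value")
}
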