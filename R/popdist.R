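#' Displacement sample at a fixed lag
#'
#' One origin-referenced displacement pair per qualifying track: the track's
#' angular travel from its first observation after exactly `lag_ms` (which
#' must be an integer multiple of the frame time; 1.6 ms at 100 us/frame is
#' 16 frames). Tracks shorter than the lag contribute nothing.
#'
#' @param trajs Trajectory tibble (post lifetime filter).
#' @param lag_ms Lag, ms.
#' @param frame_time Frame time, microseconds.
#' @param condition Optional condition label attached to the result.
#' @return Tibble with `track_id`, `d_theta_mrad`, `d_chi_mrad`; attributes
#'   `lag_ms` and `condition`. May have zero rows.
#' @export
displacement_sample <- function(trajs, lag_ms, frame_time = 100,
                                condition = NULL) {
  k <- lag_to_frames(lag_ms, frame_time)
  assert_cols(trajs, c("track_id", "frame", "theta_mrad", "chi_mrad"), "`trajs`")
  out <- trajs |>
    group_by(.data$track_id) |>
    arrange(.data$frame, .by_group = TRUE) |>
    filter(n() >= k + 1L) |>
    summarise(
      d_theta_mrad = .data$theta_mrad[k + 1L] - .data$theta_mrad[1L],
      d_chi_mrad = .data$chi_mrad[k + 1L] - .data$chi_mrad[1L],
      .groups = "drop")
  attr(out, "lag_ms") <- lag_ms
  attr(out, "condition") <- condition
  out
}

# Histogram on a bin_width-aligned grid; symmetric about 0 so that mirrored
# samples produce exactly mirrored histograms.
hist_counts <- function(values, bin_width) {
  m <- max(abs(values))
  edge <- (floor(m / bin_width) + 1) * bin_width
  breaks <- seq(-edge, edge, by = bin_width)
  idx <- findInterval(values, breaks, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = length(breaks) - 1)
  tibble(mid = (head(breaks, -1) + tail(breaks, -1)) / 2, count = counts)
}

# Least-squares fit of a k-component Gaussian sum to histogram counts.
# Parameters per component: count mass a_j, mean mu_j, sd s_j.
fit_gauss_sum <- function(h, k, n, bin_width) {
  qs <- quantile(rep(h$mid, h$count), probs = (2 * seq_len(k) - 1) / (2 * k),
                 names = FALSE, type = 1)
  sd0 <- max(sd(rep(h$mid, h$count)) / k, bin_width / 2)
  par0 <- c(rep(n / k, k), qs, rep(sd0, k))
  lower <- c(rep(0, k), rep(min(h$mid) - bin_width, k), rep(bin_width / 4, k))
  upper <- c(rep(2 * n, k), rep(max(h$mid) + bin_width, k),
             rep(diff(range(h$mid)) + bin_width, k))
  w <- 1 / pmax(h$count, 1)
  model <- function(p) {
    a <- p[1:k]; mu <- p[(k + 1):(2 * k)]; s <- p[(2 * k + 1):(3 * k)]
    rowSums(vapply(seq_len(k),
                   function(j) a[j] * bin_width * dnorm(h$mid, mu[j], s[j]),
                   numeric(nrow(h))))
  }
  fit <- minpack.lm::nls.lm(
    par = par0, lower = lower, upper = upper,
    fn = function(p) sqrt(w) * (h$count - model(p)),
    control = minpack.lm::nls.lm.control(maxiter = 300))
  p <- fit$par
  list(a = p[1:k], mu = p[(k + 1):(2 * k)], s = p[(2 * k + 1):(3 * k)],
       rss = fit$deviance, sd_floor = lower[2 * k + 1])
}

#' Gaussian mixture decomposition of a twist-displacement distribution
#'
#' Histogram-based weighted least squares of a 1-3 component Gaussian sum
#' fitted to the binned twist displacements (weights `1/max(count, 1)`),
#' mirroring the practice of fitting Gaussian curves to displacement
#' histograms. With `n_components = "auto"` the component count grows while
#' an extra component reduces the weighted residual sum of squares by more
#' than `improve_threshold` (relative), i.e. the smallest count whose
#' successor brings no substantial improvement. Sample-size preconditions:
#' >= 50 values for 1 component, >= 150 for 2, >= 300 for 3.
#'
#' Components are ordered by area fraction (descending, ties by mean
#' ascending). A component whose mean lies below
#' `-2 * sqrt(variance of the main component)` is flagged `"fast_cw"` (the
#' clockwise-drifting subpopulation); the main component is flagged
#' `"main"`.
#'
#' @param values Numeric twist displacements (mrad), or a
#'   [displacement_sample()] tibble (its `d_chi_mrad` column is used).
#' @param n_components 1, 2, 3 or `"auto"`.
#' @param bin_width Histogram bin width, mrad (default 1).
#' @param improve_threshold Relative weighted-RSS improvement required to
#'   accept an additional component in auto mode (default 0.5).
#' @return An object of class `mixture_fit`: `components` tibble (`mean`,
#'   `variance`, `area_fraction`, `role`), `n_components`, `rss`,
#'   `selection` record, `histogram`, `n_values`, `bin_width`.
#' @export
fit_mixture <- function(values, n_components = "auto", bin_width = 1,
                        improve_threshold = 0.5) {
  if (is.data.frame(values)) {
    assert_cols(values, "d_chi_mrad", "`values`")
    values <- values$d_chi_mrad
  }
  values <- values[is.finite(values)]
  n <- length(values)
  min_n <- c(50L, 150L, 300L)
  if (!identical(n_components, "auto")) {
    k_req <- as.integer(n_components)
    if (!k_req %in% 1:3) abort("`n_components` must be 1, 2, 3 or \"auto\".")
    if (n < min_n[k_req]) {
      abort(sprintf("Need >= %d values for %d component(s); got %d.",
                    min_n[k_req], k_req, n))
    }
  } else if (n < min_n[1]) {
    abort(sprintf("Need >= %d values; got %d.", min_n[1], n))
  }
  if (sd(values) == 0) abort("Degenerate sample: all values identical.")

  h <- hist_counts(values, bin_width)
  fits <- list(); sel <- list()
  k_max <- if (identical(n_components, "auto")) max(which(n >= min_n)) else
    as.integer(n_components)
  k_min <- if (identical(n_components, "auto")) 1L else k_max
  chosen <- k_min
  for (k in k_min:k_max) {
    fits[[k]] <- fit_gauss_sum(h, k, n, bin_width)
    improvement <- if (k == 1 || is.null(fits[[k - 1]])) NA_real_ else
      (fits[[k - 1]]$rss - fits[[k]]$rss) / fits[[k - 1]]$rss
    sel[[length(sel) + 1]] <- tibble(k = k, rss = fits[[k]]$rss,
                                     improvement = improvement)
    if (identical(n_components, "auto")) {
      if (k > k_min && !is.na(improvement) && improvement > improve_threshold) {
        chosen <- k
      } else if (k > k_min) {
        break  # no substantial improvement; stop growing
      }
    } else {
      chosen <- k
    }
  }
  f <- fits[[chosen]]
  # degenerate component: sd pinned at the floor with negligible mass -> merge
  degen <- f$s <= f$sd_floor * 1.01 & f$a / sum(f$a) < 0.02
  if (chosen > 1 && any(degen)) {
    chosen <- chosen - 1L
    f <- fits[[chosen]] %||% fit_gauss_sum(h, chosen, n, bin_width)
  }

  frac <- f$a / sum(f$a)
  comp <- tibble(mean = f$mu, variance = f$s^2, sd = f$s,
                 area_fraction = frac) |>
    arrange(dplyr::desc(.data$area_fraction), .data$mean)
  main_var <- comp$variance[1]
  comp$role <- ifelse(seq_len(nrow(comp)) == 1, "main",
                      ifelse(comp$mean < -2 * sqrt(main_var), "fast_cw",
                             "other"))
  structure(
    list(components = comp, n_components = chosen,
         rss = f$rss, selection = bind_rows(sel), histogram = h,
         n_values = n, bin_width = bin_width),
    class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit> %d component(s), n = %d, weighted RSS = %.4g\n",
              x$n_components, x$n_values, x$rss))
  print(as.data.frame(x$components), digits = 3)
  invisible(x)
}

#' Bootstrap confidence intervals for mixture parameters
#'
#' Nonparametric bootstrap: resamples the displacement values with
#' replacement, refits the mixture at the fitted component count, and returns
#' percentile intervals for each component's mean and area fraction
#' (components matched by rank order of area fraction).
#'
#' @inheritParams fit_mixture
#' @param B Number of bootstrap replicates.
#' @param level Confidence level.
#' @param seed Seed for resampling.
#' @return Tibble with `component`, `term`, `estimate`, `lower`, `upper`.
#' @export
bootstrap_mixture <- function(values, n_components = "auto", bin_width = 1,
                              B = 200, level = 0.95, seed = 1) {
  if (is.data.frame(values)) values <- values$d_chi_mrad
  fit <- fit_mixture(values, n_components, bin_width)
  k <- fit$n_components
  set.seed(seed)
  reps <- lapply(seq_len(B), function(b) {
    v <- sample(values, replace = TRUE)
    f <- tryCatch(fit_mixture(v, k, bin_width), error = function(e) NULL)
    if (is.null(f) || nrow(f$components) != k) return(NULL)
    f$components
  })
  reps <- reps[!vapply(reps, is.null, logical(1))]
  a <- (1 - level) / 2
  out <- lapply(seq_len(k), function(j) {
    means <- vapply(reps, function(cc) cc$mean[j], numeric(1))
    fracs <- vapply(reps, function(cc) cc$area_fraction[j], numeric(1))
    bind_rows(
      tibble(component = j, term = "mean",
             estimate = fit$components$mean[j],
             lower = quantile(means, a, names = FALSE),
             upper = quantile(means, 1 - a, names = FALSE)),
      tibble(component = j, term = "area_fraction",
             estimate = fit$components$area_fraction[j],
             lower = quantile(fracs, a, names = FALSE),
             upper = quantile(fracs, 1 - a, names = FALSE)))
  })
  bind_rows(out)
}

#' Shoulder asymmetry of a twist-displacement distribution
#'
#' Quantifies the left/right asymmetry of the displacement histogram about its
#' mode: sample skewness (negative = clockwise bias) and the ratio of the mean
#' absolute histogram slope on the negative side of the mode to that on the
#' positive side (> 1 means the clockwise shoulder falls more steeply).
#'
#' @param values Numeric twist displacements (mrad) or a displacement-sample
#'   tibble; needs >= 100 values.
#' @param bin_width Histogram bin width, mrad.
#' @return One-row tibble: `n`, `skewness`, `skew_se`, `left_steepness`,
#'   `right_steepness`, `steepness_ratio`.
#' @export
asymmetry_summary <- function(values, bin_width = 1) {
  if (is.data.frame(values)) values <- values$d_chi_mrad
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 100) abort("Need >= 100 values.")
  m <- mean(values)
  m2 <- mean((values - m)^2); m3 <- mean((values - m)^3)
  skew <- m3 / m2^1.5
  h <- hist_counts(values, bin_width)
  dens <- h$count / (n * bin_width)
  # treat the whole maximal-density run as the mode so that mirroring the
  # sample exactly swaps the two shoulders
  runs <- which(dens == max(dens))
  slope <- diff(dens) / bin_width
  left <- abs(slope[seq_len(min(runs) - 1)])
  right <- if (max(runs) <= length(slope))
    abs(slope[seq(max(runs), length(slope))]) else numeric(0)
  left_st <- if (length(left)) mean(left) else NA_real_
  right_st <- if (length(right)) mean(right) else NA_real_
  tibble(n = n, skewness = skew, skew_se = sqrt(6 / n),
         left_steepness = left_st, right_steepness = right_st,
         steepness_ratio = left_st / right_st)
}
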